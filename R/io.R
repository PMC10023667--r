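# Plain-text I/O: TSV matrices/tables and GMT gene-set files.
# All TSV files are tab-delimited, UTF-8, header row, ids in the first
# column, no quoting.

#' Write an expression or CT matrix as TSV
#'
#' @param mat Matrix with row and column names.
#' @param path Output file.
#' @param id_col Name of the first (id) column.
#' @export
write_tsv_matrix <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#'
#' @param path Input file; first column holds row ids.
#' @return Numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated format: set name, description, then member ids.
#'
#' @param path GMT file.
#' @return Named list of gene-id vectors; descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): need name, description, members",
                     call. = FALSE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (defaults to the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stop("sets must be named", call. = FALSE)
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
}
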