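# Sample QC, expression filters, region aggregation, CT table assembly and
# the neurotransmitter-panel display transform.

.qc_metric_cols <- c("pct_unique_mapping", "pct_hq_aligned", "pct_mrna_bases",
                     "pct_intergenic_bases", "median_5to3_bias",
                     "gc_dropout", "at_dropout")

.check_qc_table <- function(table) {
  if (!is.data.frame(table) || !all(c("sample_id", .qc_metric_cols) %in% names(table)))
    stop("QC table must contain `sample_id` and the seven metric columns: ",
         paste(.qc_metric_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(table$sample_id)) stop("duplicated sample ids", call. = FALSE)
  pct <- c("pct_unique_mapping", "pct_hq_aligned", "pct_mrna_bases",
           "pct_intergenic_bases")
  for (col in pct)
    if (any(table[[col]] < 0 | table[[col]] > 100))
      stop(sprintf("`%s` must lie in [0, 100]", col), call. = FALSE)
  invisible(table)
}

#' Per-sample quality z scores
#'
#' For each QC metric, `z = (value - mean) / s.d.` across samples.  The
#' default s.d. uses the `n - 1` (sample) denominator, matching R's [sd()];
#' set `sd_type = "population"` for the `n` denominator.  A metric that is
#' constant across samples gets z = 0 throughout (it can flag nothing).
#'
#' @param table QC metric `data.frame` (see [generate_qc_table()] for the
#'   expected columns).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Matrix of z scores, samples in rows (named by `sample_id`).
#' @export
qc_zscores <- function(table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  .check_qc_table(table)
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 samples to compute quality z scores", call. = FALSE)
  vals <- as.matrix(table[, .qc_metric_cols])
  mu <- colMeans(vals)
  s <- apply(vals, 2L, sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  z <- sweep(sweep(vals, 2L, mu), 2L, s, "/")
  z[, s == 0] <- 0
  rownames(z) <- table$sample_id
  z
}

#' Remove low-quality samples by outlier-index counting
#'
#' A sample accrues one outlier index for each violated condition among:
#' percent uniquely mapped reads below 50 (absolute); z > 2 for percent
#' intergenic bases, GC dropout or AT dropout; z < -2 for percent
#' high-quality aligned reads, percent mRNA bases or median 5'-to-3' bias.
#' Samples with more than two outlier indexes (i.e. at least three) are
#' removed.
#'
#' @inheritParams qc_zscores
#' @param z_limit Magnitude of the directional z thresholds.
#' @param max_outlier_index Largest tolerated outlier-index count.
#' @param min_unique_pct Absolute unique-mapping threshold (percent).
#' @return List with `kept` and `removed` sample-id vectors and
#'   `outlier_index`, the per-sample count (named integer).
#' @export
qc_remove_samples <- function(table, z_limit = 2, max_outlier_index = 2,
                              min_unique_pct = 50,
                              sd_type = c("sample", "population")) {
  .check_qc_table(table)
  z <- qc_zscores(table, sd_type = match.arg(sd_type))
  idx <- (table$pct_unique_mapping < min_unique_pct) +
    (z[, "pct_intergenic_bases"] > z_limit) +
    (z[, "gc_dropout"] > z_limit) +
    (z[, "at_dropout"] > z_limit) +
    (z[, "pct_hq_aligned"] < -z_limit) +
    (z[, "pct_mrna_bases"] < -z_limit) +
    (z[, "median_5to3_bias"] < -z_limit)
  idx <- setNames(as.integer(idx), table$sample_id)
  removed <- names(idx)[idx > max_outlier_index]
  list(kept = setdiff(table$sample_id, removed), removed = removed,
       outlier_index = idx)
}

#' Keep genes detected in a minimum fraction of samples
#'
#' A gene counts as detected in a sample when its value exceeds
#' `detect_thresh` (default 0, i.e. any nonzero signal).  Genes detected in
#' at least `min_frac` of samples are kept; the boundary is inclusive, so a
#' gene detected in exactly 10% of samples survives the default filter.
#'
#' @param expr Sample-axis expression matrix (genes x samples).
#' @param min_frac Minimum detected fraction (default 0.10).
#' @param detect_thresh Detection threshold on the raw value.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(expr, min_frac = 0.10, detect_thresh = 0) {
  if (!is.matrix(expr) || nrow(expr) == 0L || ncol(expr) == 0L)
    stop("empty expression matrix", call. = FALSE)
  .check_expr_matrix(expr)
  .check_fraction(min_frac, "min_frac")
  n_det <- rowSums(expr > detect_thresh)
  keep <- n_det >= min_frac * ncol(expr) - 1e-9
  expr[keep, , drop = FALSE]
}

#' Drop the lowest-expressed fraction of genes
#'
#' Genes are ranked by mean expression across columns and the lowest
#' `floor(drop_frac * G)` genes are dropped; ties are broken by gene id
#' (lexicographic), so the result is deterministic.  Note that, being a
#' fixed-fraction rank filter, reapplying it to its own output drops further
#' genes.
#'
#' @param expr Expression matrix (genes x samples or genes x regions).
#' @param drop_frac Fraction of genes to drop (default 0.05).
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(expr, drop_frac = 0.05) {
  .check_expr_matrix(expr)
  .check_fraction(drop_frac, "drop_frac")
  if (nrow(expr) == 0L) stop("empty expression matrix", call. = FALSE)
  n_drop <- floor(drop_frac * nrow(expr))
  if (n_drop == 0L) return(expr)
  ord <- order(rowMeans(expr), rownames(expr))
  drop_ids <- rownames(expr)[ord[seq_len(n_drop)]]
  expr[!rownames(expr) %in% drop_ids, , drop = FALSE]
}

#' Average samples into regions
#'
#' Each region's value is the unweighted arithmetic mean over its samples
#' (hemispheres, when present in the map, are simply pooled).  Regions with
#' fewer than `min_samples` samples are excluded and reported via the
#' `"excluded_regions"` attribute of the result.
#'
#' @param expr Sample-axis expression matrix (genes x samples).
#' @param map `data.frame` with `sample_id` and `region_id`, or a named
#'   character vector `sample_id -> region_id`.  Every column of `expr` must
#'   be mapped.
#' @param min_samples Minimum samples per retained region.
#' @return Region-axis matrix (genes x regions) with attribute
#'   `"excluded_regions"`.
#' @export
aggregate_regions <- function(expr, map, min_samples = 1) {
  .check_expr_matrix(expr)
  if (is.data.frame(map)) {
    if (!all(c("sample_id", "region_id") %in% names(map)))
      stop("`map` needs `sample_id` and `region_id` columns", call. = FALSE)
    map <- setNames(as.character(map$region_id), map$sample_id)
  }
  missing <- setdiff(colnames(expr), names(map))
  if (length(missing))
    stop("unmapped sample ids: ", paste(missing, collapse = ", "), call. = FALSE)
  region <- map[colnames(expr)]
  counts <- table(region)
  keep_regions <- names(counts)[counts >= min_samples]
  excluded <- setdiff(names(counts), keep_regions)
  out <- vapply(keep_regions,
                function(r) rowMeans(expr[, region == r, drop = FALSE]),
                numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), keep_regions))
  attr(out, "excluded_regions") <- excluded
  out
}

#' Assemble the per-age mean CT table
#'
#' Averages per-animal cortical thickness within each age group and drops
#' age groups represented by fewer than `min_group_size` animals (e.g. a
#' single animal at the oldest age), reporting them via attributes.
#'
#' @param ct_animal Matrix of CT values, regions x animals (mm).
#' @param animal_ages Numeric age (years) per animal, aligned with columns.
#' @param min_group_size Minimum animals per retained age group.
#' @return Regions x ages matrix (mm) with attributes `"n_animals"` (named
#'   count per retained age) and `"dropped_ages"`.
#' @export
build_ct_table <- function(ct_animal, animal_ages, min_group_size = 2) {
  if (!is.matrix(ct_animal) || is.null(rownames(ct_animal)))
    stop("`ct_animal` must be a matrix with region row names", call. = FALSE)
  if (length(animal_ages) != ncol(ct_animal))
    stop("one age per animal column is required", call. = FALSE)
  if (any(ct_animal <= 0)) stop("cortical thickness must be positive", call. = FALSE)
  ages <- sort(unique(animal_ages))
  counts <- vapply(ages, function(a) sum(animal_ages == a), integer(1))
  keep <- counts >= min_group_size
  dropped <- ages[!keep]
  ages <- ages[keep]
  if (!length(ages)) stop("no age group meets `min_group_size`", call. = FALSE)
  out <- vapply(ages,
                function(a) rowMeans(ct_animal[, animal_ages == a, drop = FALSE]),
                numeric(nrow(ct_animal)))
  out <- matrix(out, nrow = nrow(ct_animal),
                dimnames = list(rownames(ct_animal), as.character(ages)))
  attr(out, "n_animals") <- setNames(counts[keep], as.character(ages))
  attr(out, "dropped_ages") <- dropped
  out
}

#' Median-normalised exponential view of a gene panel
#'
#' For each panel gene, subtracts its median regional (log-scale) value and
#' exponentiates: `y_r = 2^(x_r - median(x))`, so every gene is on a common
#' positive scale with per-gene median 1.  Used to display regional
#' landscapes of e.g. neurotransmitter-related genes.
#'
#' @param expr Region-axis expression matrix (genes x regions).
#' @param panel Character vector of panel gene ids; ids absent from the
#'   matrix are reported with a warning, not an error.
#' @return Transformed matrix (panel genes x regions).
#' @export
neurotransmitter_view <- function(expr, panel) {
  .check_expr_matrix(expr)
  if (length(panel) == 0L) stop("empty gene panel", call. = FALSE)
  missing <- setdiff(panel, rownames(expr))
  if (length(missing))
    warning("panel ids absent from the matrix: ", paste(missing, collapse = ", "))
  present <- intersect(panel, rownames(expr))
  if (!length(present)) stop("no panel gene present in the matrix", call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  med <- apply(sub, 1L, median)
  2^sweep(sub, 1L, med)
}
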