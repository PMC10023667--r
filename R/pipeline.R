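# End-to-end orchestration: QC -> filters -> aggregation -> per-age PLS ->
# persistence -> consensus -> enrichment, with a reproducibility manifest.

#' Run the full CT imaging-transcriptomics pipeline
#'
#' Accepts in-memory objects or TSV/GMT paths for every input.  Stages, in
#' order: QC sample removal (when a QC table is supplied), expressed-gene
#' filter and region aggregation (when the expression matrix is sample-axis,
#' i.e. a sample-to-region map is supplied), low-expression filter, per-age
#' PLS1 with permutation test and bootstrap, per-age selection, persistence
#' intersection, consensus assembly, and (when gene sets are supplied)
#' enrichment of the consensus lists.  When `out_dir` is given, result
#' tables are written as TSV/JSON together with a manifest recording the
#' configuration, seeds, per-stage gene/sample counts and MD5 hashes of the
#' outputs; reruns with the same inputs and seed are byte-identical.
#'
#' @param expr Expression matrix (genes x samples or genes x regions), or a
#'   TSV path.
#' @param ct_table Regions x ages CT matrix, or a TSV path.
#' @param sample_map Optional `data.frame` (`sample_id`, `region_id`) or TSV
#'   path; its presence marks `expr` as sample-axis.
#' @param qc Optional QC metric table (or TSV path) for sample removal.
#' @param gene_sets Optional `"gene_set_collection"`, named list of sets, or
#'   GMT path, for consensus enrichment (universe defaults to the filtered
#'   gene universe).
#' @param min_frac,drop_frac Filter parameters (see [filter_expressed()],
#'   [filter_low_expression()]).
#' @param min_samples Minimum samples per region for aggregation.
#' @param n_perm,n_boot Resampling sizes.
#' @param z_thresh,r_thresh,alpha Selection/enrichment thresholds.
#' @param seed Root seed for all resampling.
#' @param out_dir Optional output directory.
#' @return List with `consensus`, `pls` (per-age results), `enrichment`
#'   (or `NULL`), `expr_regions` (the analysed matrix), and `manifest`.
#' @export
run_pipeline <- function(expr, ct_table, sample_map = NULL, qc = NULL,
                         gene_sets = NULL, min_frac = 0.10, drop_frac = 0.05,
                         min_samples = 1, n_perm = 1000, n_boot = 1000,
                         z_thresh = 3, r_thresh = 0.3, alpha = 0.05,
                         seed = 1L, out_dir = NULL) {
  if (is.character(expr)) expr <- read_tsv_matrix(expr)
  if (is.character(ct_table)) ct_table <- read_tsv_matrix(ct_table)
  if (is.character(sample_map))
    sample_map <- read.delim(sample_map, stringsAsFactors = FALSE)
  if (is.character(qc)) qc <- read.delim(qc, stringsAsFactors = FALSE)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)

  counts <- list(genes_in = nrow(expr), columns_in = ncol(expr))

  qc_result <- NULL
  if (!is.null(qc)) {
    qc_result <- qc_remove_samples(qc)
    keep <- intersect(colnames(expr), qc_result$kept)
    expr <- expr[, keep, drop = FALSE]
    counts$samples_after_qc <- ncol(expr)
  }

  if (!is.null(sample_map)) {
    expr <- filter_expressed(expr, min_frac = min_frac)
    counts$genes_expressed <- nrow(expr)
    expr <- aggregate_regions(expr, sample_map, min_samples = min_samples)
    counts$regions <- ncol(expr)
  }

  expr <- filter_low_expression(expr, drop_frac = drop_frac)
  counts$genes_analysed <- nrow(expr)

  regions <- intersect(colnames(expr), rownames(ct_table))
  if (length(regions) < 3L)
    stop("fewer than 3 regions shared between expression and CT table",
         call. = FALSE)
  expr <- expr[, regions, drop = FALSE]
  ct_table <- ct_table[regions, , drop = FALSE]

  pls <- pls_consensus_pipeline(expr, ct_table, n_perm = n_perm,
                                n_boot = n_boot, z_thresh = z_thresh,
                                r_thresh = r_thresh, alpha = alpha,
                                seed = seed)
  cons <- pls$consensus
  counts$consensus_plus <- length(cons$consensus_plus)
  counts$consensus_minus <- length(cons$consensus_minus)

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    if (!inherits(gene_sets, "gene_set_collection"))
      gene_sets <- gene_set_collection(as.list(gene_sets), rownames(expr))
    enrichment <- panel_overlap_report(cons, gene_sets, alpha = alpha)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctpls")),
    seed = as.integer(seed),
    parameters = list(min_frac = min_frac, drop_frac = drop_frac,
                      min_samples = min_samples, n_perm = n_perm,
                      n_boot = n_boot, z_thresh = z_thresh,
                      r_thresh = r_thresh, alpha = alpha),
    counts = counts,
    ages = colnames(ct_table),
    explained_var = vapply(pls$fits, `[[`, numeric(1), "explained_var"),
    perm_p = vapply(pls$permutations, `[[`, numeric(1), "perm_p")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_matrix(expr, file.path(out_dir, "expr_regions.tsv"))
    write_tsv_matrix(ct_table, file.path(out_dir, "ct_table.tsv"),
                     id_col = "region_id")
    for (age in names(pls$selections)) {
      tab <- pls$selections[[age]]$table
      write.table(tab, file.path(out_dir, sprintf("selection_age_%s.tsv", age)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(cons$provenance, file.path(out_dir, "consensus_provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(cons$consensus_plus, file.path(out_dir, "consensus_plus.txt"))
    writeLines(cons$consensus_minus, file.path(out_dir, "consensus_minus.txt"))
    if (!is.null(enrichment))
      write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$output_md5 <- as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(consensus = cons, pls = pls, enrichment = enrichment,
       expr_regions = expr, manifest = manifest)
}
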