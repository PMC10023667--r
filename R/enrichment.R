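# Marker derivation from cell-type expression and Fisher-exact enrichment
# of gene lists against marker sets and functional panels.

#' Build a gene-set collection
#'
#' @param sets Named list of gene-id character vectors (deduplicated).
#' @param universe Character vector of background gene ids.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  structure(list(sets = lapply(sets, unique), universe = unique(universe)),
            class = "gene_set_collection")
}

#' Derive cell-type marker gene sets from grouped expression
#'
#' For each cell type and gene, the fold change is the mean expression in
#' the type divided by the mean of the per-type average expression over all
#' other types (a small pseudocount guards empty denominators); significance
#' comes from a two-sided Wilcoxon rank-sum test of the in-type cells
#' against all other cells, BH-adjusted across genes within the type.  A
#' gene is a marker when fold change is at least `fold_thresh` (inclusive;
#' exactly twofold qualifies) and `q < alpha`.
#'
#' @param expr Genes x cells expression matrix.
#' @param cell_type Factor or character vector of cell-type labels, one per
#'   cell (at least 2 types, at least 2 cells each).
#' @param fold_thresh Minimum fold change (default 2, inclusive).
#' @param alpha FDR threshold (default 0.05).
#' @param pseudocount Added to numerator and denominator means.
#' @return A `"gene_set_collection"` of marker sets (universe = all genes in
#'   `expr`), with per-type `data.frame`s of fold/p/q in the `"stats"`
#'   attribute.
#' @export
derive_markers <- function(expr, cell_type, fold_thresh = 2, alpha = 0.05,
                           pseudocount = 1e-9) {
  .check_expr_matrix(expr)
  cell_type <- as.factor(cell_type)
  if (length(cell_type) != ncol(expr))
    stop("one cell-type label per cell column is required", call. = FALSE)
  types <- levels(droplevels(cell_type))
  if (length(types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  if (any(table(cell_type) < 2L)) stop("need at least 2 cells per type", call. = FALSE)
  type_means <- matrix(
    vapply(types,
           function(tp) rowMeans(expr[, cell_type == tp, drop = FALSE]),
           numeric(nrow(expr))),
    nrow = nrow(expr), dimnames = list(rownames(expr), types))
  sets <- list(); stats_list <- list()
  for (ti in seq_along(types)) {
    tp <- types[ti]
    in_mean <- type_means[, ti]
    other_mean <- rowMeans(type_means[, -ti, drop = FALSE])
    fold <- (in_mean + pseudocount) / (other_mean + pseudocount)
    in_cells <- cell_type == tp
    p <- vapply(seq_len(nrow(expr)), function(g)
      suppressWarnings(
        wilcox.test(expr[g, in_cells], expr[g, !in_cells])$p.value),
      numeric(1))
    p[is.na(p)] <- 1  # identical distributions with full ties
    q <- bh_adjust(p)
    is_marker <- fold >= fold_thresh * (1 - 1e-8) & q < alpha
    sets[[tp]] <- rownames(expr)[is_marker]
    stats_list[[tp]] <- data.frame(gene = rownames(expr), fold = fold,
                                   p = p, q = q, marker = is_marker,
                                   stringsAsFactors = FALSE)
  }
  out <- gene_set_collection(sets, rownames(expr))
  attr(out, "stats") <- stats_list
  out
}

#' Fisher-exact enrichment of a gene list against a set collection
#'
#' For every set, builds the 2x2 table `a` = list-and-set, `b` = list only,
#' `c` = set only, `d` = rest of universe, runs [fisher_exact()], and adjusts
#' p values across the sets of the collection (one BH family per collection
#' per list).  A set is flagged enriched when `OR > 1` and `q < alpha`.
#' List members and set members outside the universe are dropped (with a
#' warning for the list).
#'
#' @param gene_list Character vector of selected gene ids.
#' @param collection A `"gene_set_collection"`.
#' @param alpha FDR threshold for the enriched flag.
#' @return `data.frame` with one row per set: `set`, `overlap`, `list_size`,
#'   `set_size`, `universe_size`, `or`, `or_sample`, `ci_lo`, `ci_hi`, `p`,
#'   `q`, `enriched`.
#' @export
enrich_sets <- function(gene_list, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  if (length(gene_list) == 0L) stop("empty gene list", call. = FALSE)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) in the list are outside the universe",
            " and were dropped")
    gene_list <- intersect(gene_list, universe)
    if (length(gene_list) == 0L)
      stop("no gene of the list remains inside the universe", call. = FALSE)
  }
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(unique(collection$sets[[nm]]), universe)
    a <- length(intersect(gene_list, set))
    b <- length(gene_list) - a
    c_ <- length(set) - a
    d <- length(universe) - a - b - c_
    fe <- fisher_exact(a, b, c_, d)
    data.frame(set = nm, overlap = a, list_size = length(gene_list),
               set_size = length(set), universe_size = length(universe),
               or = fe$or, or_sample = fe$or_sample,
               ci_lo = fe$ci[1], ci_hi = fe$ci[2], p = fe$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$enriched <- !is.na(out$or) & out$or > 1 & out$q < alpha
  rownames(out) <- NULL
  out
}

#' Enrichment report of a consensus result against gene panels
#'
#' Runs [enrich_sets()] for the combined consensus list and separately for
#' the PLS1+ and PLS1- lists against every panel, returning one long-format
#' table (each list is its own BH family).  An empty list yields zero-overlap
#' rows flagged not enriched rather than an error.
#'
#' @param consensus A `"ct_consensus"` result.
#' @param panels A `"gene_set_collection"` of functional panels or marker
#'   sets sharing the consensus universe.
#' @param alpha FDR threshold.
#' @return Long `data.frame` with a `list` column in `{all, plus, minus}`.
#' @export
panel_overlap_report <- function(consensus, panels, alpha = 0.05) {
  stopifnot(inherits(consensus, "ct_consensus"),
            inherits(panels, "gene_set_collection"))
  lists <- list(all = union(consensus$consensus_plus, consensus$consensus_minus),
                plus = consensus$consensus_plus,
                minus = consensus$consensus_minus)
  out <- lapply(names(lists), function(nm) {
    gl <- lists[[nm]]
    if (length(gl) == 0L) {
      res <- data.frame(set = names(panels$sets), overlap = 0L, list_size = 0L,
                        set_size = vapply(panels$sets, function(s)
                          length(intersect(s, panels$universe)), integer(1)),
                        universe_size = length(panels$universe),
                        or = 0, or_sample = NaN, ci_lo = 0, ci_hi = Inf,
                        p = 1, q = 1, enriched = FALSE,
                        stringsAsFactors = FALSE)
    } else {
      res <- enrich_sets(gl, panels, alpha = alpha)
    }
    cbind(list = nm, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
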