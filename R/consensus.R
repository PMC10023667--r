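# Per-age gene selection, persistence across ages, and consensus assembly.

#' Select CT-related genes for one age group
#'
#' PLS1+ genes have bootstrap Z above `z_thresh`, PLS1- genes below
#' `-z_thresh` (strict inequalities).  Independently, each gene's Pearson
#' correlation with CT is computed with its two-sided p value; q values are
#' Benjamini-Hochberg-adjusted across all genes within this age, and a gene
#' is flagged CT-correlated when `|r| > r_thresh` (strict; r = 0.30 exactly
#' does not pass the default) and `q < alpha`.
#'
#' @inheritParams fit_pls1
#' @param fit A [fit_pls1()] result for this age.
#' @param boot A [pls1_bootstrap()] result for the same fit.
#' @param z_thresh Bootstrap-Z selection threshold (default 3).
#' @param r_thresh Correlation-magnitude threshold (default 0.3).
#' @param alpha FDR threshold (default 0.05).
#' @return Object of class `"age_selection"`: `plus`, `minus`,
#'   `ct_correlated` gene-id vectors and `table`, a per-gene `data.frame`
#'   with `z`, `r`, `p`, `q`.
#' @export
select_age_genes <- function(fit, boot, expr, ct, z_thresh = 3,
                             r_thresh = 0.3, alpha = 0.05) {
  stopifnot(inherits(fit, "pls1_fit"), inherits(boot, "pls_bootstrap"))
  y <- .align_expr_ct(expr, ct)
  genes <- names(fit$weights)
  if (!identical(genes, names(boot$z)) || !identical(genes, rownames(expr)))
    stop("fit, bootstrap and expression matrix must share the same genes",
         call. = FALSE)
  r <- .cor_cols(t(expr), y)
  r[is.na(r)] <- 0
  p <- .r_to_p(r, length(y))
  p[r == 0] <- 1
  q <- bh_adjust(p)
  z <- boot$z
  tab <- data.frame(gene = genes, z = as.numeric(z), r = r, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = genes)
  structure(list(plus = genes[z > z_thresh],
                 minus = genes[z < -z_thresh],
                 ct_correlated = genes[abs(r) > r_thresh & q < alpha],
                 table = tab,
                 thresholds = c(z = z_thresh, r = r_thresh, alpha = alpha)),
            class = "age_selection")
}

#' Intersect per-age selections into persistent gene sets
#'
#' A gene is persistent when selected with the same sign at every age;
#' because the per-age plus and minus sets are disjoint, a gene switching
#' sign between ages belongs to neither persistent set.
#'
#' @param selections List of [select_age_genes()] results, one per age.
#' @return List with `persistent_plus` and `persistent_minus`.
#' @export
persistence_intersection <- function(selections) {
  if (length(selections) == 0L) stop("no age selections supplied", call. = FALSE)
  stopifnot(all(vapply(selections, inherits, logical(1), "age_selection")))
  list(persistent_plus = Reduce(intersect, lapply(selections, `[[`, "plus")),
       persistent_minus = Reduce(intersect, lapply(selections, `[[`, "minus")))
}

#' Assemble consensus CT-related PLS1 genes
#'
#' The CT-correlated list contains genes flagged at every age; the consensus
#' PLS1+/PLS1- lists are the intersection of the persistent sets with that
#' list.  A per-gene provenance table (z, r, q per age, final label) is
#' attached.
#'
#' @param persistent A [persistence_intersection()] result.
#' @param selections The same per-age list used to compute it; names (if
#'   present) label the ages in the provenance table.
#' @return Object of class `"ct_consensus"`: `persistent_plus`,
#'   `persistent_minus`, `ct_correlated`, `consensus_plus`,
#'   `consensus_minus`, `provenance` (`data.frame`).
#' @export
consensus_genes <- function(persistent, selections) {
  stopifnot(is.list(persistent),
            all(c("persistent_plus", "persistent_minus") %in% names(persistent)))
  if (length(selections) == 0L) stop("no age selections supplied", call. = FALSE)
  ages <- names(selections)
  if (is.null(ages)) ages <- as.character(seq_along(selections))
  ct_corr <- Reduce(intersect, lapply(selections, `[[`, "ct_correlated"))
  consensus_plus <- intersect(persistent$persistent_plus, ct_corr)
  consensus_minus <- intersect(persistent$persistent_minus, ct_corr)
  genes <- rownames(selections[[1]]$table)
  prov <- data.frame(gene = genes, stringsAsFactors = FALSE, row.names = genes)
  for (i in seq_along(selections)) {
    tab <- selections[[i]]$table
    prov[[paste0("z_", ages[i])]] <- tab$z
    prov[[paste0("r_", ages[i])]] <- tab$r
    prov[[paste0("q_", ages[i])]] <- tab$q
  }
  prov$label <- "none"
  prov$label[genes %in% persistent$persistent_plus] <- "persistent_plus"
  prov$label[genes %in% persistent$persistent_minus] <- "persistent_minus"
  prov$label[genes %in% consensus_plus] <- "consensus_plus"
  prov$label[genes %in% consensus_minus] <- "consensus_minus"
  structure(list(persistent_plus = persistent$persistent_plus,
                 persistent_minus = persistent$persistent_minus,
                 ct_correlated = ct_corr,
                 consensus_plus = consensus_plus,
                 consensus_minus = consensus_minus,
                 provenance = prov),
            class = "ct_consensus")
}

#' @export
print.ct_consensus <- function(x, ...) {
  cat(sprintf("consensus CT-related PLS1 genes: %d (+%d / -%d)\n",
              length(x$consensus_plus) + length(x$consensus_minus),
              length(x$consensus_plus), length(x$consensus_minus)))
  cat(sprintf("  persistent: +%d / -%d; CT-correlated at every age: %d\n",
              length(x$persistent_plus), length(x$persistent_minus),
              length(x$ct_correlated)))
  invisible(x)
}

#' Per-region linear model of CT on age
#'
#' Fits ordinary least squares `CT ~ age` separately for each region and
#' returns the intercepts and slopes as two alternative response vectors for
#' [fit_pls1()] -- the intercept captures regional CT differences, the slope
#' the regional variation in the ageing effect.
#'
#' @param ct_animal Matrix of CT values, regions x animals.
#' @param animal_ages Numeric ages aligned with the animal columns.
#' @return List with named vectors `intercept` and `slope` (mm and mm/yr).
#' @export
age_model_inputs <- function(ct_animal, animal_ages) {
  if (!is.matrix(ct_animal) || is.null(rownames(ct_animal)))
    stop("`ct_animal` must be a matrix with region row names", call. = FALSE)
  if (length(animal_ages) != ncol(ct_animal))
    stop("one age per animal column is required", call. = FALSE)
  if (ncol(ct_animal) < 2L) stop("need at least 2 animals", call. = FALSE)
  if (length(unique(animal_ages)) < 2L)
    stop("need at least 2 distinct ages", call. = FALSE)
  fit <- lm.fit(cbind(intercept = 1, age = animal_ages), t(ct_animal))
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))  # single region: lm.fit returns a plain vector
    coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs), NULL))
  list(intercept = setNames(coefs["intercept", ], rownames(ct_animal)),
       slope = setNames(coefs["age", ], rownames(ct_animal)))
}

#' Run the per-age PLS stage over a CT table
#'
#' Convenience driver: for each age column of `ct_table`, fits PLS1, runs the
#' permutation test and bootstrap, and selects genes; then intersects across
#' ages and assembles the consensus.
#'
#' @inheritParams fit_pls1
#' @param ct_table Regions x ages CT matrix (e.g. from [build_ct_table()] or
#'   [generate_atlas()]).
#' @param n_perm,n_boot Resampling sizes.
#' @param z_thresh,r_thresh,alpha Selection thresholds.
#' @param seed Root seed; per-age streams are derived from it.
#' @return List with `fits`, `permutations`, `bootstraps`, `selections` (per
#'   age) and `consensus` (a `"ct_consensus"`).
#' @export
pls_consensus_pipeline <- function(expr, ct_table, n_perm = 1000,
                                   n_boot = 1000, z_thresh = 3,
                                   r_thresh = 0.3, alpha = 0.05, seed = 1L,
                                   standardize = TRUE) {
  if (!is.matrix(ct_table) || is.null(colnames(ct_table)))
    stop("`ct_table` must be a regions x ages matrix with age column names",
         call. = FALSE)
  ages <- colnames(ct_table)
  set.seed(as.integer(seed))
  age_seeds <- sample.int(.Machine$integer.max - 1L, 2L * length(ages))
  fits <- list(); perms <- list(); boots <- list(); sels <- list()
  ex <- if (is.list(expr) && !is.matrix(expr)) expr else NULL
  for (i in seq_along(ages)) {
    age <- ages[i]
    Xa <- if (is.null(ex)) expr else ex[[age]]
    y <- ct_table[, age]
    fits[[age]] <- fit_pls1(Xa, y, standardize = standardize)
    perms[[age]] <- pls1_permutation(Xa, y, n_perm = n_perm,
                                     seed = age_seeds[2L * i - 1L],
                                     standardize = standardize)
    boots[[age]] <- pls1_bootstrap(Xa, y, n_boot = n_boot,
                                   seed = age_seeds[2L * i],
                                   standardize = standardize)
    sels[[age]] <- select_age_genes(fits[[age]], boots[[age]], Xa, y,
                                    z_thresh = z_thresh, r_thresh = r_thresh,
                                    alpha = alpha)
  }
  persistent <- persistence_intersection(sels)
  cons <- consensus_genes(persistent, sels)
  list(fits = fits, permutations = perms, bootstraps = boots,
       selections = sels, consensus = cons)
}
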