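# Synthetic regional atlas, QC table and marker-set generators with planted
# ground truth.  These define the study conditions under which the pipeline
# is validated: a shared expression matrix regressed against age-varying CT,
# as in a single adult atlas analysed across age groups.

#' Configuration for the synthetic atlas generator
#'
#' Region-level expression is generated on a log-like continuous scale
#' (Gaussian around a per-gene baseline, clamped at zero), since the pipeline
#' operates on post-normalisation values.  Regional cortical thickness (CT)
#' follows a shared regional profile plus age-specific deviations:
#' `CT(r, a) = ct_mean_mm + ct_age_slope * (age - mean age) +
#' ct_sd_mm * (sqrt(age_cor) * z_r + sqrt(1 - age_cor) * e_{r,a})`,
#' so that any two ages correlate `age_cor` across regions.
#'
#' A planted persistent gene tracks the shared profile `z_r` with coefficient
#' `a = effect_r * noise_sd / sqrt(age_cor - effect_r^2)`, which makes its
#' expected Pearson correlation with CT equal `effect_r` at every age (the
#' familiar calibration `a = effect_r * noise_sd / (ct_sd * sqrt(1 -
#' effect_r^2))` against a single response is the `age_cor = 1` special case
#' of this, with the response expressed in units of its s.d.).  This requires
#' `effect_r^2 < age_cor`: with a single shared expression vector, the
#' attainable per-age correlation is capped by how strongly the per-age CT
#' vectors share the regional profile.
#'
#' Transient genes are associated with CT at only a strict subset of ages
#' (default: all but one, the hardest case for the persistence filter).  Each
#' is built as a linear combination of the realised standardised CT vectors
#' solving for in-sample covariance `transient_r` with every active age and 0
#' with the inactive age, plus Gaussian noise filling the variance to 1; the
#' construction errors if the requested correlations are geometrically
#' infeasible for the given `age_cor`.
#'
#' @param n_regions,n_genes Atlas dimensions.
#' @param n_ages Number of age groups, labelled `ages` (years).
#' @param ages Age labels; defaults to `2:(n_ages + 1)` i.e. 2..8 years for 7.
#' @param n_plus,n_minus Planted genes with positive / negative CT association
#'   at every age.
#' @param n_transient Planted genes associated only at their active ages.
#' @param effect_r Target absolute per-age Pearson correlation of persistent
#'   planted genes with CT; must satisfy `0 <= effect_r` and
#'   `effect_r^2 < age_cor`.
#' @param transient_r Target per-active-age correlation of transient genes.
#' @param noise_sd Residual expression s.d. (log-scale units).
#' @param baseline_mean,baseline_sd Per-gene baseline expression distribution.
#' @param ct_mean_mm,ct_sd_mm Mean and between-region s.d. of CT in mm.
#' @param ct_age_slope Mean CT change per year (mm/yr), a mild thinning trend.
#' @param age_cor Between-age correlation of regional CT profiles.
#' @param marker_overlap_frac Default overlap fraction handed to
#'   [generate_marker_sets()].
#' @param seed Root RNG seed; fixes all outputs bit-for-bit.
#' @return A validated list of class `"atlas_config"`.
#' @export
atlas_config <- function(n_regions = 97, n_genes = 2000, n_ages = 7,
                         ages = seq(2, length.out = n_ages),
                         n_plus = 50, n_minus = 40, n_transient = 10,
                         effect_r = 0.6, transient_r = 0.4,
                         noise_sd = 1, baseline_mean = 6, baseline_sd = 1.5,
                         ct_mean_mm = 2.2, ct_sd_mm = 0.25,
                         ct_age_slope = -0.02, age_cor = 0.7,
                         marker_overlap_frac = 0.4, seed = 1L) {
  cfg <- list(n_regions = n_regions, n_genes = n_genes, n_ages = n_ages,
              ages = ages, n_plus = n_plus, n_minus = n_minus,
              n_transient = n_transient, effect_r = effect_r,
              transient_r = transient_r, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              ct_mean_mm = ct_mean_mm, ct_sd_mm = ct_sd_mm,
              ct_age_slope = ct_age_slope, age_cor = age_cor,
              marker_overlap_frac = marker_overlap_frac,
              seed = as.integer(seed))
  counts <- c("n_regions", "n_genes", "n_ages", "n_plus", "n_minus",
              "n_transient")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 0 ||
        cfg[[nm]] != round(cfg[[nm]]))
      stop(sprintf("`%s` must be a nonnegative integer", nm), call. = FALSE)
  if (n_regions < 1 || n_genes < 1)
    stop("`n_regions` and `n_genes` must be positive", call. = FALSE)
  if (n_plus + n_minus + n_transient > n_genes)
    stop("planted gene counts exceed `n_genes`", call. = FALSE)
  if (length(ages) != n_ages) stop("`ages` must have length `n_ages`", call. = FALSE)
  .check_fraction(age_cor, "age_cor", lo = 1e-8, hi = 1)
  .check_fraction(marker_overlap_frac, "marker_overlap_frac")
  if (effect_r < 0 || effect_r >= 1 || effect_r^2 >= age_cor)
    stop("`effect_r` must satisfy 0 <= effect_r < 1 and effect_r^2 < age_cor",
         call. = FALSE)
  if (transient_r < 0 || transient_r >= 1)
    stop("`transient_r` must be in [0, 1)", call. = FALSE)
  if (noise_sd <= 0 || ct_sd_mm <= 0 || ct_mean_mm <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  structure(cfg, class = "atlas_config")
}

# deterministic component sub-seeds spawned from the root seed, so individual
# components can be regenerated without touching the others' streams
.component_seeds <- function(seed) {
  set.seed(as.integer(seed))
  setNames(sample.int(.Machine$integer.max - 1L, 4L),
           c("ct", "expression", "qc", "markers"))
}

#' Generate a synthetic regional expression atlas with planted CT genes
#'
#' Produces one shared region-level expression matrix (genes x regions), a CT
#' table (regions x ages), and the planted truth: persistent positive and
#' negative CT-associated genes and transient genes with their active-age
#' subsets, all pairwise disjoint.  With `shared = FALSE`, an independent
#' noise realisation of the expression matrix is drawn per age (for stress
#' tests); the planted signal structure is identical.
#'
#' @param config An [atlas_config()].
#' @param shared Single shared expression matrix (default) or one per age.
#' @return A list of class `"ct_atlas"` with elements `expr` (matrix, or list
#'   of matrices when `shared = FALSE`), `ct` (regions x ages matrix, mm),
#'   `truth` (list: `plus_genes`, `minus_genes`, `transient_genes` with
#'   active ages), and `config`.
#' @examples
#' atl <- generate_atlas(atlas_config(n_genes = 100, seed = 7))
#' str(atl$truth$plus_genes)
#' @export
generate_atlas <- function(config = atlas_config(), shared = TRUE) {
  if (!inherits(config, "atlas_config")) config <- do.call(atlas_config, config)
  R <- config$n_regions; G <- config$n_genes; A <- config$n_ages
  regions <- sprintf("R%03d", seq_len(R))
  genes <- sprintf("g%04d", seq_len(G))
  age_labels <- as.character(config$ages)
  seeds <- .component_seeds(config$seed)

  # CT: shared regional profile + per-age deviations.  The profile is
  # standardised in-sample and each age's deviation is orthogonalised
  # against it, so the realised profile-CT correlation is sqrt(age_cor)
  # exactly for every age and seed -- planted-gene calibration then
  # fluctuates only through per-gene noise, not through a shared
  # profile-level accident.
  set.seed(seeds[["ct"]])
  z <- as.vector(scale(rnorm(R)))
  E <- matrix(rnorm(R * A), R, A)
  E <- apply(E, 2L, function(e) {
    e <- e - mean(e) - z * sum(e * z) / sum(z * z)
    as.vector(scale(e))
  })
  age_centered <- config$ages - mean(config$ages)
  ct <- config$ct_mean_mm +
    outer(rep(1, R), age_centered) * config$ct_age_slope +
    config$ct_sd_mm * (sqrt(config$age_cor) * z +
                       sqrt(1 - config$age_cor) * E)
  dimnames(ct) <- list(regions, age_labels)

  n_pl <- config$n_plus; n_mi <- config$n_minus; n_tr <- config$n_transient
  plus_idx <- seq_len(n_pl)
  minus_idx <- seq_len(n_mi) + n_pl
  trans_idx <- seq_len(n_tr) + n_pl + n_mi

  # per-age-exact calibration: cor(x, CT_age) has expectation effect_r when
  # x tracks the shared profile with this coefficient
  a_coef <- if (config$effect_r == 0) 0 else
    config$effect_r * config$noise_sd /
      sqrt(config$age_cor - config$effect_r^2)

  # transient signal directions from the realised CT table
  ct_std <- scale(ct)
  inactive_age <- if (n_tr > 0) ((seq_len(n_tr) - 1L) %% A) + 1L else integer(0)
  gram <- cor(ct_std)
  trans_sig <- matrix(0, R, n_tr)
  trans_noise_sd <- numeric(n_tr)
  for (j in seq_len(n_tr)) {
    rho <- rep(config$transient_r, A)
    rho[inactive_age[j]] <- 0
    beta <- solve(gram, rho)
    s2 <- sum(beta * (gram %*% beta))
    if (s2 >= 1)
      stop("transient construction infeasible: requested per-age ",
           "correlations need more than unit variance; lower `transient_r` ",
           "or `age_cor`", call. = FALSE)
    trans_sig[, j] <- ct_std %*% beta
    trans_noise_sd[j] <- sqrt(1 - s2)
  }

  set.seed(seeds[["expression"]])
  baseline <- rnorm(G, config$baseline_mean, config$baseline_sd)
  draw_expr <- function() {
    eps <- matrix(rnorm(G * R, sd = config$noise_sd), G, R)
    X <- baseline + eps
    if (n_pl > 0) X[plus_idx, ] <- X[plus_idx, ] + rep(a_coef * z, each = n_pl)
    if (n_mi > 0) X[minus_idx, ] <- X[minus_idx, ] - rep(a_coef * z, each = n_mi)
    for (j in seq_len(n_tr)) {
      g <- trans_idx[j]
      X[g, ] <- baseline[g] + config$noise_sd *
        (trans_sig[, j] + trans_noise_sd[j] * rnorm(R))
    }
    X <- pmax(X, 0)  # expression is nonnegative on this scale; truncation is rare
    dimnames(X) <- list(genes, regions)
    X
  }
  expr <- if (shared) draw_expr() else
    setNames(lapply(seq_len(A), function(i) draw_expr()), age_labels)

  transient <- if (n_tr > 0) {
    lapply(seq_len(n_tr), function(j)
      list(gene = genes[trans_idx[j]],
           active_ages = age_labels[-inactive_age[j]]))
  } else list()
  names(transient) <- genes[trans_idx]

  truth <- list(plus_genes = genes[plus_idx],
                minus_genes = genes[minus_idx],
                transient_genes = transient)
  structure(list(expr = expr, ct = ct, truth = truth, config = config),
            class = "ct_atlas")
}

#' Generate a sample-level QC metric table with planted outliers
#'
#' Emulates per-sample RNA-seq quality metrics (percent uniquely mapped reads,
#' percent high-quality aligned reads, percent mRNA bases, percent intergenic
#' bases, median 5'-to-3' coverage bias, GC and AT dropout rates).  Exactly
#' `n_outliers` samples are constructed to violate three of the directional QC
#' rules applied by [qc_remove_samples()] (the absolute unique-mapping rule
#' plus two z-score rules), so they must be removed; all other samples violate
#' none.  The two z-score violations of successive outliers rotate round-robin
#' over the six z-scored metrics so that no metric's mean and s.d. are
#' dragged far enough to mask the planted outliers; this detection guarantee
#' needs `n_outliers <= floor(n_samples / 3)` and the generator refuses larger
#' requests (in particular the degenerate all-outlier case, where z scores
#' cannot separate anything).
#'
#' @param n_samples Number of samples (>= 3).
#' @param n_outliers Number of planted outlier samples.
#' @param seed RNG seed.
#' @return A `data.frame` with `sample_id`, `region_id`, the seven metric
#'   columns, and an attribute `"outlier_ids"` naming the planted outliers.
#' @export
generate_qc_table <- function(n_samples, n_outliers = 0, seed = 1L) {
  if (n_samples < 3L) stop("need at least 3 samples", call. = FALSE)
  if (n_outliers > n_samples)
    stop("`n_outliers` cannot exceed `n_samples`", call. = FALSE)
  if (n_outliers > floor(n_samples / 3))
    stop("`n_outliers` must be at most floor(n_samples / 3): with more ",
         "planted outliers the pooled z scores can no longer separate them",
         call. = FALSE)
  set.seed(as.integer(seed))
  # clean samples are drawn from a bounded (uniform) spread so that no clean
  # sample can reach the |z| > 2 region on its own; planted outliers sit 20
  # spreads away on their violated metrics
  runifb <- function(n, mu, s) runif(n, mu - 1.5 * s, mu + 1.5 * s)
  base <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    region_id = sprintf("R%03d", ((seq_len(n_samples) - 1L) %% 10L) + 1L),
    pct_unique_mapping   = runifb(n_samples, 85, 2),
    pct_hq_aligned       = runifb(n_samples, 95, 1),
    pct_mrna_bases       = runifb(n_samples, 40, 3),
    pct_intergenic_bases = runifb(n_samples, 10, 1.5),
    median_5to3_bias     = runifb(n_samples, 0.9, 0.04),
    gc_dropout           = runifb(n_samples, 2, 0.4),
    at_dropout           = runifb(n_samples, 1, 0.3),
    stringsAsFactors = FALSE
  )
  # directional z-metrics in a fixed rotation order: (column, violation sign)
  zmetrics <- list(c("pct_intergenic_bases", 1), c("gc_dropout", 1),
                   c("at_dropout", 1), c("pct_hq_aligned", -1),
                   c("pct_mrna_bases", -1), c("median_5to3_bias", -1))
  spread <- c(pct_hq_aligned = 1, pct_mrna_bases = 3,
              pct_intergenic_bases = 1.5, median_5to3_bias = 0.04,
              gc_dropout = 0.4, at_dropout = 0.3)
  outlier_rows <- if (n_outliers > 0) sample(n_samples, n_outliers) else integer(0)
  for (j in seq_along(outlier_rows)) {
    i <- outlier_rows[j]
    base$pct_unique_mapping[i] <- runif(1, 44, 49)  # absolute rule: < 50
    picks <- ((2L * (j - 1L) + 0:1) %% 6L) + 1L
    for (pk in picks) {
      col <- zmetrics[[pk]][1]
      dir <- as.numeric(zmetrics[[pk]][2])
      base[[col]][i] <- base[[col]][i] + dir * 20 * spread[[col]]
    }
  }
  base$pct_hq_aligned <- pmin(100, pmax(0, base$pct_hq_aligned))
  base$pct_mrna_bases <- pmin(100, pmax(0, base$pct_mrna_bases))
  base$pct_intergenic_bases <- pmin(100, pmax(0, base$pct_intergenic_bases))
  base$median_5to3_bias <- pmax(0.01, base$median_5to3_bias)
  base$gc_dropout <- pmax(0, base$gc_dropout)
  base$at_dropout <- pmax(0, base$at_dropout)
  attr(base, "outlier_ids") <- base$sample_id[sort(outlier_rows)]
  base
}

#' Generate marker gene sets with planted enrichment
#'
#' Builds named gene sets in which a fraction `overlap_frac` of each set's
#' members is drawn from a designated planted gene list (alternating between
#' the planted positive and negative lists across sets, mimicking cell types
#' whose markers sit in one tail of the PLS weights) and the rest uniformly
#' from non-planted universe genes.  The realised 2x2 table of each set
#' against its designated planted list, and the corresponding sample odds
#' ratio, are recorded so enrichment recovery can be checked in closed form.
#'
#' @param truth The `truth` element of a [generate_atlas()] result.
#' @param universe Character vector of all gene ids.
#' @param set_sizes Named integer vector of set sizes (names become set names).
#' @param overlap_frac Fraction of each set drawn from its planted list.
#' @param seed RNG seed.
#' @return A list of class `"gene_set_collection"` with `sets` (named list of
#'   gene-id vectors), `universe`, and `planted` (per-set: designated list,
#'   realised table, sample OR).
#' @export
generate_marker_sets <- function(truth, universe,
                                 set_sizes = c(ExcNeuron = 80, InhNeuron = 80,
                                               Oligo = 80, Micro = 60,
                                               Astro = 60, OPC = 50),
                                 overlap_frac = 0.4, seed = 1L) {
  .check_fraction(overlap_frac, "overlap_frac")
  if (is.null(names(set_sizes)) || any(names(set_sizes) == ""))
    stop("`set_sizes` must be a named vector", call. = FALSE)
  if (any(set_sizes > length(universe)))
    stop("set sizes cannot exceed the universe", call. = FALSE)
  planted_all <- c(truth$plus_genes, truth$minus_genes)
  nonplanted <- setdiff(universe, c(planted_all, names(truth$transient_genes)))
  set.seed(as.integer(seed))
  sets <- list(); planted <- list()
  for (i in seq_along(set_sizes)) {
    nm <- names(set_sizes)[i]
    size <- set_sizes[[i]]
    target_name <- if (i %% 2L == 1L) "plus" else "minus"
    target <- if (target_name == "plus") truth$plus_genes else truth$minus_genes
    n_in <- min(round(overlap_frac * size), length(target), size)
    members <- c(sample(target, n_in),
                 sample(nonplanted, size - n_in))
    sets[[nm]] <- sort(members)
    a <- length(intersect(members, target))
    b <- length(target) - a
    c_ <- size - a
    d <- length(universe) - a - b - c_
    planted[[nm]] <- list(target = target_name,
                          table = c(a = as.integer(a), b = as.integer(b),
                                    c = as.integer(c_), d = as.integer(d)),
                          or_sample = if (b * c_ == 0) Inf else a * d / (b * c_))
  }
  structure(list(sets = sets, universe = universe, planted = planted),
            class = "gene_set_collection")
}

#' Expand a region-level atlas into sample-level expression
#'
#' Draws `n_per_region` samples around each regional profile with additional
#' sample-level Gaussian noise, returning the sample-axis matrix and the
#' sample-to-region map consumed by [aggregate_regions()].
#'
#' @param atlas A [generate_atlas()] result (with a shared matrix).
#' @param n_per_region Samples per region.
#' @param sample_sd Sample-level noise s.d.
#' @param seed RNG seed.
#' @return List with `expr` (genes x samples) and `map` (`data.frame` of
#'   `sample_id`, `region_id`).
#' @export
simulate_samples <- function(atlas, n_per_region = 2, sample_sd = 0.5, seed = 1L) {
  stopifnot(inherits(atlas, "ct_atlas"), is.matrix(atlas$expr))
  set.seed(as.integer(seed))
  regions <- colnames(atlas$expr)
  G <- nrow(atlas$expr)
  cols <- rep(regions, each = n_per_region)
  expr <- atlas$expr[, cols, drop = FALSE] +
    matrix(rnorm(G * length(cols), sd = sample_sd), G)
  expr <- pmax(expr, 0)
  ids <- sprintf("%s_s%02d", cols, rep(seq_len(n_per_region), times = length(regions)))
  colnames(expr) <- ids
  list(expr = expr,
       map = data.frame(sample_id = ids, region_id = cols,
                        stringsAsFactors = FALSE))
}
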