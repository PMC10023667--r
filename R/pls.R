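# Single-component PLS of regional cortical thickness on gene expression,
# with permutation significance and bootstrap Z-scores of gene weights.
#
# For one response and one component the PLS weight vector has the closed
# form w = X'y / ||X'y|| on the standardised predictors, which is what makes
# the heavy resampling below cheap: only cross-products are required.

# standardise regions x genes matrix: columns to mean 0 / sd 1 (sample sd);
# constant columns become all-zero (they carry no weight)
.standardize_cols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt((colSums(X^2) - nrow(X) * mu^2) / (nrow(X) - 1))
  s_safe <- ifelse(s > 0, s, 1)
  Xs <- sweep(sweep(X, 2L, mu), 2L, s_safe, "/")
  Xs[, s == 0] <- 0
  attr(Xs, "sd_zero") <- s == 0
  Xs
}

.align_expr_ct <- function(expr, ct) {
  .check_expr_matrix(expr)
  if (is.null(names(ct)))
    stop("`ct` must be a named vector over regions", call. = FALSE)
  if (!setequal(names(ct), colnames(expr)))
    stop("region ids of `expr` and `ct` do not match", call. = FALSE)
  ct[colnames(expr)]
}

#' Fit the first PLS component of CT on regional expression
#'
#' Gene columns are standardised (mean 0, s.d. 1; constant genes get weight
#' 0) and the response centred; the first-component weight vector is the
#' normalised expression-CT cross-covariance, `w = X'y / ||X'y||`, the
#' scores are `t = Xw`, and the component sign is fixed so that
#' `cor(t, y) >= 0`.  Explained variance is the squared Pearson correlation
#' between the scores and the response (the fraction of response variance
#' captured); the fraction of predictor variance carried by the component is
#' reported alongside as `explained_var_x`.  Loadings are the correlations
#' between each gene and the scores (the shared variance between gene and
#' component).
#'
#' @param expr Region-axis expression matrix (genes x regions).
#' @param ct Named numeric vector of mean CT (mm) over the same regions.
#' @param standardize Standardise gene columns first (default `TRUE`).
#' @return Object of class `"pls1_fit"`: `weights` (unit norm, named by
#'   gene), `scores` (named by region), `loadings`, `explained_var`,
#'   `explained_var_x`, `y` (aligned response).
#' @examples
#' atl <- generate_atlas(atlas_config(n_genes = 60, n_plus = 5, n_minus = 5,
#'                                    n_transient = 0, seed = 3))
#' fit <- fit_pls1(atl$expr, atl$ct[, "2"])
#' fit$explained_var
#' @export
fit_pls1 <- function(expr, ct, standardize = TRUE) {
  y <- .align_expr_ct(expr, ct)
  X <- t(expr)
  if (nrow(X) < 3L) stop("need at least 3 regions", call. = FALSE)
  if (sd(y) == 0) stop("constant response", call. = FALSE)
  Xs <- if (standardize) .standardize_cols(X) else
    sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  w_raw <- as.vector(crossprod(Xs, yc))
  nrm <- sqrt(sum(w_raw^2))
  if (nrm < 1e-12)
    stop("degenerate fit: response has zero cross-covariance with every gene",
         call. = FALSE)
  w <- w_raw / nrm
  t_scores <- as.vector(Xs %*% w)
  if (cor(t_scores, y) < 0) { w <- -w; t_scores <- -t_scores }
  loadings <- .cor_cols(Xs, t_scores)
  loadings[is.na(loadings)] <- 0
  # predictor variance captured by the component via its loading projection
  ss_tot <- sum(Xs^2)
  proj <- as.vector(crossprod(Xs, t_scores)) / sum(t_scores^2)
  ev_x <- sum(t_scores^2) * sum(proj^2) / ss_tot
  structure(list(weights = setNames(w, colnames(Xs)),
                 scores = setNames(t_scores, rownames(X)),
                 loadings = setNames(loadings, colnames(Xs)),
                 explained_var = cor(t_scores, y)^2,
                 explained_var_x = ev_x,
                 y = y, standardize = standardize),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d genes, %d regions\n", length(x$weights),
              length(x$scores)))
  cat(sprintf("  explained CT variance (cor^2): %.3f\n", x$explained_var))
  cat(sprintf("  predictor variance captured:   %.3f\n", x$explained_var_x))
  invisible(x)
}

#' Permutation test of the PLS1 explained variance
#'
#' Shuffles the response over regions `n_perm` times, refits PLS1 (via the
#' closed form, so only the response changes) and records the explained
#' variance.  The p value uses the add-one estimator
#' `(1 + #[perm >= observed]) / (1 + n_perm)`, which never returns 0.
#'
#' @inheritParams fit_pls1
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return List with `perm_p`, `observed` (explained variance) and
#'   `perm_stats`.
#' @export
pls1_permutation <- function(expr, ct, n_perm = 10000, seed = NULL,
                             standardize = TRUE) {
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)
  y <- .align_expr_ct(expr, ct)
  fit <- fit_pls1(expr, ct, standardize = standardize)
  X <- t(expr)
  Xs <- if (standardize) .standardize_cols(X) else sweep(X, 2L, colMeans(X))
  K <- tcrossprod(Xs)  # regions x regions; scores of a refit are K y up to scale
  n <- length(y)
  if (!is.null(seed)) set.seed(as.integer(seed))
  perm <- matrix(0, n, n_perm)
  for (i in seq_len(n_perm)) perm[, i] <- y[sample.int(n)]
  Tm <- K %*% perm
  # squared correlation column-by-column, vectorised
  Tc <- sweep(Tm, 2L, colMeans(Tm))
  Pc <- sweep(perm, 2L, colMeans(perm))
  num <- colSums(Tc * Pc)
  den <- sqrt(colSums(Tc^2) * colSums(Pc^2))
  stats <- ifelse(den > 0, (num / den)^2, 0)
  p <- (1 + sum(stats >= fit$explained_var)) / (1 + n_perm)
  list(perm_p = p, observed = fit$explained_var, perm_stats = stats)
}

#' Bootstrap Z-scores of PLS1 gene weights
#'
#' Resamples regions with replacement, refits the PLS1 weight vector on each
#' replicate, and aligns the replicate's sign to the original fit (flipping
#' when its dot product with the original weights is negative) before
#' accumulation -- PLS components have arbitrary sign, and without alignment
#' the standard errors are inflated and the Z-scores collapse.  Each gene's
#' standard error is the s.d. of its aligned replicate weights, and
#' `z = w / se`.  Replicates with a degenerate fit (constant resampled
#' response, or zero cross-covariance) are discarded and counted; more than
#' 50% degenerate replicates is an error.  A gene with `se = 0` and nonzero
#' weight gets a signed-infinity Z (always selected by thresholding); with
#' zero weight it gets Z = 0.
#'
#' @inheritParams fit_pls1
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return Object of class `"pls_bootstrap"`: `weights`, `se`, `z` (named by
#'   gene), `n_boot`, `n_kept`, `n_degenerate`.
#' @export
pls1_bootstrap <- function(expr, ct, n_boot = 1000, seed = NULL,
                           standardize = TRUE) {
  if (n_boot < 2) stop("`n_boot` must be at least 2", call. = FALSE)
  y <- .align_expr_ct(expr, ct)
  fit <- fit_pls1(expr, ct, standardize = standardize)
  X <- t(expr)
  X2 <- X^2
  n <- nrow(X)
  w0 <- fit$weights
  if (!is.null(seed)) set.seed(as.integer(seed))
  sum_w <- numeric(length(w0))
  sum_w2 <- numeric(length(w0))
  kept <- 0L
  degenerate <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    cnt <- tabulate(idx, nbins = n)
    yb <- y[idx]
    ybar <- mean(yb)
    if (sd(yb) == 0) { degenerate <- degenerate + 1L; next }
    # column sums over the resampled rows via the count weights
    s1 <- as.vector(crossprod(X, cnt))            # sum x
    s2 <- as.vector(crossprod(X2, cnt))           # sum x^2
    sxy <- as.vector(crossprod(X, cnt * y))       # sum x y (resampled)
    mu <- s1 / n
    ssd <- sqrt(pmax(0, (s2 - n * mu^2) / (n - 1)))
    cross <- sxy - ybar * s1                      # sum x (y - ybar)
    wb <- if (standardize) ifelse(ssd > 0, cross / ssd, 0) else cross
    nrm <- sqrt(sum(wb^2))
    if (nrm < 1e-12) { degenerate <- degenerate + 1L; next }
    wb <- wb / nrm
    if (sum(wb * w0) < 0) wb <- -wb
    sum_w <- sum_w + wb
    sum_w2 <- sum_w2 + wb^2
    kept <- kept + 1L
  }
  if (kept < n_boot / 2)
    stop(sprintf("bootstrap failed: %d of %d replicates degenerate",
                 degenerate, n_boot), call. = FALSE)
  mu_b <- sum_w / kept
  se <- sqrt(pmax(0, (sum_w2 - kept * mu_b^2) / (kept - 1)))
  z <- ifelse(se > 0, w0 / se, ifelse(w0 == 0, 0, sign(w0) * Inf))
  structure(list(weights = w0, se = setNames(se, names(w0)),
                 z = setNames(z, names(w0)), n_boot = as.integer(n_boot),
                 n_kept = kept, n_degenerate = degenerate),
            class = "pls_bootstrap")
}
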