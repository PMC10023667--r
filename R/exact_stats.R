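# Exact 2x2 and correlation statistics shared by the selection and
# enrichment stages.

#' Two-sided Fisher's exact test with conditional-MLE odds ratio
#'
#' Computes, for a 2x2 contingency table, the two-sided exact p value
#' (probability-ordering definition: the sum of hypergeometric masses of all
#' tables with the same margins whose probability does not exceed that of the
#' observed table), the conditional maximum-likelihood estimate of the odds
#' ratio under the noncentral hypergeometric model with fixed margins, and the
#' exact conditional confidence interval obtained by inverting the one-sided
#' tail tests.
#'
#' Cell layout follows the enrichment convention: `a` = in-list and in-set,
#' `b` = in-list only, `c` = in-set only, `d` = neither.
#'
#' Conventions at the boundary of the conditional support: when the observed
#' `a` sits at the minimum of the support (which includes every table with
#' `a = 0`) the odds ratio is 0; at the maximum (e.g. `b = 0` or `c = 0` with
#' `a > 0`) it is `Inf`; when the support is a single point (a zero margin)
#' the p value is 1 and the odds ratio is undefined (`NaN`).  Probability ties
#' in the two-sided sum are resolved with a relative tolerance of `1e-7`,
#' since floating-point equality of hypergeometric masses is not exact.
#'
#' @param a,b,c,d Nonnegative integer cell counts, or `a` may be a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))` with `b`, `c`, `d` missing.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return A list with elements `p` (two-sided p value), `or` (conditional-MLE
#'   odds ratio), `ci` (length-2 confidence bounds), `or_sample` (the sample
#'   cross-product estimate `ad/bc`), and `table` (the counts used).
#' @examples
#' fisher_exact(2, 0, 0, 2)$p   # 1/3
#' fisher_exact(5, 5, 5, 5)$or  # 1
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L)))
      stop("matrix input must be 2x2", call. = FALSE)
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)

  # hypergeometric parametrisation: x = a, white = a + c, black = b + d,
  # drawn = a + b
  m <- a + c
  n <- b + d
  k <- a + b
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dc <- dhyper(support, m, n, k)

  rel_tol <- 1e-7
  p_obs <- dc[support == a]
  p <- min(1, sum(dc[dc <= p_obs * (1 + rel_tol)]))

  logdc <- dhyper(support, m, n, k, log = TRUE)
  dnhyper <- function(psi) {
    w <- logdc + support * log(psi)
    w <- exp(w - max(w))
    w / sum(w)
  }
  mnhyper <- function(psi) {
    if (psi == 0) return(lo)
    if (!is.finite(psi)) return(hi)
    sum(support * dnhyper(psi))
  }
  pnhyper <- function(q, psi, upper = FALSE) {
    dn <- dnhyper(psi)
    if (upper) sum(dn[support >= q]) else sum(dn[support <= q])
  }

  or <- if (lo == hi) {
    NaN
  } else if (a == lo) {
    0
  } else if (a == hi) {
    Inf
  } else {
    mu1 <- mnhyper(1)
    if (mu1 == a) 1
    else if (mu1 > a)
      uniroot(function(t) mnhyper(t) - a, c(.Machine$double.eps, 1), tol = 1e-12)$root
    else
      1 / uniroot(function(t) mnhyper(1 / t) - a,
                  c(.Machine$double.eps, 1), tol = 1e-12)$root
  }

  alpha2 <- (1 - conf_level) / 2
  ci_lower <- if (a == lo) 0 else {
    if (pnhyper(a, 1, upper = TRUE) > alpha2)
      uniroot(function(t) pnhyper(a, t, upper = TRUE) - alpha2,
              c(.Machine$double.eps, 1), tol = 1e-12)$root
    else
      1 / uniroot(function(t) pnhyper(a, 1 / t, upper = TRUE) - alpha2,
                  c(.Machine$double.eps, 1), tol = 1e-12)$root
  }
  ci_upper <- if (a == hi) Inf else {
    if (pnhyper(a, 1) < alpha2)
      uniroot(function(t) pnhyper(a, t) - alpha2,
              c(.Machine$double.eps, 1), tol = 1e-12)$root
    else
      1 / uniroot(function(t) pnhyper(a, 1 / t) - alpha2,
                  c(.Machine$double.eps, 1), tol = 1e-12)$root
  }
  if (lo == hi) { ci_lower <- 0; ci_upper <- Inf }

  or_sample <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)

  list(p = p, or = or, ci = c(ci_lower, ci_upper), or_sample = or_sample,
       table = c(a = a, b = b, c = c, d = d))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validating front end to
#' [stats::p.adjust()] so that malformed p values fail loudly rather than
#' propagating.
#'
#' @param p Numeric vector of p values in `[0, 1]` (`NA` not allowed).
#' @return Adjusted q values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must be finite numbers in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson correlation and the two-sided p value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return A list with `r` and `p`.
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input", call. = FALSE)
  r <- cor(x, y)
  list(r = r, p = .r_to_p(r, n))
}

# two-sided p for Pearson r on n observations (vectorised over r)
.r_to_p <- function(r, n) {
  df <- n - 2
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  t_stat <- r[!exact] * sqrt(df / (1 - r[!exact]^2))
  p[!exact] <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  p
}

# correlation of each column of X (matrix, observations in rows) with y
.cor_cols <- function(X, y) {
  n <- nrow(X)
  yc <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  denom <- sqrt(colSums(Xc^2) * sum(yc^2))
  r <- as.vector(crossprod(Xc, yc)) / denom
  r[denom == 0] <- NA_real_
  r
}
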