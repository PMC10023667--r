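# Independent oracles used to validate the package's own implementations.
# Each deliberately takes a different computational route from the code it
# checks.

# First PLS component by the iterative NIPALS algorithm (power iteration on
# the cross-covariance), independent of the closed-form route in fit_pls1.
oracle_nipals_pls1 <- function(X, y, tol = 1e-12, max_iter = 500) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  Xs <- sweep(sweep(X, 2L, mu), 2L, ifelse(s > 0, s, 1), "/")
  Xs[, s == 0] <- 0
  Y <- matrix(y - mean(y), ncol = 1)
  u <- Y[, 1]
  w_old <- rep(0, ncol(Xs))
  for (i in seq_len(max_iter)) {
    w <- as.vector(crossprod(Xs, u))
    w <- w / sqrt(sum(w^2))
    t_vec <- as.vector(Xs %*% w)
    q <- sum(Y[, 1] * t_vec) / sum(t_vec^2)   # Y loading
    u <- Y[, 1] * q / q^2                      # updated Y score
    if (sqrt(sum((w - w_old)^2)) < tol) break
    w_old <- w
  }
  if (cor(t_vec, y) < 0) { w <- -w; t_vec <- -t_vec }
  list(weights = w, scores = t_vec)
}

# Exact hypergeometric probability of a 2x2 table via log-binomials.
.oracle_table_prob <- function(x, r1, r2, c1) {
  exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
}

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins, summing probabilities no larger than the observed one.
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- vapply(lo:hi, .oracle_table_prob, numeric(1), r1, r2, c1)
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Conditional-MLE odds ratio by golden-section maximisation of the
# conditional log-likelihood over log(psi).
oracle_fisher_or <- function(a, b, c, d, lo_log = -35, hi_log = 35,
                             tol = 1e-10) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  slo <- max(0, c1 - r2); shi <- min(c1, r1)
  if (slo == shi) return(NaN)
  if (a == slo) return(0)
  if (a == shi) return(Inf)
  support <- slo:shi
  logc <- lchoose(r1, support) + lchoose(r2, c1 - support)
  loglik <- function(lpsi) {
    terms <- logc + support * lpsi
    a * lpsi - (max(terms) + log(sum(exp(terms - max(terms)))))
  }
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi_log - gr * (hi_log - lo_log)
  x2 <- lo_log + gr * (hi_log - lo_log)
  f1 <- loglik(x1); f2 <- loglik(x2)
  while (hi_log - lo_log > tol) {
    if (f1 < f2) {
      lo_log <- x1; x1 <- x2; f1 <- f2
      x2 <- lo_log + gr * (hi_log - lo_log); f2 <- loglik(x2)
    } else {
      hi_log <- x2; x2 <- x1; f2 <- f1
      x1 <- hi_log - gr * (hi_log - lo_log); f1 <- loglik(x1)
    }
  }
  exp((lo_log + hi_log) / 2)
}

# Benjamini-Hochberg by the direct sorted step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# Textbook Pearson correlation and two-sided p via explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE))
}

# Random expression fixture: genes x regions matrix with names.
random_expr <- function(n_genes, n_regions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n_genes * n_regions, mean = 5),
         n_genes, n_regions,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("R%03d", seq_len(n_regions))))
}

# Random 2x2 table with total at most n_max (at least 1).
random_table <- function(n_max) {
  n <- sample.int(n_max, 1)
  cuts <- sort(sample.int(n + 3, 3))  # stars and bars over 4 cells
  counts <- diff(c(0, cuts, n + 4)) - 1
  stopifnot(sum(counts) == n, all(counts >= 0))
  counts
}
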