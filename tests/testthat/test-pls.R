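# small aligned fixture: y plus genes exactly orthogonal to it
orthogonal_fixture <- function(n_regions = 20, n_noise = 5, seed = 1) {
  set.seed(seed)
  y <- rnorm(n_regions)
  yc <- y - mean(y)
  noise <- replicate(n_noise, {
    e <- rnorm(n_regions)
    e - mean(e) - yc * sum(e * yc) / sum(yc^2)  # zero sample correlation
  })
  regions <- sprintf("R%03d", seq_len(n_regions))
  expr <- t(cbind(target = y, noise))
  rownames(expr) <- c("target", sprintf("noise%d", seq_len(n_noise)))
  colnames(expr) <- regions
  list(expr = expr, y = setNames(y, regions))
}

test_that("a gene equal to the response carries all the weight", {
  fx <- orthogonal_fixture()
  fit <- fit_pls1(fx$expr, fx$y)
  expect_equal(unname(fit$weights["target"]), 1, tolerance = 1e-12)
  expect_equal(unname(abs(fit$weights[-1])), rep(0, 5), tolerance = 1e-10)
  expect_equal(fit$explained_var, 1, tolerance = 1e-10)
  expect_gte(cor(fit$scores, fx$y), 0)
})

test_that("closed-form weights match an independent NIPALS implementation", {
  set.seed(31)
  for (i in 1:10) {
    R <- sample(10:40, 1); G <- sample(20:80, 1)
    expr <- random_expr(G, R)
    y <- setNames(rnorm(R), colnames(expr))
    fit <- fit_pls1(expr, y)
    orc <- oracle_nipals_pls1(t(expr), y)
    if (sum(orc$weights * fit$weights) < 0) orc$weights <- -orc$weights
    expect_equal(unname(fit$weights), orc$weights, tolerance = 1e-8)
    expect_equal(sum(fit$weights^2), 1, tolerance = 1e-10)
  }
})

test_that("degenerate and malformed PLS inputs error", {
  fx <- orthogonal_fixture()
  # response orthogonal to every gene: zero cross-covariance
  expect_error(fit_pls1(fx$expr[-1, , drop = FALSE], fx$y), "degenerate")
  expect_error(fit_pls1(fx$expr, setNames(rep(1, 20), names(fx$y))),
               "constant")
  y_bad <- fx$y; names(y_bad)[1] <- "nope"
  expect_error(fit_pls1(fx$expr, y_bad), "region ids")
})

test_that("permutation p uses the add-one estimator", {
  fx <- orthogonal_fixture(n_regions = 15, seed = 2)
  # perfect predictor: observed explained variance 1 beats every permutation
  res <- pls1_permutation(fx$expr, fx$y, n_perm = 100, seed = 1)
  expect_equal(res$perm_p, 1 / 101)
  expect_error(pls1_permutation(fx$expr, fx$y, n_perm = 0), "n_perm")
  # null data: p cannot be small
  expr <- random_expr(30, 25, seed = 3)
  y <- setNames(rnorm(25), colnames(expr))
  res2 <- pls1_permutation(expr, y, n_perm = 99, seed = 4)
  expect_gte(res2$perm_p, 1 / 100)
  expect_length(res2$perm_stats, 99)
})

test_that("bootstrap Z separates planted from null genes", {
  atl <- generate_atlas(atlas_config(n_genes = 400, n_plus = 20, n_minus = 10,
                                     n_transient = 0, seed = 61))
  y <- atl$ct[, "5"]
  boot <- pls1_bootstrap(atl$expr, y, n_boot = 300, seed = 62)
  planted <- c(atl$truth$plus_genes, atl$truth$minus_genes)
  nulls <- setdiff(rownames(atl$expr), planted)
  expect_gte(mean(abs(boot$z[planted]) > 3), 0.9)
  expect_lte(mean(abs(boot$z[nulls]) > 3), 0.05)
  expect_true(all(boot$z[atl$truth$plus_genes] > 0))
  expect_true(all(boot$z[atl$truth$minus_genes] < 0))
  # sign(z) = sign(w) wherever se > 0
  ok <- boot$se > 0 & boot$weights != 0
  expect_true(all(sign(boot$z[ok]) == sign(boot$weights[ok])))
  expect_identical(boot$n_kept + boot$n_degenerate, boot$n_boot)
})

test_that("bootstrap counts degenerate replicates and validates n_boot", {
  fx <- orthogonal_fixture(n_regions = 6, seed = 5)
  y <- setNames(c(1, 1, 1, 1, 1, 2), names(fx$y))  # near-constant response
  expr <- random_expr(10, 6, seed = 6)
  colnames(expr) <- names(y)
  boot <- pls1_bootstrap(expr, y, n_boot = 200, seed = 7)
  expect_gt(boot$n_degenerate, 0)
  expect_error(pls1_bootstrap(expr, y, n_boot = 1), "n_boot")
})

test_that("selection applies strict thresholds on z, r and q", {
  genes <- c("g1", "g2", "g3")
  expr <- random_expr(3, 30, seed = 8)
  rownames(expr) <- genes
  y <- setNames(rnorm(30), colnames(expr))
  fit <- fit_pls1(expr, y)
  boot <- pls1_bootstrap(expr, y, n_boot = 50, seed = 9)
  boot$z[] <- c(3.1, -3.5, 0.2)
  sel <- select_age_genes(fit, boot, expr, y)
  expect_identical(sel$plus, "g1")
  expect_identical(sel$minus, "g2")

  # strict ">" on |r|: a gene whose realised |r| equals the threshold exactly
  # is not CT-correlated
  r_g1 <- sel$table["g1", "r"]
  sel_edge <- select_age_genes(fit, boot, expr, y, r_thresh = abs(r_g1),
                               alpha = 1)
  expect_false("g1" %in% sel_edge$ct_correlated)

  # a gene identical to the response is flagged
  expr2 <- expr; expr2["g3", ] <- y
  fit2 <- fit_pls1(expr2, y)
  boot2 <- pls1_bootstrap(expr2, y, n_boot = 50, seed = 10)
  sel2 <- select_age_genes(fit2, boot2, expr2, y)
  expect_true("g3" %in% sel2$ct_correlated)
  expect_equal(sel2$table["g3", "r"], 1, tolerance = 1e-12)
})

test_that("persistence requires selection at every age with a stable sign", {
  mk_sel <- function(plus, minus) {
    structure(list(plus = plus, minus = minus, ct_correlated = character(0),
                   table = data.frame(row.names = character(0))),
              class = "age_selection")
  }
  sels <- list(mk_sel(c("a", "b"), "c"),
               mk_sel(c("a", "b"), "c"),
               mk_sel("a", c("c", "b")))   # b switches sign at age 3
  res <- persistence_intersection(sels)
  expect_identical(res$persistent_plus, "a")
  expect_identical(res$persistent_minus, "c")
  expect_false("b" %in% unlist(res))
  expect_error(persistence_intersection(list()), "no age selections")
})

test_that("consensus intersects persistent and CT-correlated sets", {
  mk_sel <- function(plus, minus, ct, genes = c("a", "b", "c", "d")) {
    tab <- data.frame(gene = genes, z = 0, r = 0, p = 1, q = 1,
                      row.names = genes, stringsAsFactors = FALSE)
    structure(list(plus = plus, minus = minus, ct_correlated = ct,
                   table = tab), class = "age_selection")
  }
  sels <- list(age2 = mk_sel(c("a", "b"), "c", c("a", "c", "d")),
               age3 = mk_sel(c("a", "b"), "c", c("a", "c")))
  pers <- persistence_intersection(sels)
  cons <- consensus_genes(pers, sels)
  expect_identical(cons$consensus_plus, "a")   # b persistent but fails r filter
  expect_identical(cons$consensus_minus, "c")
  expect_setequal(cons$ct_correlated, c("a", "c"))
  expect_identical(cons$provenance["b", "label"], "persistent_plus")

  # disjoint persistent and correlated sets give an empty, valid consensus
  sels2 <- list(mk_sel("a", "b", "d"), mk_sel("a", "b", "d"))
  cons2 <- consensus_genes(persistence_intersection(sels2), sels2)
  expect_length(cons2$consensus_plus, 0)
  expect_length(cons2$consensus_minus, 0)
})

test_that("age_model_inputs matches exact lines and the normal equations", {
  ct <- matrix(c(2.0, 2.2), 1, 2, dimnames = list("RA", c("m1", "m2")))
  res <- age_model_inputs(ct, c(2, 4))
  expect_equal(unname(res$slope["RA"]), 0.1)
  expect_equal(unname(res$intercept["RA"]), 1.8)

  ct2 <- matrix(rep(2.5, 4), 1, 4, dimnames = list("RA", paste0("m", 1:4)))
  res2 <- age_model_inputs(ct2, c(2, 3, 4, 5))
  expect_equal(unname(res2$slope), 0)
  expect_equal(unname(res2$intercept), 2.5)

  set.seed(41)
  ages <- sample(2:8, 10, replace = TRUE)
  ctr <- matrix(rnorm(30, 2.2, 0.2), 3, 10,
                dimnames = list(c("RA", "RB", "RC"), paste0("m", 1:10)))
  res3 <- age_model_inputs(ctr, ages)
  for (r in rownames(ctr)) {
    beta <- solve(crossprod(cbind(1, ages)), crossprod(cbind(1, ages), ctr[r, ]))
    expect_equal(unname(res3$intercept[r]), beta[1], tolerance = 1e-10)
    expect_equal(unname(res3$slope[r]), beta[2], tolerance = 1e-10)
  }
  expect_error(age_model_inputs(ctr, rep(3, 10)), "distinct ages")
})

test_that("response scaling and joint region permutation leave results invariant", {
  atl <- generate_atlas(atlas_config(n_genes = 120, n_plus = 8, n_minus = 8,
                                     n_transient = 0, seed = 51))
  y <- atl$ct[, "3"]
  fit <- fit_pls1(atl$expr, y)
  boot <- pls1_bootstrap(atl$expr, y, n_boot = 100, seed = 1)
  sel <- select_age_genes(fit, boot, atl$expr, y)

  # positive scaling of the response
  fit_s <- fit_pls1(atl$expr, 1000 * y)
  boot_s <- pls1_bootstrap(atl$expr, 1000 * y, n_boot = 100, seed = 1)
  sel_s <- select_age_genes(fit_s, boot_s, atl$expr, 1000 * y)
  expect_equal(fit_s$weights, fit$weights, tolerance = 1e-12)
  expect_equal(boot_s$z, boot$z, tolerance = 1e-9)
  expect_identical(sel_s$plus, sel$plus)
  expect_identical(sel_s$minus, sel$minus)
  expect_identical(sel_s$ct_correlated, sel$ct_correlated)

  # joint permutation of regions (deterministic surface)
  perm <- sample(colnames(atl$expr))
  fit_p <- fit_pls1(atl$expr[, perm], y[perm])
  expect_equal(fit_p$weights, fit$weights, tolerance = 1e-10)
  expect_equal(fit_p$explained_var, fit$explained_var, tolerance = 1e-12)
  expect_equal(fit_p$scores[names(fit$scores)], fit$scores, tolerance = 1e-10)
})

test_that("raising thresholds never enlarges the selected sets", {
  atl <- generate_atlas(atlas_config(n_genes = 200, n_plus = 15, n_minus = 15,
                                     n_transient = 0, seed = 52))
  y <- atl$ct[, "4"]
  fit <- fit_pls1(atl$expr, y)
  boot <- pls1_bootstrap(atl$expr, y, n_boot = 200, seed = 2)
  loose <- select_age_genes(fit, boot, atl$expr, y, z_thresh = 2, r_thresh = 0.2)
  tight <- select_age_genes(fit, boot, atl$expr, y, z_thresh = 3, r_thresh = 0.4)
  expect_true(all(tight$plus %in% loose$plus))
  expect_true(all(tight$minus %in% loose$minus))
  expect_true(all(tight$ct_correlated %in% loose$ct_correlated))
})

test_that("null atlases produce an essentially empty consensus", {
  over_one <- 0L
  n_runs <- 20L
  for (i in seq_len(n_runs)) {
    atl <- generate_atlas(atlas_config(n_regions = 60, n_genes = 150,
                                       n_plus = 0, n_minus = 0,
                                       n_transient = 0, n_ages = 3,
                                       seed = 700 + i))
    res <- pls_consensus_pipeline(atl$expr, atl$ct, n_perm = 10, n_boot = 100,
                                  seed = i)
    n_cons <- length(res$consensus$consensus_plus) +
      length(res$consensus$consensus_minus)
    if (n_cons > 1L) over_one <- over_one + 1L
  }
  expect_lte(over_one, 1L)  # at most one gene in at least 95% of runs
})
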