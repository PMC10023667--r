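test_that("generator is bit-for-bit deterministic under a fixed seed", {
  cfg <- atlas_config(n_genes = 200, n_plus = 10, n_minus = 10,
                      n_transient = 4, seed = 42)
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(a1$expr, a2$expr)
  expect_identical(a1$ct, a2$ct)
  expect_identical(a1$truth, a2$truth)
  a3 <- generate_atlas(atlas_config(n_genes = 200, n_plus = 10, n_minus = 10,
                                    n_transient = 4, seed = 43))
  expect_false(identical(a1$expr, a3$expr))
})

test_that("zero planted effect yields null correlations", {
  atl <- generate_atlas(atlas_config(n_genes = 300, n_plus = 60, n_minus = 0,
                                     n_transient = 0, effect_r = 0, seed = 9))
  r <- cor(t(atl$expr[atl$truth$plus_genes, ]), atl$ct[, 1])
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(max(abs(r)), 4 / sqrt(atl$config$n_regions))
})

test_that("planted effect calibration hits the target correlation per age", {
  atl <- generate_atlas(atlas_config(n_genes = 600, n_plus = 250,
                                     n_minus = 250, n_transient = 0,
                                     effect_r = 0.6, noise_sd = 1, seed = 21))
  planted <- c(atl$truth$plus_genes, atl$truth$minus_genes)
  for (age in colnames(atl$ct)) {
    mean_abs_r <- mean(abs(cor(t(atl$expr[planted, ]), atl$ct[, age])))
    expect_equal(mean_abs_r, 0.6, tolerance = 0.05 / 0.6)
  }
  # signs follow the planted direction
  r_plus <- cor(t(atl$expr[atl$truth$plus_genes, ]), atl$ct[, 1])
  r_minus <- cor(t(atl$expr[atl$truth$minus_genes, ]), atl$ct[, 1])
  expect_true(all(r_plus > 0))
  expect_true(all(r_minus < 0))
})

test_that("transient genes decouple from CT at their inactive age", {
  atl <- generate_atlas(atlas_config(seed = 5))
  for (tg in names(atl$truth$transient_genes)) {
    info <- atl$truth$transient_genes[[tg]]
    inactive <- setdiff(colnames(atl$ct), info$active_ages)
    expect_length(inactive, 1L)
    r <- cor(atl$expr[tg, ], atl$ct)
    # active-age association is clearly stronger than the inactive-age one
    expect_gt(mean(r[, info$active_ages]), 0.2)
    expect_lt(abs(r[, inactive]), 0.25)
  }
})

test_that("planted gene sets are pairwise disjoint for any seed", {
  for (sd in c(1, 17, 303)) {
    atl <- generate_atlas(atlas_config(n_genes = 150, n_plus = 30,
                                       n_minus = 30, n_transient = 10,
                                       seed = sd))
    tr <- names(atl$truth$transient_genes)
    expect_length(intersect(atl$truth$plus_genes, atl$truth$minus_genes), 0)
    expect_length(intersect(atl$truth$plus_genes, tr), 0)
    expect_length(intersect(atl$truth$minus_genes, tr), 0)
    expect_true(all(c(atl$truth$plus_genes, atl$truth$minus_genes, tr)
                    %in% rownames(atl$expr)))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(atlas_config(n_regions = 0), "positive")
  expect_error(atlas_config(n_genes = 50, n_plus = 40, n_minus = 40),
               "exceed")
  expect_error(atlas_config(effect_r = 1.2), "effect_r")
  expect_error(atlas_config(effect_r = 0.9, age_cor = 0.7), "effect_r")
  expect_error(atlas_config(noise_sd = 0), "positive")
})

test_that("per-age matrices share truth but differ in noise", {
  cfg <- atlas_config(n_genes = 120, n_plus = 10, n_minus = 10,
                      n_transient = 0, n_ages = 3, seed = 8)
  atl <- generate_atlas(cfg, shared = FALSE)
  expect_named(atl$expr, as.character(cfg$ages))
  expect_false(identical(atl$expr[[1]], atl$expr[[2]]))
  r1 <- mean(abs(cor(t(atl$expr[["2"]][atl$truth$plus_genes, ]), atl$ct[, "2"])))
  expect_gt(r1, 0.4)
})

test_that("QC generator plants exactly the requested outliers", {
  qc0 <- generate_qc_table(15, n_outliers = 0, seed = 3)
  expect_length(qc_remove_samples(qc0)$removed, 0)

  qc <- generate_qc_table(10, n_outliers = 2, seed = 1)
  res <- qc_remove_samples(qc)
  expect_setequal(res$removed, attr(qc, "outlier_ids"))
  expect_true(all(res$outlier_index[res$removed] >= 3))
  expect_true(all(res$outlier_index[res$kept] <= 2))

  expect_error(generate_qc_table(10, n_outliers = 10), "floor")
  expect_error(generate_qc_table(9, n_outliers = 4), "floor")
  expect_error(generate_qc_table(2, n_outliers = 0), "at least 3")
})

test_that("marker-set generator records the realised contingency table", {
  atl <- generate_atlas(atlas_config(n_genes = 2000, seed = 12))
  universe <- rownames(atl$expr)
  coll <- generate_marker_sets(atl$truth, universe,
                               set_sizes = c(A = 100, B = 80),
                               overlap_frac = 0.4, seed = 2)
  for (nm in names(coll$sets)) {
    pl <- coll$planted[[nm]]
    target <- if (pl$target == "plus") atl$truth$plus_genes else atl$truth$minus_genes
    a <- length(intersect(coll$sets[[nm]], target))
    expect_identical(unname(pl$table["a"]), a)
    expect_equal(sum(pl$table), length(universe))
    # recorded sample OR equals the hand cross-product of the table
    tb <- pl$table
    expect_equal(pl$or_sample, tb["a"] * tb["d"] / (tb["b"] * tb["c"]),
                 ignore_attr = TRUE)
  }
  # zero overlap fraction -> no planted members
  c0 <- generate_marker_sets(atl$truth, universe, set_sizes = c(A = 100),
                             overlap_frac = 0, seed = 2)
  expect_identical(unname(c0$planted$A$table["a"]), 0L)
  expect_error(generate_marker_sets(atl$truth, universe,
                                    set_sizes = c(A = 50),
                                    overlap_frac = 1.5), "overlap_frac")
  e <- generate_marker_sets(atl$truth, universe, set_sizes = c(A = 0),
                            overlap_frac = 0.4, seed = 1)
  expect_length(e$sets$A, 0)
})

test_that("simulate_samples expands regions into mapped samples", {
  atl <- generate_atlas(atlas_config(n_genes = 50, n_regions = 6, n_plus = 2,
                                     n_minus = 2, n_transient = 0, seed = 4))
  sim <- simulate_samples(atl, n_per_region = 3, seed = 7)
  expect_identical(ncol(sim$expr), 18L)
  expect_identical(nrow(sim$map), 18L)
  expect_setequal(unique(sim$map$region_id), colnames(atl$expr))
  expect_true(all(sim$expr >= 0))
})
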