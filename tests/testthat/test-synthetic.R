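test_that("source profiles are proper distributions with the stated shape", {
  bg <- build_profile()
  tm <- tumor_profile()
  expect_equal(sum(bg), 1, tolerance = 1e-12)
  expect_equal(sum(tm), 1, tolerance = 1e-12)
  expect_true(all(bg >= 0) && all(tm >= 0))
  # degenerate config collapses to a renormalized Gaussian
  g <- build_profile(dinucleosome_weight = 0, periodicity_amplitude = 0,
                     lengths = 100:250)
  ref <- dnorm(100:250, 166, 20); ref <- ref / sum(ref)
  expect_equal(unname(g), ref, tolerance = 1e-12)
  # tumor profile is left-shifted: lower mean length
  grid <- as.numeric(names(bg))
  expect_lt(sum(grid * tm), sum(grid * bg))
  # the tumor di-nucleosome peak is enlarged relative to background
  di <- grid >= 280 & grid <= 360
  expect_gt(sum(tm[di]), sum(bg[di]))
  expect_error(build_profile(dinucleosome_weight = 0.6,
                             periodicity_amplitude = 0.5), "sum below 1")
})

test_that("cohort simulation conserves depth and honors boundary weights", {
  sim <- simulate_cohort(n_samples = 8, tumor_weights = rep(c(0, 1), 4),
                         depth = 2e5, seed = 2)
  expect_equal(unname(rowSums(sim$matrix)), rep(2e5, 8))
  expect_equal(nrow(sim$truth), 8)
  bg <- build_profile(); tm <- tumor_profile()
  # pure-background and pure-tumor rows match their generator in
  # total-variation distance at this depth
  f0 <- colSums(sim$matrix[sim$truth$tumor_weight == 0, ])
  f0 <- f0 / sum(f0)
  f1 <- colSums(sim$matrix[sim$truth$tumor_weight == 1, ])
  f1 <- f1 / sum(f1)
  expect_lt(sum(abs(f0 - bg)) / 2, 0.01)
  expect_lt(sum(abs(f1 - tm)) / 2, 0.01)
  # aggregated pure-background counts pass a chi-square goodness-of-fit
  # against the generating distribution (cells pooled to expected >= 5)
  tot <- sum(f0) * sum(sim$matrix[sim$truth$tumor_weight == 0, ])
  exp_counts <- bg * 4 * 2e5
  grp <- ifelse(exp_counts >= 5, seq_along(exp_counts), 0)
  obs <- tapply(colSums(sim$matrix[sim$truth$tumor_weight == 0, ]), grp, sum)
  ex <- tapply(exp_counts, grp, sum)
  pval <- stats::chisq.test(obs, p = ex / sum(ex))$p.value
  expect_gt(pval, 0.01)
})

test_that("simulation is reproducible and weight errors shrink with depth", {
  a <- simulate_cohort(n_samples = 5, depth = 1e4, seed = 9)
  b <- simulate_cohort(n_samples = 5, depth = 1e4, seed = 9)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  d <- simulate_cohort(n_samples = 5, depth = 1e4, seed = 10)
  expect_false(identical(a$matrix, d$matrix))

  # recovered-weight error decreases with depth (projection onto the true
  # signatures isolates depth noise from factorization noise)
  H <- rbind(build_profile(), tumor_profile())
  w_true <- seq(0.05, 0.85, length.out = 12)
  err <- vapply(c(1e3, 1e4, 1e6), function(dp) {
    sim <- simulate_cohort(n_samples = 12, tumor_weights = w_true,
                           depth = dp, seed = 31)
    w <- transform_weights(normalize_rows(sim$matrix), H, seed = 1)
    mean(abs(w[, 2] - w_true))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("binned cohorts carry known openness and fixed per-bin depth", {
  sb <- simulate_binned_cohort(n_bins = 10, depth_per_bin = 3000, seed = 4)
  expect_equal(unname(rowSums(sb$matrix)), rep(3000, 10))
  expect_equal(sb$truth$bin_id, rownames(sb$matrix))
  expect_true(all(sb$truth$openness >= 0 & sb$truth$openness <= 1))
  # fully open bins are shorter on average than fully closed bins
  sb2 <- simulate_binned_cohort(n_bins = 2, openness = c(1, 0),
                                depth_per_bin = 5e4, seed = 5)
  grid <- as.numeric(colnames(sb2$matrix))
  mean_len <- (sb2$matrix %*% grid) / rowSums(sb2$matrix)
  expect_lt(mean_len[1], mean_len[2])
})

test_that("labelled cohorts couple class to tumor weight", {
  sim <- simulate_labelled_cohort(n_cases = 6, n_controls = 6, depth = 1e4,
                                  seed = 12)
  expect_equal(as.character(sim$labels),
               rep(c("control", "case"), each = 6))
  expect_true(all(sim$truth$tumor_weight[sim$labels == "control"] == 0))
  expect_true(all(sim$truth$tumor_weight[sim$labels == "case"] > 0))
})
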