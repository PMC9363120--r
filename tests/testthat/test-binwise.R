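test_that("bins tile chromosomes without gaps and conserve total length", {
  b <- make_bins(data.frame(chrom = "chr1", size = 600000), 250000)
  expect_equal(b$start, c(0, 250000, 500000))
  expect_equal(b$end, c(250000, 500000, 600000))
  expect_equal(b$bin_id[1], "chr1:0-250000")
  # bin_size >= chromosome -> single bin
  one <- make_bins(data.frame(chrom = "chrM", size = 16571), 250000)
  expect_equal(nrow(one), 1)
  expect_equal(one$end, 16571)
  # conservation over several chromosomes
  cs <- data.frame(chrom = c("c1", "c2"), size = c(701, 1000))
  bb <- make_bins(cs, 300)
  expect_equal(sum(bb$end - bb$start), 1701)
  expect_true(all(bb$start < bb$end))
  expect_error(make_bins(cs, 0), "positive")
})

test_that("fragments land in bins by midpoint and totals are conserved", {
  bins <- make_bins(data.frame(chrom = "chr1", size = 1000000), 5000)
  bm <- binned_histograms(fx_bam(), bins, fx_filters())
  h <- extract_fragment_lengths(fx_bam(), fx_filters())
  expect_equal(sum(bm), sum(h))
  # pairA: pos 1001, length 166 -> midpoint 1083 (0-based) -> bin [0,5000)
  expect_equal(sum(bm["chr1:0-5000", ]), 1)
  expect_equal(unname(bm["chr1:0-5000", "166"]), 1)
  # pairF/G/H midpoints near 5055-5073 -> bin [5000,10000)
  expect_equal(sum(bm["chr1:5000-10000", ]), 3)
  # empty bins retained as zero rows
  expect_true(any(rowSums(bm) == 0))
  # a fragment crossing a bin edge is assigned by its midpoint
  edge_bins <- make_bins(data.frame(chrom = "chr1", size = 1000000), 1084)
  bm2 <- binned_histograms(fx_bam(), edge_bins, fx_filters())
  expect_equal(unname(bm2["chr1:0-1084", "166"]), 1)
})

test_that("control aggregation is an element-wise sum over identical grids", {
  a <- simulate_binned_cohort(n_bins = 6, depth_per_bin = 500, seed = 1)$matrix
  b <- simulate_binned_cohort(n_bins = 6, depth_per_bin = 500, seed = 2)$matrix
  agg <- aggregate_controls(list(a, b))
  expect_equal(unclass(agg), unclass(a) + unclass(b), ignore_attr = TRUE)
  expect_equal(sum(agg), sum(a) + sum(b))
  expect_identical(unname(unclass(aggregate_controls(list(a)))),
                   unname(unclass(a)))
  bad <- b[6:1, ]
  expect_error(aggregate_controls(list(a, bad)), "differ")
})

test_that("bin QC excludes bins outside median +/- 2 IQR of control means", {
  # brute-force oracle with type-7 quartiles: means (100,102,98,101,99,500)
  means <- c(100, 102, 98, 101, 99, 500)
  q <- stats::quantile(means, c(0.25, 0.75), type = 7)
  expect_equal(unname(q), c(99.25, 101.75))
  window <- stats::median(means) + c(-2, 2) * (q[2] - q[1])
  expect_equal(unname(window), c(95.5, 105.5))

  grid <- as.character(100:102)
  mk <- function(totals) {
    m <- outer(totals / 3, rep(1, 3))
    dimnames(m) <- list(paste0("b", seq_along(totals)), grid)
    m
  }
  kept <- qc_bins(list(mk(means), mk(means)))  # two identical controls
  expect_equal(as.character(kept), paste0("b", 1:5))  # 500 bin excluded
  expect_equal(unname(attr(kept, "bin_means")), means)

  # all means equal -> IQR 0 -> only bins at the median survive
  kept2 <- qc_bins(list(mk(rep(7, 4)), mk(rep(7, 4))))
  expect_equal(as.character(kept2), paste0("b", 1:4))
  # in-window means are all kept, and order of bins/controls is irrelevant
  m1 <- mk(means[1:5]); m2 <- mk(means[1:5] + 1)
  expect_equal(as.character(qc_bins(list(m1, m2))), paste0("b", 1:5))
  expect_setequal(as.character(qc_bins(list(m2, m1))),
                  as.character(qc_bins(list(m1, m2))))
  expect_error(qc_bins(list(m1)), "at least 2")
})

test_that("per-bin features recover constructed mixtures and flag empty bins", {
  H <- rbind(sig1 = as.numeric(build_profile(mode_length = 160, mode_sd = 22,
                                             periodicity_amplitude = 0.12)),
             sig2 = as.numeric(build_profile(mode_length = 168, mode_sd = 18,
                                             periodicity_amplitude = 0.02)))
  p_mix <- 0.4 * H[1, ] + 0.6 * H[2, ]
  set.seed(21)
  deep <- as.numeric(rmultinom(1, 1e5, p_mix))
  pure <- round(H[1, ] * 1e6)
  shallow <- as.numeric(rmultinom(1, 50, p_mix))
  m <- rbind(deep, pure, shallow)
  colnames(m) <- as.character(30:700)
  rownames(m) <- c("mix", "pure", "shallow")
  f <- per_bin_weight_features(m, H, component = 1, seed = 2)
  expect_length(f, 3)
  expect_equal(unname(f["mix"]), 0.4, tolerance = 0.05)
  expect_equal(unname(f["pure"]), 1, tolerance = 5e-3)
  expect_true(is.na(f["shallow"]))  # below the 100-fragment floor
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  # kept_bins restricts the feature vector
  f2 <- per_bin_weight_features(m, H, kept_bins = c("mix", "pure"), seed = 2)
  expect_length(f2, 2)
})

test_that("bin values rank-correlate with an external signal by bin id", {
  vals <- c(b1 = 0.1, b2 = 0.5, b3 = 0.9, b4 = 0.3)
  sig <- data.frame(bin_id = c("b3", "b1", "b2", "b4"),
                    value = c(9, 1, 5, 3))
  expect_equal(bin_signal_correlation(vals, sig), 1)
  expect_error(bin_signal_correlation(vals[1:2], sig[1:2, ]), "fewer than 3")
})
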