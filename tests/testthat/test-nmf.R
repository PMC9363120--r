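test_that("generalized KL divergence matches its closed form", {
  V <- matrix(c(1, 2, 3, 4), 2)
  W <- matrix(c(1, 2), 2)
  H <- matrix(c(1, 1.5), 1, 2)
  expect_equal(kl_divergence(W %*% H, W, H), 0)
  expect_equal(kl_divergence(matrix(1), matrix(1), matrix(2)), 1 - log(2))
  # a zero data cell contributes only the reconstruction term
  expect_equal(kl_divergence(matrix(0), matrix(1), matrix(3)), 3)
  # zero reconstruction against positive data is infinite
  expect_equal(kl_divergence(matrix(2), matrix(0), matrix(0)), Inf)
  expect_error(kl_divergence(matrix(-1), matrix(1), matrix(1)),
               "non-negative")
})

test_that("an exact rank-1 matrix is recovered to numerical precision", {
  w <- c(1, 2, 5, 0.3)
  h <- build_profile(lengths = 100:160)
  V <- outer(w, as.numeric(h))
  V <- V / rowSums(V)
  attr(V, "normalized") <- TRUE
  fit <- fl_nmf(V, k = 1, restarts = 2, seed = 4, tol = 1e-14,
                max_iter = 5000)
  expect_lt(fit$loss, 1e-8)
  expect_equal(unname(fit$W[, 1]), rep(1, 4))
})

test_that("multiplicative updates never increase the loss", {
  set.seed(42)
  for (i in 1:25) {
    V <- matrix(rexp(8 * 12), 8, 12)
    V <- V / rowSums(V)
    attr(V, "normalized") <- TRUE
    fit <- fl_nmf(V, k = 3, restarts = 1, seed = i, max_iter = 60)
    expect_true(all(diff(fit$loss_trace) <= 1e-10))
  }
})

test_that("more restarts never select a worse fit under nested seeds", {
  sim <- fx_small_cohort()
  x <- normalize_rows(sim$matrix)
  losses <- vapply(c(1, 3, 6), function(r)
    fl_nmf(x, k = 2, restarts = r, seed = 99, max_iter = 300)$loss,
    numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("rescaling yields row-stochastic factors without changing the fit", {
  W <- matrix(c(1, 2, 3, 4), 2)
  H <- matrix(c(1, 3, 2, 2), 2, byrow = TRUE)
  sc <- rescale_factors(W, H)
  expect_equal(unname(sc$H[1, ]), c(0.25, 0.75))
  expect_equal(rowSums(sc$W), c(1, 1))
  # the row-normalized reconstruction is invariant under rescaling
  A <- W %*% H; B <- sc$W %*% sc$H
  expect_equal(A / rowSums(A), B / rowSums(B))
  expect_identical(rescale_factors(sc$W, sc$H)$H, sc$H)
  expect_error(rescale_factors(matrix(0, 1, 2), H[1, , drop = FALSE]),
               "all-zero")
})

test_that("the tumor signature is the one with lowest mean length", {
  fit <- list(H = rbind(S1 = c(0.2, 0.8), S2 = c(0.8, 0.2)))
  colnames(fit$H) <- c("140", "170")
  class(fit) <- "fl_nmf"
  expect_equal(tumor_signature_index(fit), 2)
  # k = 1 trivially returns the only component
  fit1 <- list(H = matrix(c(0.5, 0.5), 1, dimnames = list("S1", c("140", "170"))))
  class(fit1) <- "fl_nmf"
  expect_equal(tumor_signature_index(fit1), 1)
  # exact tie -> lowest index with a warning
  tie <- list(H = rbind(S1 = c(0.5, 0.5), S2 = c(0.5, 0.5)))
  colnames(tie$H) <- c("140", "170")
  class(tie) <- "fl_nmf"
  expect_warning(idx <- tumor_signature_index(tie), "tied")
  expect_equal(idx, 1)
  # matching against reference signatures overrides the mean-length rule
  expect_equal(tumor_signature_index(fit, reference = matrix(c(0.21, 0.79), 1)),
               1)
})

test_that("weights of new samples are recovered under fixed signatures", {
  H <- rbind(build_profile(), tumor_profile())
  mix <- rbind(H[1, ],
               0.3 * H[1, ] + 0.7 * H[2, ])
  attr(mix, "normalized") <- TRUE
  w <- transform_weights(mix, H, seed = 5, tol = 1e-14, max_iter = 20000)
  # multiplicative updates approach boundary weights geometrically; at this
  # iteration budget the spurious component is down to ~1e-5
  expect_equal(unname(w[1, ]), c(1, 0), tolerance = 1e-4)
  expect_equal(unname(w[2, ]), c(0.3, 0.7), tolerance = 1e-4)
  expect_error(transform_weights(mix[, 1:10], H), "grids differ")
})

test_that("projecting the training rows reproduces the training weights", {
  sim <- fx_small_cohort()
  x <- normalize_rows(sim$matrix)
  fit <- fl_nmf(x, k = 2, restarts = 5, seed = 3)
  w <- transform_weights(x, fit$H, seed = 3)
  expect_lt(max(rowSums(abs(w - fit$W))), 1e-3)
})

test_that("max cosine similarity matches closed forms", {
  A <- rbind(c(1, 1), c(1, 0))
  expect_equal(max_cosine_similarity(A, A), c(1, 1))
  expect_equal(max_cosine_similarity(matrix(c(1, 0), 1), matrix(c(0, 1), 1)),
               0)
  expect_equal(max_cosine_similarity(matrix(c(1, 1), 1), matrix(c(1, 0), 1)),
               1 / sqrt(2))
  expect_error(max_cosine_similarity(matrix(0, 1, 2), A), "zero-norm")
  expect_error(max_cosine_similarity(matrix(1, 1, 3), A), "grids differ")
})

test_that("the model object provides the standard accessor methods", {
  sim <- fx_small_cohort()
  x <- normalize_rows(sim$matrix)
  fit <- fl_nmf(x, k = 2, restarts = 3, seed = 8)
  expect_s3_class(fit, "fl_nmf")
  expect_equal(dim(coef(fit)), c(16, 2))
  expect_equal(dim(coef(fit, "signatures")), c(2, 671))
  expect_equal(rowSums(coef(fit)), setNames(rep(1, 16), rownames(x)))
  expect_equal(dim(fitted(fit)), dim(x))
  expect_equal(unclass(x) - fitted(fit), residuals(fit),
               ignore_attr = TRUE)
  expect_equal(predict(fit), fit$W)
  w_new <- predict(fit, sim$matrix[1:3, ], seed = 1)
  expect_equal(dim(w_new), c(3, 2))
  expect_output(print(fit), "KL-NMF")
  expect_output(print(summary(fit)), "Tumor-like signature")
  sims <- simulate(fit, nsim = 2, seed = 1, depth = 1000)
  expect_length(sims, 2)
  expect_equal(unname(rowSums(sims[[1]])), rep(1000, 16))
})

test_that("fits agree with an independent KL-NMF implementation", {
  # scikit-learn's NMF (same objective, same update rule) run on an easy
  # low-rank-plus-noise matrix should reach the same loss basin.
  py <- Sys.which("python")
  set.seed(10)
  W0 <- matrix(rexp(12 * 2), 12, 2)
  H0 <- matrix(rexp(2 * 25), 2, 25)
  V <- W0 %*% H0 + matrix(runif(12 * 25, 0, 0.01), 12, 25)
  V <- V / rowSums(V)
  attr(V, "normalized") <- TRUE
  fit <- fl_nmf(V, k = 2, restarts = 10, seed = 2, tol = 1e-10,
                max_iter = 5000)
  vtxt <- paste(apply(V, 1, paste, collapse = ","), collapse = ";")
  code <- paste0(
    "import numpy as np\n",
    "from sklearn.decomposition import NMF\n",
    "V = np.array([[float(x) for x in r.split(',')] for r in '", vtxt,
    "'.split(';')])\n",
    "best = np.inf\n",
    "for s in range(10):\n",
    "    m = NMF(2, init='random', solver='mu', beta_loss='kullback-leibler',\n",
    "            max_iter=5000, tol=1e-10, random_state=s)\n",
    "    W = m.fit_transform(V); H = m.components_\n",
    "    A = W @ H\n",
    "    mask = V > 0\n",
    "    kl = (V[mask]*np.log(V[mask]/A[mask])).sum() - V.sum() + A.sum()\n",
    "    best = min(best, kl)\n",
    "print(best)\n")
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  ref <- as.numeric(system2(py, f, stdout = TRUE))
  expect_equal(fit$loss, ref, tolerance = 0.02)
})
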