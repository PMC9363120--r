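#' Generalized Kullback--Leibler divergence D(V || WH)
#'
#' The objective minimized by the factorization:
#' \deqn{D(V \| WH) = \sum_{ij} V_{ij} \log(V_{ij}/(WH)_{ij}) - V_{ij} + (WH)_{ij}}
#' with the convention `0 * log(0) = 0`. Cells where `(WH)_ij = 0` but
#' `V_ij > 0` contribute `+Inf`.
#'
#' @param V non-negative data matrix.
#' @param W non-negative weight matrix (rows align with `V` rows).
#' @param H non-negative signature matrix (columns align with `V` columns).
#' @return the divergence, a non-negative scalar (possibly `Inf`).
#' @examples
#' kl_divergence(matrix(1), matrix(1), matrix(2))  # 1 - log(2)
#' @export
kl_divergence <- function(V, W, H) {
  V <- as.matrix(V); W <- as.matrix(W); H <- as.matrix(H)
  if (min(V) < 0 || min(W) < 0 || min(H) < 0)
    stop_fatal("kl_divergence requires non-negative inputs")
  .kl(V, W %*% H)
}

.kl <- function(V, A) {
  pos <- V > 0
  if (any(pos & A == 0)) return(Inf)
  s <- sum(A) - sum(V)
  s + sum(V[pos] * log(V[pos] / A[pos]))
}

# One sweep of the Lee-Seung multiplicative updates for the generalized KL
# objective. eps guards 0/0; the updates never increase the loss.
.mu_step <- function(V, W, H, eps, update_W = TRUE) {
  WH <- W %*% H
  R <- V / (WH + eps)
  H <- H * crossprod(W, R) / (colSums(W) + eps)
  if (update_W) {
    WH <- W %*% H
    R <- V / (WH + eps)
    W <- W * tcrossprod(R, H) / rep(rowSums(H) + eps, each = nrow(W))
  }
  list(W = W, H = H)
}

#' Fit fragment-length signatures by KL-loss non-negative matrix factorization
#'
#' Factorizes a row-normalized samples-by-lengths (or bins-by-lengths)
#' frequency matrix `V` as `V ~ W H` with `k` components, minimizing the
#' generalized Kullback--Leibler divergence by multiplicative updates from
#' random non-negative initializations. The fit with the lowest loss across
#' `restarts` independent initializations is kept, then rescaled so every
#' signature (row of `H`) and every sample weight vector (row of `W`) sums to
#' one. Each signature is then a probability distribution over fragment
#' length — a cfDNA source profile — and each sample's weights are its
#' estimated mixing proportions across sources.
#'
#' @param x row-normalized frequency matrix (see [normalize_rows()]); rows are
#'   samples or genomic bins, columns are fragment lengths.
#' @param k number of components (sources), `1 <= k <= min(dim(x))`.
#' @param restarts independent random initializations; the lowest-loss fit is
#'   returned.
#' @param max_iter maximum multiplicative-update sweeps per restart.
#' @param tol stop when the relative loss improvement falls below this.
#' @param seed master seed; restart seeds are derived from it.
#' @param eps numerical floor inside the updates to avoid 0/0.
#' @return an object of class `fl_nmf` with elements `W` (n x k,
#'   row-stochastic weights), `H` (k x L row-stochastic signatures), `loss`
#'   (final generalized KL divergence of the unscaled fit), `k`, `restarts`,
#'   `iterations` (sweeps run by the winning restart), `loss_trace` (loss per
#'   sweep of the winning restart), `seed`, and the training matrix `V`.
#' @examples
#' sim <- simulate_cohort(n_samples = 12, depth = 2e4, seed = 1)
#' fit <- fl_nmf(normalize_rows(sim$matrix), k = 2, restarts = 4, seed = 1)
#' fit
#' @seealso [predict.fl_nmf()], [tumor_signature_index()], [rescale_factors()]
#' @export
fl_nmf <- function(x, k = 2, restarts = 20, max_iter = 2000, tol = 1e-6,
                   seed = NULL, eps = 1e-12) {
  if (!is_normalized(x))
    stop_fatal("x must be row-normalized (see normalize_rows())")
  V <- unclass(as.matrix(x))
  if (k < 1 || k > min(dim(V)))
    stop_fatal("k must be between 1 and min(dim(x)) = ", min(dim(V)))
  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .fit_one(V, k, max_iter, tol, seeds[[r]], eps)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  sc <- rescale_factors(best$W, best$H)
  dimnames(sc$W) <- list(rownames(x), paste0("S", seq_len(k)))
  dimnames(sc$H) <- list(paste0("S", seq_len(k)), colnames(x))
  structure(list(W = sc$W, H = sc$H, loss = best$loss, k = k,
                 restarts = restarts, iterations = best$iterations,
                 loss_trace = best$trace, seed = seed, eps = eps, V = x),
            class = "fl_nmf")
}

.fit_one <- function(V, k, max_iter, tol, seed, eps) {
  n <- nrow(V); L <- ncol(V)
  init <- with_seed(seed, list(
    W = matrix(runif(n * k), n, k),
    H = matrix(runif(k * L), k, L)))
  scale <- sqrt(mean(V) / k)
  W <- init$W * scale
  H <- init$H * scale
  trace <- numeric(0)
  prev <- .kl(V, W %*% H)
  it <- 0L
  for (i in seq_len(max_iter)) {
    st <- .mu_step(V, W, H, eps)
    W <- st$W; H <- st$H
    cur <- .kl(V, W %*% H)
    trace <- c(trace, cur)
    it <- i
    if (is.finite(prev) && prev - cur < tol * max(prev, eps)) break
    prev <- cur
  }
  list(W = W, H = H, loss = trace[length(trace)], iterations = it,
       trace = trace)
}

#' Rescale a factorization to row-stochastic signatures and weights
#'
#' Each signature (row of `H`) is divided by its sum, each weight row of `W`
#' by its own sum. The row-normalized reconstruction is invariant under this
#' rescaling.
#'
#' @param W,H non-negative factors with no all-zero rows.
#' @return list with row-stochastic `W` and `H`.
#' @export
rescale_factors <- function(W, H) {
  s <- rowSums(H)
  if (any(s == 0)) stop_fatal("all-zero signature row")
  if (any(rowSums(W) == 0)) stop_fatal("all-zero sample weight row")
  H <- H / s
  # absorb the signature scales into W so the product is unchanged, then
  # normalize each sample's weights; the reconstruction changes only by a
  # positive per-row factor
  W <- sweep(W, 2, s, "*")
  W <- W / rowSums(W)
  list(W = W, H = H)
}

#' Index of the tumor (cancer-related) signature
#'
#' The tumor-derived component is identified as the signature with the lowest
#' mean fragment length, reflecting the characteristic left shift of ctDNA
#' fragments. Ties go to the lowest index with a warning. Alternatively a
#' reference signature set can be supplied, in which case the component with
#' the highest cosine similarity to any reference signature is returned.
#'
#' @param fit an [fl_nmf()] object (rescaled, as returned).
#' @param reference optional reference signature matrix (rows = signatures on
#'   the same length grid) to match by cosine similarity instead.
#' @return integer component index.
#' @export
tumor_signature_index <- function(fit, reference = NULL) {
  H <- fit$H
  if (!is.null(reference)) {
    sims <- apply(as.matrix(reference), 1, function(ref)
      apply(H, 1, .cosine, ref))
    sims <- matrix(sims, nrow = nrow(H))
    return(which.max(apply(sims, 1, max)))
  }
  lens <- as.numeric(colnames(H))
  means <- as.vector(H %*% lens)
  idx <- which(means == min(means))
  if (length(idx) > 1L) warning("tied mean fragment lengths; taking lowest index")
  idx[1]
}

#' Infer mixing weights for new samples under fixed signatures
#'
#' Runs only the weight-side multiplicative update with the signature matrix
#' held fixed, so samples unseen at training time can be projected onto a
#' learned signature set (e.g. hold-out samples, or genomic bins projected
#' onto sample-wise signatures).
#'
#' @param x row-normalized frequency matrix for the new samples.
#' @param H row-stochastic signature matrix on the same length grid.
#' @param max_iter,tol,eps as in [fl_nmf()].
#' @param seed seed for the random weight initialization.
#' @return row-stochastic weight matrix (rows = new samples, cols = signatures).
#' @export
transform_weights <- function(x, H, max_iter = 2000, tol = 1e-8,
                              seed = NULL, eps = 1e-12) {
  H <- as.matrix(H)
  if (ncol(x) != ncol(H))
    stop_fatal("length grids differ: x has ", ncol(x), " columns, H has ",
               ncol(H))
  if (!is_normalized(x))
    stop_fatal("x must be row-normalized (see normalize_rows())")
  V <- unclass(as.matrix(x))
  k <- nrow(H)
  W <- with_seed(seed, matrix(runif(nrow(V) * k, 0.5, 1.5) / k, nrow(V), k))
  prev <- .kl(V, W %*% H)
  hs <- rep(rowSums(H) + eps, each = nrow(W))
  for (i in seq_len(max_iter)) {
    R <- V / (W %*% H + eps)
    W <- W * tcrossprod(R, H) / hs
    cur <- .kl(V, W %*% H)
    if (is.finite(prev) && prev - cur < tol * max(prev, eps)) break
    prev <- cur
  }
  W <- W / rowSums(W)
  dimnames(W) <- list(rownames(x), rownames(H))
  W
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_fatal("zero-norm signature")
  sum(a * b) / (na * nb)
}

#' Best-match cosine similarity between two signature sets
#'
#' For every signature in `H_a`, the maximum cosine similarity over all
#' signatures in `H_b`. Used to quantify signature stability between fits on
#' reduced and full datasets.
#'
#' @param H_a,H_b signature matrices (rows = signatures, same length grid).
#' @return numeric vector, one similarity in `[0, 1]` per row of `H_a`.
#' @export
max_cosine_similarity <- function(H_a, H_b) {
  H_a <- as.matrix(H_a); H_b <- as.matrix(H_b)
  if (ncol(H_a) != ncol(H_b)) stop_fatal("length grids differ")
  apply(H_a, 1, function(a) max(apply(H_b, 1, .cosine, a)))
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.fl_nmf <- function(x, ...) {
  cat(sprintf("Fragment-length KL-NMF fit: %d samples x %d lengths, k = %d\n",
              nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  final KL loss %.6g after %d iterations (best of %d restarts)\n",
              x$loss, x$iterations, x$restarts))
  ti <- tumor_signature_index(x)
  lens <- as.numeric(colnames(x$H))
  means <- as.vector(x$H %*% lens)
  cat(sprintf("  signature mean lengths (bp): %s; tumor-like: S%d\n",
              paste(sprintf("%.1f", means), collapse = ", "), ti))
  invisible(x)
}

#' @export
summary.fl_nmf <- function(object, ...) {
  ti <- tumor_signature_index(object)
  lens <- as.numeric(colnames(object$H))
  out <- list(k = object$k, loss = object$loss,
              iterations = object$iterations, restarts = object$restarts,
              signature_mean_length = as.vector(object$H %*% lens),
              tumor_index = ti,
              tumor_weight = object$W[, ti])
  class(out) <- "summary.fl_nmf"
  out
}

#' @export
print.summary.fl_nmf <- function(x, ...) {
  cat(sprintf("KL-NMF with k = %d (loss %.6g, %d restarts)\n",
              x$k, x$loss, x$restarts))
  cat(sprintf("Signature mean lengths (bp): %s\n",
              paste(sprintf("%.1f", x$signature_mean_length), collapse = ", ")))
  cat(sprintf("Tumor-like signature: S%d\n", x$tumor_index))
  cat("Tumor-signature weight per sample:\n")
  print(summary(x$tumor_weight))
  invisible(x)
}

#' Extract factor matrices from a fit
#' @param object an [fl_nmf()] fit.
#' @param which `"weights"` for the sample weight matrix `W`, `"signatures"`
#'   for the signature matrix `H`.
#' @param ... unused.
#' @export
coef.fl_nmf <- function(object, which = c("weights", "signatures"), ...) {
  switch(match.arg(which), weights = object$W, signatures = object$H)
}

#' @export
fitted.fl_nmf <- function(object, ...) {
  A <- object$W %*% object$H
  A / rowSums(A)  # row-normalized reconstruction
}

#' @export
residuals.fl_nmf <- function(object, ...) {
  unclass(as.matrix(object$V)) - fitted(object)
}

#' Project new samples onto fitted signatures
#'
#' @param object an [fl_nmf()] fit.
#' @param newdata count or row-normalized frequency matrix on the same length
#'   grid; counts are normalized first. Defaults to the training matrix.
#' @param ... passed to [transform_weights()].
#' @return row-stochastic weight matrix for `newdata`.
#' @export
predict.fl_nmf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$W)
  if (!is_normalized(newdata)) newdata <- normalize_rows(newdata)
  transform_weights(newdata, object$H, eps = object$eps, ...)
}

#' Plot fitted fragment-length signatures
#' @param x an [fl_nmf()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fl_nmf <- function(x, ...) {
  lens <- as.numeric(colnames(x$H))
  graphics::matplot(lens, t(x$H), type = "l", lty = 1,
                    xlab = "Fragment length (bp)", ylab = "Frequency", ...)
  graphics::legend("topright", legend = rownames(x$H), lty = 1,
                   col = seq_len(x$k), bty = "n")
  invisible(x)
}

#' Simulate count matrices from a fitted model
#'
#' Draws multinomial fragment counts for each sample from its fitted length
#' distribution `(WH)_s`, at a given sequencing depth.
#'
#' @param object an [fl_nmf()] fit.
#' @param nsim number of simulated cohorts.
#' @param seed master seed.
#' @param depth fragments per sample.
#' @param ... unused.
#' @return list of `nsim` count matrices shaped like the training matrix.
#' @export
simulate.fl_nmf <- function(object, nsim = 1, seed = NULL, depth = 1e5, ...) {
  P <- fitted(object)
  seeds <- derive_seeds(seed, nsim)
  lapply(seq_len(nsim), function(s) with_seed(seeds[[s]], {
    m <- t(apply(P, 1, function(p) as.numeric(rmultinom(1, depth, p))))
    dimnames(m) <- dimnames(P)
    attr(m, "normalized") <- FALSE
    m
  }))
}
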