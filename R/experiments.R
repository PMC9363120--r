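#' Signature stability under sample subsetting
#'
#' Repeatedly fits the factorization on random sample subsets of a given size
#' and measures, for every subset-fit signature, the maximum cosine similarity
#' against the signatures fitted on the full dataset. Quantifies how many
#' samples are needed before the learned length signatures stabilize.
#'
#' @param x row-normalized frequency matrix.
#' @param k components.
#' @param subset_sizes vector of subset sizes to test (each `<= nrow(x)`);
#'   sizes `< k` are skipped with a warning.
#' @param replicates random subsets per size.
#' @param seed master seed.
#' @param restarts,max_iter,tol passed to [fl_nmf()].
#' @param full_fit optional precomputed full-data [fl_nmf()] fit.
#' @return data.frame with columns `subset_size`, `replicate`, `signature`,
#'   `similarity`.
#' @export
stability_experiment <- function(x, k = 2, subset_sizes, replicates = 100,
                                 seed = NULL, restarts = 5, max_iter = 2000,
                                 tol = 1e-6, full_fit = NULL) {
  bad <- subset_sizes < k
  if (any(bad)) {
    warning("skipping subset sizes smaller than k: ",
            paste(subset_sizes[bad], collapse = ", "))
    subset_sizes <- subset_sizes[!bad]
  }
  if (any(subset_sizes > nrow(x)))
    stop_fatal("subset size exceeds number of rows")
  seeds <- derive_seeds(seed, length(subset_sizes) * replicates + 1L)
  if (is.null(full_fit))
    full_fit <- fl_nmf(x, k, restarts = restarts, max_iter = max_iter,
                       tol = tol, seed = seeds[[length(seeds)]])
  out <- vector("list", length(subset_sizes) * replicates)
  i <- 0L
  for (sz in subset_sizes) for (r in seq_len(replicates)) {
    i <- i + 1L
    s <- seeds[[i]]
    rows <- with_seed(s, sample.int(nrow(x), sz))
    sub <- x[rows, , drop = FALSE]
    attr(sub, "normalized") <- TRUE
    fit <- fl_nmf(sub, k, restarts = restarts, max_iter = max_iter,
                  tol = tol, seed = s)
    sims <- max_cosine_similarity(fit$H, full_fit$H)
    out[[i]] <- data.frame(subset_size = sz, replicate = r,
                           signature = seq_len(k), similarity = sims)
  }
  do.call(rbind, out)
}

#' Hold-out generalization of tumor-weight estimates
#'
#' Repeatedly splits the cohort into equal-size train/test halves, fits the
#' factorization on the training half, projects the held-out half onto the
#' learned signatures, and correlates the tumor-signature weight with an
#' external ctDNA-fraction estimate in each partition. Similar train and test
#' correlations indicate the signatures generalize to unseen samples.
#'
#' @param x row-normalized frequency matrix.
#' @param ctdna numeric ctDNA fractions aligned with `rownames(x)`.
#' @param k components.
#' @param repeats number of random half-splits.
#' @param seed master seed.
#' @param restarts,max_iter,tol passed to [fl_nmf()].
#' @return data.frame with columns `replicate`, `train_correlation`,
#'   `test_correlation` (Pearson).
#' @export
holdout_experiment <- function(x, ctdna, k = 2, repeats = 20, seed = NULL,
                               restarts = 5, max_iter = 2000, tol = 1e-6) {
  n <- nrow(x)
  if (length(ctdna) != n) stop_fatal("ctdna must align with rows of x")
  if (n < 2 * k) stop_fatal("need at least 2*k rows for a half-split")
  seeds <- derive_seeds(seed, repeats)
  half <- n %/% 2
  res <- lapply(seq_len(repeats), function(r) {
    s <- seeds[[r]]
    idx <- with_seed(s, sample.int(n, half))
    tr <- x[idx, , drop = FALSE]; attr(tr, "normalized") <- TRUE
    te <- x[-idx, , drop = FALSE]; attr(te, "normalized") <- TRUE
    fit <- fl_nmf(tr, k, restarts = restarts, max_iter = max_iter,
                  tol = tol, seed = s)
    ti <- tumor_signature_index(fit)
    w_te <- transform_weights(te, fit$H, seed = s)
    data.frame(replicate = r,
               train_correlation = correlate(fit$W[, ti], ctdna[idx]),
               test_correlation = correlate(w_te[, ti], ctdna[-idx]))
  })
  do.call(rbind, res)
}

#' Reproduce the signature-weight vs ctDNA-fraction correlations on a cohort
#'
#' Given a samples-by-lengths count matrix and per-sample ctDNA-fraction
#' estimates, fits a 2-component factorization and reports (a) the Pearson
#' correlation between the tumor-signature weight and the ctDNA fraction,
#' (b) the same correlation for the short/long fragment ratio, and (c) the
#' tumor-weight correlation after subsampling every sample to a fixed number
#' of fragments. Written for cohort-level validation, e.g. against histogram
#' tables distributed with published studies.
#'
#' @param counts count matrix (rows = samples), e.g. from [read_matrix_tsv()].
#' @param ctdna ctDNA fractions aligned with `rownames(counts)`.
#' @param subsample_n fragments per sample for the subsampled re-estimate.
#' @param k,restarts,seed passed to [fl_nmf()].
#' @return list with `nmf_correlation`, `delfi_correlation`,
#'   `subsampled_correlation`, the fitted model, and the tumor index.
#' @export
supplementary_reproduction <- function(counts, ctdna, subsample_n = 1000,
                                       k = 2, restarts = 20, seed = 1) {
  stopifnot(nrow(counts) == length(ctdna))
  x <- normalize_rows(counts)
  fit <- fl_nmf(x, k, restarts = restarts, seed = seed)
  ti <- tumor_signature_index(fit)
  grid <- matrix_lengths(counts)
  delfi <- apply(counts, 1, function(row)
    delfi_ratio(length_histogram(row, grid)))
  sub <- subsample_matrix(counts, subsample_n, seed = seed)
  fit_sub <- fl_nmf(normalize_rows(sub), k, restarts = restarts, seed = seed)
  ti_sub <- tumor_signature_index(fit_sub)
  list(nmf_correlation = correlate(fit$W[, ti], ctdna),
       delfi_correlation = correlate(delfi, ctdna),
       subsampled_correlation = correlate(fit_sub$W[, ti_sub], ctdna),
       fit = fit, tumor_index = ti)
}
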