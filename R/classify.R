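#' Area under the ROC curve (Mann--Whitney formulation)
#'
#' The probability that a randomly chosen case scores above a randomly chosen
#' control, with ties counted one half.
#'
#' @param scores numeric decision scores (higher = more case-like).
#' @param labels binary labels; a factor whose second level is the case class,
#'   a logical, or a 0/1 vector with 1 = case.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels) {
  case <- .as_case(labels)
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop_fatal("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_case <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2) stop_fatal("labels must be binary")
    labels == levels(labels)[2]
  } else as.logical(labels)
}

#' AUC of the raw tumor-signature weight
#'
#' Class separation achieved by the tumor-signature weight alone, with no
#' classifier on top.
#'
#' @param weights per-sample tumor-signature weights.
#' @param labels as in [auc()].
#' @export
weight_only_auc <- function(weights, labels) auc(weights, labels)

#' Standardize features with training-fold statistics
#'
#' Subtracts the feature mean and divides by the feature standard deviation
#' (n - 1 denominator). When `stats` from a training fold is supplied, those
#' statistics are applied instead, so held-out data never informs the
#' transform. Zero-variance features are dropped with a warning.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param stats optional list with `mean`, `sd`, `keep` from a previous call.
#' @return standardized matrix with attribute `"stats"` for reuse on test data.
#' @export
standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sdev <- apply(x, 2, stats::sd)
    keep <- sdev > 0
    if (any(!keep))
      warning("dropping zero-variance features: ",
              paste(colnames(x)[!keep] %||% which(!keep), collapse = ", "))
    stats <- list(mean = mu[keep], sd = sdev[keep], keep = keep)
  }
  out <- sweep(sweep(x[, stats$keep, drop = FALSE], 2, stats$mean), 2,
               stats$sd, "/")
  attr(out, "stats") <- stats
  out
}

# Stratified fold ids: each class distributed evenly across folds.
.stratified_folds <- function(case, folds) {
  ids <- integer(length(case))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(case == cl)
    if (length(idx) < folds)
      stop_fatal("fewer samples than folds in one class")
    ids[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  ids
}

#' Repeated stratified cross-validated AUC of a linear SVM
#'
#' Fits a linear support-vector machine on signature-weight (or per-bin
#' feature) tables under repeated stratified k-fold cross-validation. Within
#' each fold, missing features are imputed with the training-fold mean,
#' features are standardized with training-fold statistics, and held-out
#' samples are scored with the SVM decision function. One AUC is computed per
#' repeat from the pooled out-of-fold scores.
#'
#' @param x feature matrix (rows = samples, columns = features; `NA` allowed).
#' @param labels as in [auc()].
#' @param folds folds per repeat (default 10).
#' @param repeats number of repeats (default 50).
#' @param cost SVM cost parameter C (default 1; no inner tuning).
#' @param seed master seed; per-repeat fold draws derive from it.
#' @return list with `mean_auc`, `sd_auc`, `per_repeat_aucs`, `n_features`,
#'   and the settings used.
#' @export
repeated_cv_auc <- function(x, labels, folds = 10, repeats = 50, cost = 1,
                            seed = NULL) {
  x <- as.matrix(x)
  case <- .as_case(labels)
  if (min(sum(case), sum(!case)) < folds)
    stop_fatal("need at least `folds` samples per class for stratified CV")
  seeds <- derive_seeds(seed, repeats)
  per_repeat <- vapply(seq_len(repeats), function(r) {
    with_seed(seeds[[r]], {
      fold_id <- .stratified_folds(case, folds)
      scores <- numeric(nrow(x))
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        scores[!tr] <- .svm_fold_scores(x[tr, , drop = FALSE], case[tr],
                                        x[!tr, , drop = FALSE], cost)
      }
      auc(scores, case)
    })
  }, numeric(1))
  list(mean_auc = mean(per_repeat), sd_auc = stats::sd(per_repeat),
       per_repeat_aucs = per_repeat, n_features = ncol(x),
       settings = list(folds = folds, repeats = repeats, cost = cost,
                       seed = seed))
}

# Train on (x_tr, case_tr), return decision scores for x_te oriented so that
# larger = more case-like. Imputation and standardization use training
# statistics only.
.svm_fold_scores <- function(x_tr, case_tr, x_te, cost) {
  mu <- colMeans(x_tr, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  for (j in seq_len(ncol(x_tr))) {
    x_tr[is.na(x_tr[, j]), j] <- mu[j]
    x_te[is.na(x_te[, j]), j] <- mu[j]
  }
  z_tr <- standardize(x_tr)
  z_te <- standardize(x_te, stats = attr(z_tr, "stats"))
  y <- factor(ifelse(case_tr, "case", "control"),
              levels = c("control", "case"))
  fit <- e1071::svm(z_tr, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, z_te, decision.values = TRUE),
             "decision.values")
  # e1071 orients decision values toward the first label it encountered in
  # training; flip so that positive means "case".
  if (grepl("^control/", colnames(dv)[1])) -as.numeric(dv)
  else as.numeric(dv)
}
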