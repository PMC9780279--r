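# Population decoding of grating phase: standardization, stratified
# cross-validated rbf-SVM classification, f1 scoring, permutation feature
# importance.

#' Standard-score scaling with train-only statistics
#'
#' Column means and population standard deviations (divide by n) are
#' estimated on the training rows only and applied to `X_apply`:
#' z = (x - mu) / sigma. Zero-variance columns map to 0 rather than NaN.
#'
#' @param X_train Training matrix (rows = samples).
#' @param X_apply Matrix to transform (defaults to `X_train`).
#' @return List with `mu`, `sigma` (per column) and `Z`, the transformed
#'   `X_apply`.
#' @export
standardize <- function(X_train, X_apply = X_train) {
  X_train <- as.matrix(X_train)
  X_apply <- as.matrix(X_apply)
  if (nrow(X_train) == 0) stop("standardize: empty training matrix", call. = FALSE)
  mu <- colMeans(X_train)
  sigma <- sqrt(colMeans(sweep(X_train, 2, mu)^2))
  Z <- sweep(X_apply, 2, mu)
  nz <- sigma > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sigma[nz], "/")
  Z[, !nz] <- 0
  list(mu = mu, sigma = sigma, Z = Z)
}

#' f1 score from confusion counts
#'
#' Computed as TP / (TP + (FP + FN) / 2), which is algebraically identical to
#' the harmonic mean 2PR/(P+R) of precision and recall whenever the latter is
#' defined. All-zero counts give 0 with attribute `flag = "undefined"`.
#'
#' @param TP,FP,FN True positive, false positive, false negative counts.
#' @return f1 in `[0, 1]`.
#' @export
f1_from_confusion <- function(TP, FP, FN) {
  if (TP + FP + FN == 0) {
    out <- 0
    attr(out, "flag") <- "undefined"
    return(out)
  }
  TP / (TP + 0.5 * (FP + FN))
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class at the given seed, then deals fold ids
#' round-robin, preserving class proportions per fold.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated phase decoding with an rbf-kernel SVM
#'
#' Stratified k-fold cross-validation with shuffling at a fixed seed. Within
#' each fold the scaler is fit on the training part only (no leakage), an
#' rbf-kernel support vector classifier (cost C, kernel width
#' gamma = 1 / (p * var(Z_train)), the variance-scaled default) is trained,
#' and f1 is computed on the held-out part with `positive` as the positive
#' class. Optionally a single stratified holdout split can be used instead of
#' k-fold.
#'
#' @param X Repetitions x units firing-rate matrix (or `firing_rate_matrix`).
#' @param y Binary phase labels (defaults to the matrix's `phase_labels`).
#' @param folds Number of folds (default 10); reduced with a warning if a
#'   class has fewer members.
#' @param C SVM regularization constant.
#' @param seed Integer seed controlling fold shuffling.
#' @param positive Positive class label.
#' @param holdout_fraction If non-`NULL` (e.g. 0.2), evaluate on a single
#'   stratified train/test split with this test fraction instead of k-fold.
#' @return An object of class `decoding_result`: `f1_per_fold`, `f1_mean`,
#'   `f1_sd`, pooled `confusion` (TP, FP, FN, TN over all test folds), and a
#'   `config` echo.
#' @export
cross_validated_decode <- function(X, y = NULL, folds = 10L, C = 1,
                                   seed = 1L, positive = "phase1",
                                   holdout_fraction = NULL) {
  if (inherits(X, "firing_rate_matrix")) {
    if (is.null(y)) y <- X$phase_labels
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- unique(y)
  if (length(classes) < 2)
    stop("cross_validated_decode: need both phase classes in the data", call. = FALSE)
  min_class <- min(table(y))
  if (!is.null(holdout_fraction)) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    test <- logical(length(y))
    for (cl in classes) {
      idx <- sample(which(y == cl))
      test[idx[seq_len(max(1, round(holdout_fraction * length(idx))))]] <- TRUE
    }
    fold_sets <- list(which(test))
  } else {
    if (folds > min_class) {
      warning(sprintf("fold count %d exceeds smallest class size %d; using %d folds",
                      folds, min_class, min_class), call. = FALSE)
      folds <- min_class
    }
    fid <- stratified_folds(y, folds, seed)
    fold_sets <- split(seq_along(y), fid)
  }

  conf <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  f1s <- numeric(length(fold_sets))
  for (k in seq_along(fold_sets)) {
    te <- fold_sets[[k]]
    tr <- setdiff(seq_along(y), te)
    sc <- standardize(X[tr, , drop = FALSE], X[c(tr, te), , drop = FALSE])
    Ztr <- sc$Z[seq_along(tr), , drop = FALSE]
    Zte <- sc$Z[length(tr) + seq_along(te), , drop = FALSE]
    fit <- fit_rbf_svm(Ztr, y[tr], C)
    pred <- as.character(stats::predict(fit, Zte))
    ck <- confusion_counts(y[te], pred, positive)
    conf <- conf + ck
    f1s[k] <- as.numeric(f1_from_confusion(ck["TP"], ck["FP"], ck["FN"]))
  }
  structure(list(
    f1_per_fold = f1s,
    f1_mean = mean(f1s),
    f1_sd = if (length(f1s) > 1) stats::sd(f1s) else NA_real_,
    confusion = as.list(conf),
    config = list(folds = length(fold_sets), C = C, seed = seed,
                  positive = positive, holdout_fraction = holdout_fraction,
                  n_samples = nrow(X), n_units = ncol(X))
  ), class = "decoding_result")
}

fit_rbf_svm <- function(Z, y, C) {
  v <- stats::var(as.vector(Z))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(Z) * v) else 1 / ncol(Z)
  e1071::svm(x = Z, y = factor(y), kernel = "radial", cost = C,
             gamma = gamma, scale = FALSE)
}

confusion_counts <- function(truth, pred, positive) {
  c(TP = sum(pred == positive & truth == positive),
    FP = sum(pred == positive & truth != positive),
    FN = sum(pred != positive & truth == positive),
    TN = sum(pred != positive & truth != positive))
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> f1 = %.3f +/- %.3f over %d folds (%d samples, %d units)\n",
              x$f1_mean, x$f1_sd, length(x$f1_per_fold),
              x$config$n_samples, x$config$n_units))
  cat(sprintf("  confusion: TP %d FP %d FN %d TN %d\n",
              x$confusion$TP, x$confusion$FP, x$confusion$FN, x$confusion$TN))
  invisible(x)
}

#' Permutation feature importance of the phase decoder
#'
#' For each cross-validation fold, each unit's column of the held-out data is
#' shuffled `repeats` times and the drop in f1 relative to the intact fold is
#' recorded; the importance of a unit is the mean drop over repeats and
#' folds. An rbf kernel has no primal coefficients, so permutation importance
#' is the operational definition of "most informative features" here.
#'
#' @inheritParams cross_validated_decode
#' @param repeats Permutations per unit and fold.
#' @return Data frame `unit_id`, `importance`, `rank` (1 = most important),
#'   sorted by rank.
#' @export
feature_importance <- function(X, y = NULL, folds = 10L, C = 1, seed = 1L,
                               positive = "phase1", repeats = 5L) {
  unit_ids <- NULL
  if (inherits(X, "firing_rate_matrix")) {
    if (is.null(y)) y <- X$phase_labels
    unit_ids <- X$unit_ids
    X <- X$values
  }
  X <- as.matrix(X)
  if (is.null(unit_ids)) unit_ids <- colnames(X)
  if (is.null(unit_ids)) unit_ids <- sprintf("u%03d", seq_len(ncol(X)))
  if (ncol(X) < 2)
    stop("feature_importance: need at least 2 units", call. = FALSE)
  y <- as.character(y)
  folds <- min(folds, min(table(y)))
  fid <- stratified_folds(y, folds, seed)
  rng <- local_rng(seed + 1L)
  on.exit(rng(), add = TRUE)

  drops <- matrix(0, nrow = folds, ncol = ncol(X))
  for (k in seq_len(folds)) {
    te <- which(fid == k)
    tr <- which(fid != k)
    sc <- standardize(X[tr, , drop = FALSE], X[c(tr, te), , drop = FALSE])
    Ztr <- sc$Z[seq_along(tr), , drop = FALSE]
    Zte <- sc$Z[length(tr) + seq_along(te), , drop = FALSE]
    fit <- fit_rbf_svm(Ztr, y[tr], C)
    base_pred <- as.character(stats::predict(fit, Zte))
    cb <- confusion_counts(y[te], base_pred, positive)
    f1_base <- as.numeric(f1_from_confusion(cb["TP"], cb["FP"], cb["FN"]))
    for (j in seq_len(ncol(X))) {
      dj <- 0
      for (r in seq_len(repeats)) {
        Zp <- Zte
        Zp[, j] <- Zp[sample.int(nrow(Zp)), j]
        pp <- as.character(stats::predict(fit, Zp))
        cp <- confusion_counts(y[te], pp, positive)
        dj <- dj + (f1_base - as.numeric(f1_from_confusion(cp["TP"], cp["FP"], cp["FN"])))
      }
      drops[k, j] <- dj / repeats
    }
  }
  imp <- colMeans(drops)
  out <- data.frame(unit_id = unit_ids, importance = imp,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}

#' Fraction of units contributing to the decoding
#'
#' Fraction of units whose permutation importance exceeds a threshold defined
#' as a fraction of the top importance (default 5%). The threshold is echoed
#' in the result.
#'
#' @param importance Result of [feature_importance()].
#' @param threshold_fraction Fraction of the maximum importance a unit must
#'   exceed to count as contributing.
#' @return List with `fraction`, `n_contributing`, `n_units`, `threshold`.
#' @export
fraction_contributing_units <- function(importance, threshold_fraction = 0.05) {
  m <- max(importance$importance)
  if (!is.finite(m) || m <= 0)
    return(list(fraction = 0, n_contributing = 0L,
                n_units = nrow(importance), threshold = NA_real_))
  thr <- threshold_fraction * m
  n_c <- sum(importance$importance >= thr)
  list(fraction = n_c / nrow(importance), n_contributing = n_c,
       n_units = nrow(importance), threshold = thr)
}
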