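stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a meta-classifier
#'
#' Shuffles the data (governed by `seed`), splits it into `k` stratified
#' folds, and for each fold trains on the remaining k-1 folds and scores
#' accuracy on the held-out fold — the stability protocol for the ensemble
#' classifiers, with per-fold accuracy as the stability metric.
#'
#' @param spec A [model_spec()].
#' @param x Feature matrix (or `feature_matrix`).
#' @param y Binary labels or [ground_truth()].
#' @param k Number of folds (default 10).
#' @param seed Seed governing the shuffle.
#' @return An object of class `cv_result`: list with `fold_accuracy`
#'   (length `k`), `mean`, `sd`, and the fold assignment.
#' @export
cross_validate <- function(spec, x, y, k = 10, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- resolve_xy(x, y)
  x <- xy$x; y <- xy$y
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > nrow(x)) stop("`k` exceeds the number of samples", call. = FALSE)
  if (min(table(y)) < k) {
    stop("each class needs at least `k` members for stratified folds",
         call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    test <- fold == f
    fit <- fit_model(spec, x[!test, , drop = FALSE], y[!test])
    pred <- stats::predict(fit, x[test, , drop = FALSE], type = "label")
    mean(pred == (y[test] == "de"))
  }, numeric(1))
  structure(list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 fold = fold, k = k, seed = seed, spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV of %s: mean accuracy %.4f (sd %.4f)\n",
              x$k, x$spec$family, x$mean, x$sd))
  invisible(x)
}
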