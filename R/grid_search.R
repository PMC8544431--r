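#' Default hyperparameter grids
#'
#' Small per-family grids used by [random_grid_search()] when none is
#' supplied. Grids are data: a named list of candidate value vectors whose
#' names must be valid hyperparameters of the family.
#'
#' @param family One of the model families of [model_spec()].
#' @return Named list of candidate value vectors.
#' @export
default_grid <- function(family) {
  switch(
    match.arg(family, MODEL_FAMILIES),
    svm = list(cost = c(0.1, 1, 10), gamma = c(0.05, 0.1, 0.5)),
    random_forest = list(ntree = c(50, 100, 200), nodesize = c(1, 5)),
    rotation_forest = list(n_trees = c(5, 10), features_per_subset = c(2, 3)),
    xgboost = list(nrounds = c(50, 100), max_depth = c(3, 4, 6),
                   eta = c(0.1, 0.3))
  )
}

#' Random hyperparameter grid search with cross-validation
#'
#' Expands the grid, samples `n_models` combinations at random (without
#' replacement when the grid is large enough, with replacement otherwise),
#' scores each by stratified `cv_folds`-fold cross-validated accuracy, and
#' returns the best spec — highest mean CV accuracy, ties broken by the
#' earlier trial. Every trial is recorded in the log, including the number
#' of model fits it cost (`cv_folds` per trial, so the total fit count is
#' `n_models * cv_folds`).
#'
#' @param x Feature matrix (or `feature_matrix`).
#' @param y Binary labels or [ground_truth()].
#' @param family Model family to search.
#' @param grid Named list of candidate value vectors (default
#'   [default_grid()]).
#' @param n_models Number of sampled combinations (>= 1).
#' @param cv_folds Folds per trial (default 5).
#' @param seed Seed governing sampling and fold shuffles.
#' @return An object of class `grid_search`: list with `best_spec`,
#'   `best_trial`, and `log` (data.frame: trial, flattened hyperparameters,
#'   `mean_cv_accuracy`, `sd_cv_accuracy`, `n_fits`).
#' @export
random_grid_search <- function(x, y, family, grid = default_grid(family),
                               n_models = 10, cv_folds = 5, seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (!is.list(grid) || !length(grid) || is.null(names(grid)) ||
      any(!nzchar(names(grid))) || any(!lengths(grid))) {
    stop("`grid` must be a non-empty named list of candidate values",
         call. = FALSE)
  }
  bad <- setdiff(names(grid), names(HYPER_REGISTRY[[family]]))
  if (length(bad)) {
    stop(sprintf("grid names unknown for %s: %s", family,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (n_models < 1) stop("`n_models` must be >= 1", call. = FALSE)

  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  set.seed(seed)
  take <- if (n_models <= nrow(combos)) {
    sample.int(nrow(combos), n_models)
  } else {
    sample.int(nrow(combos), n_models, replace = TRUE)
  }

  log <- vector("list", n_models)
  best_score <- -Inf
  best_trial <- NA_integer_
  best_spec <- NULL
  for (i in seq_len(n_models)) {
    hp <- as.list(combos[take[i], , drop = FALSE])
    names(hp) <- names(combos)
    spec <- model_spec(family, hyper = hp,
                       seed = derive_tool_seed(seed, i))
    cv <- cross_validate(spec, x, y, k = cv_folds,
                         seed = derive_tool_seed(seed, 1000L + i))
    log[[i]] <- data.frame(trial = i, hp, mean_cv_accuracy = cv$mean,
                           sd_cv_accuracy = cv$sd, n_fits = cv_folds,
                           stringsAsFactors = FALSE)
    if (cv$mean > best_score) {
      best_score <- cv$mean
      best_trial <- i
      best_spec <- spec
    }
  }
  structure(list(best_spec = best_spec, best_trial = best_trial,
                 best_accuracy = best_score,
                 log = do.call(rbind, log), family = family, seed = seed),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %s: %d trials, best trial %d (mean CV accuracy %.4f)\n",
              x$family, nrow(x$log), x$best_trial, x$best_accuracy))
  print(x$best_spec)
  invisible(x)
}

#' Write a grid-search trial log as CSV
#'
#' @param gs A `grid_search` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(gs, path) {
  stopifnot(inherits(gs, "grid_search"))
  utils::write.csv(gs$log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
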