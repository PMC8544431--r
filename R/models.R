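MODEL_FAMILIES <- c("svm", "random_forest", "rotation_forest", "xgboost")

# Per-family hyperparameter registry: known names and defaults.
HYPER_REGISTRY <- list(
  svm = list(kernel = "radial", cost = 1, gamma = NA_real_,
             class_weight = "balanced"),
  random_forest = list(ntree = 100, mtry = NA_real_, nodesize = 1,
                       class_weight = "balanced"),
  rotation_forest = list(n_trees = 10, features_per_subset = 3,
                         class_subsample_fraction = 0.75,
                         bootstrap_fraction = 0.75,
                         class_weight = "balanced"),
  xgboost = list(nrounds = 100, max_depth = 4, eta = 0.3, subsample = 1,
                 colsample_bytree = 1, min_child_weight = 1,
                 class_weight = "balanced")
)

#' Model specification
#'
#' Names a meta-classifier family and its hyperparameters. Unknown
#' hyperparameter names are rejected against a per-family registry;
#' unspecified ones take the registry defaults.
#'
#' @param family One of `"svm"`, `"random_forest"`, `"rotation_forest"`,
#'   `"xgboost"`.
#' @param hyper Named list of hyperparameter overrides.
#' @param seed Integer seed governing the fit's randomness.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, hyper = list(), seed = 1) {
  if (length(family) != 1L || !family %in% MODEL_FAMILIES) {
    stop(sprintf("unknown model family '%s'; available: %s",
                 paste(family, collapse = ","),
                 paste(MODEL_FAMILIES, collapse = ", ")), call. = FALSE)
  }
  known <- HYPER_REGISTRY[[family]]
  bad <- setdiff(names(hyper), names(known))
  if (length(bad)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s",
                 family, paste(bad, collapse = ", ")), call. = FALSE)
  }
  full <- utils::modifyList(known, hyper)
  structure(list(family = family, hyper = full, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyper), vapply(x$hyper, format, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<model_spec> %s (%s), seed %d\n", x$family, hp, x$seed))
  invisible(x)
}

resolve_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) {
    x <- feature_values(x)
  } else {
    x <- as.matrix(x)
  }
  if (inherits(y, "ground_truth")) {
    de <- is_de(y)
    if (is.null(rownames(x))) {
      if (length(de) != nrow(x)) stop("x and ground truth sizes differ", call. = FALSE)
      y <- de
    } else {
      missing <- setdiff(rownames(x), names(de))
      if (length(missing)) {
        stop(sprintf("ground truth missing %d transcript(s)", length(missing)),
             call. = FALSE)
      }
      y <- de[rownames(x)]
    }
  }
  list(x = x, y = as_binary_labels(y))
}

guard_sd <- function(s) ifelse(s > 0, s, 1)

#' Fit a meta-classifier on a harmonized feature matrix
#'
#' Dispatches on the spec's family; every family returns scores on a
#' common orientation where larger means more evidence of differential
#' expression, in \[0, 1\]:
#' random forest and rotation forest report ensemble class probabilities;
#' XGBoost reports its logistic output; SVM decision values are mapped to
#' \[0, 1\] through a logistic link fitted on the training decision values.
#' Class imbalance is handled by per-family balanced weighting by default
#' (`class_weight` hyperparameter). If every feature is constant the fit
#' degenerates to a majority-class predictor.
#'
#' @param spec A [model_spec()].
#' @param x A `feature_matrix` from [harmonize()] or a numeric matrix.
#' @param y Binary DE labels, or a [ground_truth()] (aligned to `x` row
#'   names and collapsed to DE / not-DE).
#' @return An object of class `txensemble_model`.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- resolve_xy(x, y)
  x <- xy$x; y <- xy$y
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("labels contain a single class; need both DE and not-DE examples",
         call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  hp <- spec$hyper
  balanced <- identical(hp$class_weight, "balanced")
  meta <- list(n = nrow(x), class_counts = as.list(table(y)),
               fitted_at = format(Sys.time(), tz = "UTC"))

  if (all(apply(x, 2L, function(col) length(unique(col)) == 1L))) {
    fit <- list(type = "majority", prob = mean(y == "de"))
    return(new_model(spec, "majority", fit, colnames(x), NULL, meta))
  }

  set.seed(spec$seed)
  y01 <- as.integer(y == "de")
  model <- switch(
    spec$family,
    svm = {
      mu <- colMeans(x); sdv <- guard_sd(apply(x, 2L, stats::sd))
      xs <- scale(x, center = mu, scale = sdv)
      cw <- if (balanced) {
        tab <- table(y)
        stats::setNames(as.numeric(length(y) / (2 * tab)), names(tab))
      } else NULL
      gamma <- if (is.na(hp$gamma)) 1 / ncol(x) else hp$gamma
      fit <- e1071::svm(xs, y, kernel = hp$kernel, cost = hp$cost,
                        gamma = gamma, class.weights = cw, scale = FALSE)
      dv <- as.numeric(attr(stats::predict(fit, xs, decision.values = TRUE),
                            "decision.values"))
      link <- suppressWarnings(
        stats::glm(y01 ~ dv, family = stats::binomial()))
      new_model(spec, "svm", fit, colnames(x),
                list(scaler = list(mu = mu, sd = sdv),
                     link = stats::coef(link)), meta)
    },
    random_forest = {
      mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(x)))) else hp$mtry
      cw <- if (balanced) {
        tab <- table(y)
        as.numeric(length(y) / (2 * tab))
      } else NULL
      fit <- randomForest::randomForest(x = x, y = y, ntree = hp$ntree,
                                        mtry = mtry, nodesize = hp$nodesize,
                                        classwt = cw)
      new_model(spec, "random_forest", fit, colnames(x), NULL, meta)
    },
    rotation_forest = {
      fit <- rotation_forest(
        x, y, n_trees = hp$n_trees,
        features_per_subset = min(hp$features_per_subset, ncol(x)),
        class_subsample_fraction = hp$class_subsample_fraction,
        bootstrap_fraction = hp$bootstrap_fraction,
        class_weight = if (balanced) "balanced" else "none",
        seed = spec$seed)
      new_model(spec, "rotation_forest", fit, colnames(x), NULL, meta)
    },
    xgboost = {
      spw <- if (balanced) sum(y01 == 0) / max(1, sum(y01 == 1)) else 1
      dtrain <- xgboost::xgb.DMatrix(x, label = y01)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      min_child_weight = hp$min_child_weight,
                      scale_pos_weight = spw, nthread = 1,
                      seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
      new_model(spec, "xgboost", fit, colnames(x), NULL, meta)
    }
  )
  model
}

new_model <- function(spec, engine, fit, feature_names, extra, meta) {
  structure(list(spec = spec, engine = engine, fit = fit,
                 feature_names = feature_names, extra = extra,
                 metadata = meta),
            class = "txensemble_model")
}

align_features <- function(object, newdata) {
  ids <- NULL
  if (inherits(newdata, "feature_matrix")) {
    ids <- newdata$transcript_id
    newdata <- feature_values(newdata)
  }
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && any(nzchar(colnames(x)))) {
    missing <- setdiff(object$feature_names, colnames(x))
    extra <- setdiff(colnames(x), object$feature_names)
    if (length(missing) || length(extra)) {
      msg <- c(
        if (length(missing)) sprintf("missing: %s", paste(missing, collapse = ", ")),
        if (length(extra)) sprintf("unexpected: %s", paste(extra, collapse = ", ")))
      stop(sprintf("feature mismatch (%s)", paste(msg, collapse = "; ")),
           call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  } else if (ncol(x) != length(object$feature_names)) {
    stop("newdata has the wrong number of feature columns", call. = FALSE)
  } else {
    colnames(x) <- object$feature_names
  }
  list(x = x, ids = ids)
}

#' Predict DE evidence scores and labels
#'
#' @param object A fitted [fit_model()] object.
#' @param newdata Feature matrix with the training features; columns are
#'   aligned by name when names are present.
#' @param type `"score"` for the numeric evidence score in \[0, 1\],
#'   `"label"` for the logical DE call at the 0.5 cutoff, or `"both"` for a
#'   data.frame with both (plus `transcript_id` when available).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.txensemble_model <- function(object, newdata,
                                     type = c("score", "label", "both"), ...) {
  type <- match.arg(type)
  al <- align_features(object, newdata)
  x <- al$x
  score <- switch(
    object$engine,
    majority = rep(object$fit$prob, nrow(x)),
    svm = {
      xs <- scale(x, center = object$extra$scaler$mu,
                  scale = object$extra$scaler$sd)
      dv <- as.numeric(attr(stats::predict(object$fit, xs,
                                           decision.values = TRUE),
                            "decision.values"))
      beta <- object$extra$link
      as.numeric(stats::plogis(beta[1L] + beta[2L] * dv))
    },
    random_forest = as.numeric(
      stats::predict(object$fit, x, type = "prob")[, "de"]),
    rotation_forest = as.numeric(stats::predict(object$fit, x)),
    xgboost = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(x)))
  )
  label <- score >= 0.5
  if (!is.null(al$ids)) names(score) <- names(label) <- al$ids
  switch(type,
         score = score,
         label = label,
         both = {
           out <- data.frame(score = score, label = label)
           if (!is.null(al$ids)) {
             out <- cbind(data.frame(transcript_id = al$ids), out)
             rownames(out) <- NULL
           }
           out
         })
}

#' @export
print.txensemble_model <- function(x, ...) {
  cat(sprintf("<txensemble_model> family %s (%s engine), %d features, n = %d\n",
              x$spec$family, x$engine, length(x$feature_names), x$metadata$n))
  invisible(x)
}

#' @export
summary.txensemble_model <- function(object, ...) {
  print(object)
  cat("features:", paste(object$feature_names, collapse = ", "), "\n")
  cc <- object$metadata$class_counts
  cat(sprintf("training classes: not_de = %s, de = %s; fitted %s\n",
              cc$not_de, cc$de, object$metadata$fitted_at))
  invisible(object)
}

ARCHIVE_FORMAT <- "txensemble_model_archive"
ARCHIVE_VERSION <- 1L

#' Save / load a trained meta-classifier
#'
#' Models are persisted as a self-describing versioned archive: a manifest
#' (format tag, version, model spec, feature names, training metadata)
#' plus the fitted state. XGBoost boosters are stored in their portable
#' raw format. A loaded model predicts identically to the saved one.
#'
#' @param model A `txensemble_model`.
#' @param path File path for the archive.
#' @return `path` invisibly for the writer; the model for the reader.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "txensemble_model"))
  state <- model$fit
  if (model$engine == "xgboost") state <- xgboost::xgb.save.raw(model$fit)
  archive <- list(format = ARCHIVE_FORMAT, version = ARCHIVE_VERSION,
                  manifest = list(spec = model$spec,
                                  engine = model$engine,
                                  feature_names = model$feature_names,
                                  metadata = model$metadata),
                  extra = model$extra, state = state)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  archive <- readRDS(path)
  if (!identical(archive$format, ARCHIVE_FORMAT)) {
    stop("not a txensemble model archive", call. = FALSE)
  }
  if (archive$version > ARCHIVE_VERSION) {
    stop("archive written by a newer package version", call. = FALSE)
  }
  fit <- archive$state
  if (archive$manifest$engine == "xgboost") fit <- xgboost::xgb.load.raw(fit)
  new_model(archive$manifest$spec, archive$manifest$engine, fit,
            archive$manifest$feature_names, archive$extra,
            archive$manifest$metadata)
}
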