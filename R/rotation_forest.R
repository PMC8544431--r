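# Normalize any reasonable binary label encoding to factor(not_de, de).
# Positive class: TRUE, 1, "de", or the second level of a 2-level factor.
as_binary_labels <- function(y) {
  if (is.logical(y)) {
    out <- ifelse(y, "de", "not_de")
  } else if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    out <- ifelse(y == 1, "de", "not_de")
  } else {
    f <- as.factor(y)
    if (nlevels(f) > 2L) stop("labels must be binary", call. = FALSE)
    if (all(levels(f) %in% c("not_de", "de"))) {
      out <- as.character(f)
    } else {
      out <- ifelse(f == levels(f)[nlevels(f)], "de", "not_de")
    }
  }
  factor(out, levels = c("not_de", "de"))
}

balanced_case_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[y])
}

#' Fit a rotation forest
#'
#' Tree ensemble in which each member is trained on a rotated copy of the
#' full training set. Per tree, the features are randomly partitioned into
#' subsets of size `features_per_subset`; for each subset a principal
#' component analysis is run on a subsample of the rows (drawn, without
#' replacement, from a random subset of the classes), and the full
#' orthonormal loading matrices are assembled into a block-diagonal
#' rotation. A classification tree is then grown on the whole rotated
#' dataset. Rotations differ across trees, which is the source of ensemble
#' diversity; all principal components are retained, so each rotation is a
#' pure orthonormal change of basis and no information is discarded.
#'
#' @param x Numeric matrix or data.frame of features.
#' @param y Binary labels (logical, 0/1, or 2-level factor; positive class
#'   is `TRUE` / `1` / the second level).
#' @param n_trees Number of trees L (default 10).
#' @param features_per_subset Subset size M (default 3; clamped to the
#'   number of features).
#' @param class_subsample_fraction Probability of retaining each class when
#'   choosing the rows used to estimate a subset's PCA (default 0.75; at
#'   least one class is always retained).
#' @param bootstrap_fraction Fraction of the retained rows subsampled
#'   (without replacement) for PCA estimation (default 0.75; 1.0 uses all
#'   retained rows).
#' @param control An [rpart::rpart.control()] for the base trees; the
#'   default grows full-depth trees (`minsplit = 2`, `cp = 0`).
#' @param class_weight `"balanced"` (inverse-frequency case weights,
#'   default) or `"none"`.
#' @param seed Integer seed controlling all randomness of the fit.
#' @return An object of class `rotation_forest` with one
#'   `(rotation, tree)` pair per member.
#' @export
rotation_forest <- function(x, y, n_trees = 10, features_per_subset = 3,
                            class_subsample_fraction = 0.75,
                            bootstrap_fraction = 0.75,
                            control = NULL,
                            class_weight = c("balanced", "none"),
                            seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  y <- as_binary_labels(y)
  if (length(y) != nrow(x)) stop("`x` and `y` sizes differ", call. = FALSE)
  if (any(table(y) < 2L)) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  p <- ncol(x)
  if (features_per_subset < 1 || features_per_subset > p) {
    stop(sprintf("`features_per_subset` must be in [1, %d]", p), call. = FALSE)
  }
  if (class_subsample_fraction <= 0 || class_subsample_fraction > 1 ||
      bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    stop("fractions must be in (0, 1]", call. = FALSE)
  }
  class_weight <- match.arg(class_weight)
  if (is.null(control)) {
    control <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                    maxdepth = 30, xval = 0,
                                    maxcompete = 0, maxsurrogate = 0,
                                    usesurrogate = 0)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  w <- if (class_weight == "balanced") balanced_case_weights(y) else rep(1, length(y))
  classes <- levels(y)

  set.seed(seed)
  members <- vector("list", n_trees)
  rot_names <- paste0("RC", seq_len(p))
  for (l in seq_len(n_trees)) {
    perm <- sample.int(p)
    groups <- split(perm, ceiling(seq_along(perm) / features_per_subset))
    R <- matrix(0, p, p, dimnames = list(colnames(x), rot_names))
    off <- 0L
    for (g in groups) {
      keep_cls <- classes[stats::runif(length(classes)) <= class_subsample_fraction]
      if (!length(keep_cls)) keep_cls <- sample(classes, 1L)
      pool <- which(y %in% keep_cls)
      m <- max(2L, round(bootstrap_fraction * length(pool)))
      rows <- if (m >= length(pool)) pool else sample(pool, m)
      C <- stats::cov(x[rows, g, drop = FALSE])
      if (anyNA(C) || any(!is.finite(C))) C <- diag(length(g))
      # eigen of the covariance gives a complete orthonormal loading basis
      # even when the subset is rank-deficient (prcomp would drop columns)
      loadings <- eigen(C, symmetric = TRUE)$vectors
      R[g, off + seq_along(g)] <- loadings
      off <- off + length(g)
    }
    xr <- x %*% R
    dat <- data.frame(xr, check.names = FALSE)
    dat$.y <- y
    tree <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                         control = control)
    members[[l]] <- list(rotation = R, tree = tree)
  }
  structure(list(members = members, feature_names = colnames(x),
                 classes = classes,
                 params = list(n_trees = n_trees,
                               features_per_subset = features_per_subset,
                               class_subsample_fraction = class_subsample_fraction,
                               bootstrap_fraction = bootstrap_fraction,
                               class_weight = class_weight, seed = seed)),
            class = "rotation_forest")
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("<rotation_forest> %d trees, %d features (subsets of %d)\n",
              length(x$members), length(x$feature_names),
              x$params$features_per_subset))
  invisible(x)
}

#' Predict from a rotation forest
#'
#' @param object A [rotation_forest()] fit.
#' @param newdata Numeric matrix or data.frame with the training features
#'   (matched by name when column names are present).
#' @param ... Unused.
#' @return Numeric vector of positive-class (DE) probabilities: the mean of
#'   the member trees' class probabilities.
#' @export
predict.rotation_forest <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x))) {
    missing <- setdiff(object$feature_names, colnames(x))
    if (length(missing)) {
      stop(sprintf("missing feature column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  } else if (ncol(x) != length(object$feature_names)) {
    stop("newdata has the wrong number of columns", call. = FALSE)
  }
  probs <- vapply(object$members, function(m) {
    xr <- x %*% m$rotation
    stats::predict(m$tree, data.frame(xr, check.names = FALSE),
                   type = "prob")[, "de"]
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}
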