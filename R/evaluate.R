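as_named_logical <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("transcript_id", "de") %in% names(x))) {
      stop(sprintf("%s data.frame needs columns transcript_id and de", what),
           call. = FALSE)
    }
    stats::setNames(as.logical(x$de), as.character(x$transcript_id))
  } else if (is.logical(x)) {
    if (is.null(names(x))) stop(sprintf("%s must be named by transcript", what),
                                call. = FALSE)
    x
  } else {
    stop(sprintf("%s must be a logical vector or a data.frame", what),
         call. = FALSE)
  }
}

#' Confusion counts for DE calls
#'
#' DE (regardless of up/down regulation) is the positive class. The
#' prediction and truth must cover exactly the same transcripts; counts
#' are exact.
#'
#' @param pred Named logical vector of DE calls, or a data.frame with
#'   columns `transcript_id` and `de`.
#' @param truth A [ground_truth()] or a named logical vector.
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_named_logical(pred, "pred")
  tr <- if (inherits(truth, "ground_truth")) is_de(truth)
        else as_named_logical(truth, "truth")
  if (!setequal(names(pred), names(tr)) || length(pred) != length(tr)) {
    stop("prediction and truth transcript sets differ", call. = FALSE)
  }
  tr <- tr[names(pred)]
  structure(list(TP = sum(pred & tr), FP = sum(pred & !tr),
                 TN = sum(!pred & !tr), FN = sum(!pred & tr)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, TN %d, FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Rank-based AUC (pairwise concordance)
#'
#' Fraction of (positive, negative) pairs in which the positive outscores
#' the negative, ties counted one half — the Mann-Whitney identity,
#' computed from midranks. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores Numeric evidence scores (larger = more DE).
#' @param labels Binary labels (positive = DE).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels) == "de"
  if (length(scores) != length(y)) stop("lengths differ", call. = FALSE)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluation metrics for one method's DE calls
#'
#' The six tabulated metrics — accuracy, sensitivity, specificity, NPV,
#' PPV, AUC — plus the two directional true-positive rates: the fraction
#' of truly up-regulated transcripts called DE and the fraction of truly
#' down-regulated transcripts called DE. Zero-denominator metrics are
#' reported as `NA` (undefined), never as an error. AUC is `NA` when no
#' continuous scores are supplied.
#'
#' @param pred Named logical DE calls, or a data.frame with
#'   `transcript_id` and `de` (and optionally `score`).
#' @param truth A [ground_truth()].
#' @param scores Optional named numeric evidence scores (taken from
#'   `pred$score` when `pred` is a data.frame that has it).
#' @return Object of class `metric_report`: named list of the eight
#'   metrics plus the confusion counts.
#' @export
metric_report <- function(pred, truth, scores = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.data.frame(pred) && is.null(scores) && "score" %in% names(pred)) {
    scores <- stats::setNames(pred$score, as.character(pred$transcript_id))
  }
  pred <- as_named_logical(pred, "pred")
  cc <- confusion_counts(pred, truth)
  total <- cc$TP + cc$FP + cc$TN + cc$FN
  lab <- stats::setNames(as.character(truth$label), truth$transcript_id)[names(pred)]
  up_tp <- safe_ratio(sum(pred & lab == "up"), sum(lab == "up"))
  down_tp <- safe_ratio(sum(pred & lab == "down"), sum(lab == "down"))
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(names(scores))) {
      stop("`scores` must be named by transcript", call. = FALSE)
    }
    scores <- scores[names(pred)]
    de <- lab != "none"
    if (any(de) && any(!de)) auc <- auc_score(scores, de)
  }
  structure(list(
    accuracy = safe_ratio(cc$TP + cc$TN, total),
    sensitivity = safe_ratio(cc$TP, cc$TP + cc$FN),
    specificity = safe_ratio(cc$TN, cc$TN + cc$FP),
    npv = safe_ratio(cc$TN, cc$TN + cc$FN),
    ppv = safe_ratio(cc$TP, cc$TP + cc$FP),
    auc = auc,
    up_tp_rate = up_tp,
    down_tp_rate = down_tp,
    counts = cc), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x[METRIC_COLUMNS])
  cat("<metric_report>\n")
  print(round(c(v, up_tp_rate = x$up_tp_rate, down_tp_rate = x$down_tp_rate), 4))
  invisible(x)
}

METRIC_COLUMNS <- c("accuracy", "sensitivity", "specificity", "npv", "ppv", "auc")

check_metric_table <- function(metric_table) {
  if (!is.data.frame(metric_table) || !"method" %in% names(metric_table)) {
    stop("metric table must be a data.frame with a `method` column",
         call. = FALSE)
  }
  nm <- stats::setNames(names(metric_table), tolower(names(metric_table)))
  missing <- setdiff(METRIC_COLUMNS, names(nm))
  if (length(missing)) {
    stop(sprintf("metric table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(method = as.character(metric_table$method))
  for (m in METRIC_COLUMNS) out[[m]] <- as.numeric(metric_table[[nm[[m]]]])
  out
}

# descending rank with ties broken by row order (stable)
rank_desc_stable <- function(v) {
  o <- order(-v, seq_along(v))
  r <- integer(length(v)); r[o] <- seq_along(v)
  r
}

#' Rank methods across the six evaluation metrics
#'
#' Within each metric, methods are ranked by descending value (1 = best)
#' with ties broken by input row order; each method's aggregated score is
#' its rank-sum divided by the number of methods. Output rows are sorted
#' ascending by score, ties again by input row order. Methods with an
#' undefined (NA) metric are excluded with a warning: they cannot receive
#' a comparable rank-sum.
#'
#' @param metric_table data.frame with a `method` column and the six
#'   metric columns `accuracy`, `sensitivity`, `specificity`, `npv`,
#'   `ppv`, `auc` (case-insensitive).
#' @return Object of class `rank_table`: data.frame with `method`, one
#'   rank column per metric, and `score`.
#' @export
rank_methods <- function(metric_table) {
  tab <- check_metric_table(metric_table)
  if (nrow(tab) < 2L) stop("need at least 2 methods to rank", call. = FALSE)
  bad <- !stats::complete.cases(tab[METRIC_COLUMNS])
  if (any(bad)) {
    warning(sprintf("excluding method(s) with undefined metrics: %s",
                    paste(tab$method[bad], collapse = ", ")), call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
    if (nrow(tab) < 2L) stop("fewer than 2 methods with defined metrics",
                             call. = FALSE)
  }
  ranks <- vapply(tab[METRIC_COLUMNS], rank_desc_stable, integer(nrow(tab)))
  score <- rowSums(ranks) / nrow(tab)
  out <- data.frame(method = tab$method, ranks, score = score)
  out <- out[order(score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' @export
print.rank_table <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$score <- round(shown$score, 1)
  print(shown)
  invisible(x)
}

#' Best method per metric
#'
#' Argmax per metric column, ties broken by input row order.
#'
#' @inheritParams rank_methods
#' @return Named character vector: winning method per metric.
#' @export
best_per_metric <- function(metric_table) {
  tab <- check_metric_table(metric_table)
  vapply(METRIC_COLUMNS, function(m) {
    v <- tab[[m]]
    tab$method[which.max(ifelse(is.na(v), -Inf, v))]
  }, character(1))
}

#' Bundled ten-method benchmark metric table
#'
#' A published benchmark of six DIEA pipelines and four ML integrations
#' (accuracy, sensitivity, specificity, NPV, PPV, AUC on simulated mouse
#' data), shipped as example input for [rank_methods()] and
#' [best_per_metric()].
#'
#' @return data.frame with columns `method` and the six metrics, rows in
#'   the benchmark's original order.
#' @export
benchmark_metric_table <- function() {
  path <- system.file("extdata", "benchmark_metrics.tsv",
                      package = "txensemble", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t")
}
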