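gt_from_logical <- function(de) {
  ground_truth(names(de), ifelse(de, "up", "none"))
}

test_that("confusion counts match hand-worked cases", {
  ids <- paste0("t", 1:10)
  truth <- ground_truth(ids, c(rep("up", 3), rep("none", 7)))
  pred <- setNames(c(rep(TRUE, 3), rep(FALSE, 7)), ids)
  cc <- confusion_counts(pred, truth)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 3L, TN = 7L, FP = 0L, FN = 0L))

  cc2 <- confusion_counts(!pred, truth)
  expect_equal(cc2$TP, 0L)
  expect_equal(cc2$TN, 0L)

  ids5 <- paste0("t", 1:5)
  truth5 <- ground_truth(ids5, c("up", "none", "down", "none", "none"))
  pred5 <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), ids5)
  cc3 <- confusion_counts(pred5, truth5)
  expect_equal(unlist(cc3[c("TP", "FP", "FN", "TN")]),
               c(TP = 1L, FP = 1L, FN = 1L, TN = 2L))

  expect_error(confusion_counts(pred5[1:4], truth5), "differ")
})

test_that("metric reports match hand arithmetic and flag undefined ratios", {
  ids5 <- paste0("t", 1:5)
  truth5 <- ground_truth(ids5, c("up", "none", "down", "none", "none"))
  pred5 <- setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), ids5)
  rep5 <- metric_report(pred5, truth5)
  expect_equal(rep5$sensitivity, 0.5)
  expect_equal(rep5$specificity, 2 / 3)
  expect_equal(rep5$ppv, 0.5)
  expect_equal(rep5$npv, 2 / 3)
  expect_equal(rep5$accuracy, 0.6)
  expect_equal(rep5$up_tp_rate, 1.0)
  expect_equal(rep5$down_tp_rate, 0.0)

  # perfect predictions
  perfect <- metric_report(setNames(truth5$label != "none", ids5), truth5,
                           scores = setNames(c(1, 0, 1, 0, 0), ids5))
  for (m in c("accuracy", "sensitivity", "specificity", "npv", "ppv", "auc",
              "up_tp_rate", "down_tp_rate")) {
    expect_equal(perfect[[m]], 1.0, info = m)
  }

  # no positives predicted: PPV undefined, specificity 1
  none_called <- metric_report(setNames(rep(FALSE, 5), ids5), truth5)
  expect_true(is.na(none_called$ppv))
  expect_equal(none_called$specificity, 1.0)
})

test_that("metrics agree with a brute-force recount on random instances", {
  set.seed(99)
  for (n in c(50, 1000, 10000)) {
    ids <- sprintf("x%05d", seq_len(n))
    de <- runif(n) < 0.2
    truth <- ground_truth(ids, ifelse(de, sample(c("up", "down"), n, TRUE), "none"))
    pred <- setNames(runif(n) < 0.3, ids)
    rep <- metric_report(pred, truth)
    # element-wise recount, no confusion-matrix shortcut
    tp <- sum(pred & de); tn <- sum(!pred & !de)
    fp <- sum(pred & !de); fn <- sum(!pred & de)
    expect_equal(rep$accuracy, (tp + tn) / n)
    expect_equal(rep$sensitivity, tp / (tp + fn))
    expect_equal(rep$specificity, tn / (tn + fp))
    expect_equal(rep$ppv, tp / (tp + fp))
    expect_equal(rep$npv, tn / (tn + fn))
  }
})

test_that("AUC matches pair enumeration, handles ties, and is rank-invariant", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.9, 0.4, 0.8, 0.3), c(1, 0, 0, 1)), 0.5)
  expect_equal(auc_score(rep(0.7, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")

  auc_oracle <- function(s, y) {  # exhaustive pair enumeration
    pos <- s[y]; neg <- s[!y]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(42)
  for (i in 1:5) {
    n <- 400
    y <- runif(n) < 0.3
    y[1:2] <- c(TRUE, FALSE)
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auc_score(s, y), auc_oracle(s, y))
    # invariance under a strictly monotone transform
    expect_equal(auc_score(exp(3 * s), y), auc_score(s, y))
    # third route: an independent ROC implementation agrees
    expect_equal(auc_score(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("rank_methods orders two methods deterministically", {
  tab <- data.frame(method = c("A", "B"),
                    accuracy = c(0.9, 0.8), sensitivity = c(0.9, 0.8),
                    specificity = c(0.9, 0.8), npv = c(0.9, 0.8),
                    ppv = c(0.9, 0.8), auc = c(0.9, 0.8))
  rt <- rank_methods(tab)
  expect_equal(rt$method, c("A", "B"))
  expect_equal(rt$score, c(6 / 2, 12 / 2))
  expect_error(rank_methods(tab[1, ]), "at least 2")
  expect_error(rank_methods(tab[, -2]), "missing column")
})

test_that("rank scores ignore metric column order and monotone rescaling", {
  tab <- benchmark_metric_table()
  base <- rank_methods(tab)
  shuffled <- tab[, c("method", "auc", "ppv", "accuracy", "npv",
                      "specificity", "sensitivity")]
  expect_equal(rank_methods(shuffled)$score, base$score)
  rescaled <- tab
  rescaled$accuracy <- 100 * rescaled$accuracy
  rescaled$auc <- rescaled$auc^3
  expect_equal(rank_methods(rescaled)$score, base$score)
})

test_that("methods with undefined metrics are excluded with a warning", {
  tab <- benchmark_metric_table()
  tab$ppv[3] <- NA
  expect_warning(rt <- rank_methods(tab), tab$method[3])
  expect_false(tab$method[3] %in% rt$method)
  expect_equal(nrow(rt), 9L)
})

test_that("best_per_metric takes the argmax with row-order ties", {
  tab <- data.frame(method = c("A", "B"),
                    accuracy = c(0.9, 0.9), sensitivity = c(0.1, 0.9),
                    specificity = c(0.9, 0.8), npv = c(0.5, 0.5),
                    ppv = c(0.2, 0.8), auc = c(0.9, 0.2))
  best <- best_per_metric(tab)
  expect_equal(unname(best["accuracy"]), "A")  # tie -> earlier row
  expect_equal(unname(best["sensitivity"]), "B")
  single <- best_per_metric(tab[2, ])
  expect_true(all(single == "B"))
})

test_that("cross-validation folds partition the data and score in [0, 1]", {
  sim <- small_sim(n = 600, n_de = 60, seed = 3)
  d <- sim_xy(sim)
  spec <- model_spec("xgboost", list(nrounds = 10), seed = 1)
  cv <- cross_validate(spec, d$x, d$y, k = 5, seed = 8)
  expect_length(cv$fold_accuracy, 5L)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(length(cv$fold), nrow(d$x))     # disjoint folds covering all
  # stratification: every fold holds both classes
  for (f in 1:5) expect_equal(sort(unique(d$y[cv$fold == f])), c(FALSE, TRUE))
  expect_error(cross_validate(spec, d$x, d$y, k = nrow(d$x) + 1), "exceeds")
  expect_error(cross_validate(spec, d$x, d$y, k = 100), "at least")
})
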