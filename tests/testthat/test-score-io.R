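test_that("tool tables parse from TSV with family-specific schemas", {
  path <- write_tsv_text(c("transcript_id\tpvalue\tqvalue",
                           "t1\t0.01\t0.03", "t2\t0.5\t0.75", "t3\t1.0\t1.0"))
  tab <- read_tool_table(path, "toolA", "PQ")
  expect_s3_class(tab, "tool_score_table")
  expect_equal(nrow(tab$scores), 3L)
  expect_equal(tab$metric_family, "PQ")
  expect_equal(tab$scores$pvalue, c(0.01, 0.5, 1.0))

  # a PPLR file has no qvalue column and that is fine
  pplr_path <- write_tsv_text(c("transcript_id\tpplr", "t1\t0.9", "t2\t0.5"))
  pplr <- read_tool_table(pplr_path, "toolB", "PPLR")
  expect_equal(pplr$scores$pplr, c(0.9, 0.5))
})

test_that("invalid tool tables are rejected with informative errors", {
  # score outside [0, 1]
  bad_range <- write_tsv_text(c("transcript_id\tpvalue\tqvalue",
                                "t1\t1.5\t0.5"))
  expect_error(read_tool_table(bad_range, "toolA", "PQ"), "outside \\[0, 1\\]")

  # missing required column, named in the message
  no_q <- write_tsv_text(c("transcript_id\tpvalue", "t1\t0.5"))
  expect_error(read_tool_table(no_q, "toolA", "PQ"), "qvalue")

  # duplicate transcript
  dup <- write_tsv_text(c("transcript_id\tppde", "t1\t0.5", "t1\t0.6"))
  expect_error(read_tool_table(dup, "toolA", "PPDE"), "duplicated")

  # non-numeric score with its line number
  nn <- write_tsv_text(c("transcript_id\tppde", "t1\t0.5", "t2\tabc"))
  expect_error(read_tool_table(nn, "toolA", "PPDE"), "line 3")
})

test_that("tool tables round-trip through write_tool_table", {
  tab <- make_pq_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tool_table(tab, path)
  back <- read_tool_table(path, tab$tool_name, tab$metric_family)
  expect_equal(back$scores, tab$scores)
})

test_that("ground truth validates labels and round-trips", {
  gt <- ground_truth(c("a", "b", "c"), c("up", "down", "none"))
  expect_equal(as.vector(table(gt$label)), c(1L, 1L, 1L))
  expect_equal(is_de(gt), c(a = TRUE, b = TRUE, c = FALSE))
  expect_error(ground_truth(c("a", "a"), c("up", "up")), "duplicated")
  expect_error(ground_truth("a", "sideways"), "invalid")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(gt, path)
  expect_equal(read_ground_truth(path), gt)
})

test_that("harmonize derives the documented per-family features", {
  ids <- c("t1", "t2", "t3")
  tabs <- list(
    make_pq_table(ids = ids, p = c(0.01, 0.5, 1.0), q = c(0.03, 0.75, 1.0)),
    make_ppde_table(ids = ids, ppde = c(0.99, 0.5, 0.01)),
    make_pplr_table(ids = ids, pplr = c(1.0, 0.5, 0.3))
  )
  fm <- harmonize(tabs, ids)
  x <- feature_values(fm)
  expect_equal(nrow(x), 3L)
  # -log10(0.01) = 2 exactly
  expect_equal(unname(x["t1", "pq_tool_neglog10_p"]), 2.0)
  expect_equal(unname(x["t3", "pq_tool_neglog10_p"]), 0.0)
  # PPDE passes through
  expect_equal(unname(x[, "ppde_tool_ppde"]), c(0.99, 0.5, 0.01))
  # PPLR folding: 0.5 is the symmetry point, 1.0 the boundary
  expect_equal(unname(x["t2", "pplr_tool_evidence"]), 0.0)
  expect_equal(unname(x["t2", "pplr_tool_direction"]), 0.0)
  expect_equal(unname(x["t1", "pplr_tool_evidence"]), 1.0)
  expect_equal(unname(x["t1", "pplr_tool_direction"]), 1.0)
  expect_equal(unname(x["t3", "pplr_tool_evidence"]), 0.4)
  expect_equal(unname(x["t3", "pplr_tool_direction"]), -1.0)
})

test_that("the -log10 cap keeps p = 0 finite", {
  tab <- make_pq_table(ids = "t1", p = 0, q = 0)
  fm <- harmonize(list(tab), "t1", harmonize_policy(cap = 10))
  expect_equal(unname(feature_values(fm)[1, ]), c(10, 10))
})

test_that("harmonize is invariant to table order and imputes missing transcripts", {
  ids <- c("t1", "t2", "t3", "t4")
  tabs <- list(make_pq_table(ids = ids[1:3]), make_ppde_table(ids = ids[c(1, 3, 4)]),
               make_pplr_table(ids = ids[1:3]))
  fm1 <- harmonize(tabs, ids)
  fm2 <- harmonize(rev(tabs), ids)
  expect_identical(fm1, fm2)

  x <- feature_values(fm1)
  # t4 absent from PQ and PPLR tools: no-evidence imputation
  expect_equal(unname(x["t4", c("pq_tool_neglog10_p", "pq_tool_neglog10_q")]),
               c(0, 0))
  expect_equal(unname(x["t4", c("pplr_tool_evidence", "pplr_tool_direction")]),
               c(0, 0))
  # t2 absent from the PPDE tool
  expect_equal(unname(x["t2", "ppde_tool_ppde"]), 0)

  expect_error(harmonize(tabs, ids, harmonize_policy(impute = FALSE)),
               "forbids imputation")
  expect_error(harmonize(list(), ids), "non-empty")
  expect_error(harmonize(tabs, character(0)), "non-empty")
})

test_that("binarize_tool applies inclusive family cutoffs", {
  pq <- make_pq_table(ids = c("a", "b"), p = c(0.001, 0.2), q = c(0.04, 0.5))
  b <- binarize_tool(pq, de_thresholds(q_cut = 0.05))
  expect_equal(b$de, c(TRUE, FALSE))

  ppde <- make_ppde_table(ids = c("a", "b"), ppde = c(0.95, 0.94))
  b <- binarize_tool(ppde, de_thresholds(ppde_cut = 0.95))
  expect_equal(b$de, c(TRUE, FALSE))  # boundary is inclusive

  pplr <- make_pplr_table(ids = "a", pplr = 0.30)
  b <- binarize_tool(pplr, de_thresholds(pplr_evidence_cut = 0.9))
  expect_false(b$de)
  expect_equal(b$score, 0.4)

  expect_error(de_thresholds(q_cut = 1.5), "\\[0, 1\\]")
})

test_that("DE counts are non-increasing as cutoffs tighten", {
  set.seed(31)
  n <- 400
  ids <- sprintf("t%03d", seq_len(n))
  p <- runif(n)^2
  tabs <- list(
    make_pq_table(ids = ids, p = p),
    make_ppde_table(ids = ids, ppde = runif(n)),
    make_pplr_table(ids = ids, pplr = runif(n))
  )
  q_cuts <- seq(0.5, 0.01, length.out = 8)
  ppde_cuts <- seq(0.5, 0.99, length.out = 8)
  ev_cuts <- seq(0.1, 0.95, length.out = 8)
  for (tab in tabs) {
    counts <- vapply(seq_along(q_cuts), function(i) {
      th <- de_thresholds(q_cut = q_cuts[i], ppde_cut = ppde_cuts[i],
                          pplr_evidence_cut = ev_cuts[i])
      sum(binarize_tool(tab, th)$de)
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("imputed transcripts always binarize to not-DE", {
  ids <- c("seen", "unseen")
  tabs <- list(make_pq_table(ids = "seen", p = 0.001, q = 0.001),
               make_ppde_table(ids = "seen", ppde = 0.99),
               make_pplr_table(ids = "seen", pplr = 0.99))
  x <- feature_values(harmonize(tabs, ids))
  set.seed(11)
  for (i in 1:20) {
    th <- de_thresholds(q_cut = runif(1, 0.01, 0.5),
                        ppde_cut = runif(1, 0.5, 0.99),
                        pplr_evidence_cut = runif(1, 0.1, 0.95))
    # imputed q = 1 -> neglog10 q = 0 < -log10(q_cut); ppde = 0; evidence = 0
    expect_lt(x["unseen", "pq_tool_neglog10_q"], -log10(th$q_cut))
    expect_lt(x["unseen", "ppde_tool_ppde"], th$ppde_cut)
    expect_lt(x["unseen", "pplr_tool_evidence"], th$pplr_evidence_cut)
  }
})

test_that("feature matrices round-trip through CSV", {
  sim <- small_sim(n = 50, n_de = 10)
  fm <- harmonize(sim$tables, sim$truth$transcript_id)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(feature_values(back), feature_values(fm), tolerance = 1e-12)
})
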