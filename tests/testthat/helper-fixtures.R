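# Small in-code fixtures shared across test files.

make_pq_table <- function(tool = "pq_tool",
                          ids = c("t1", "t2", "t3"),
                          p = c(0.01, 0.5, 1.0),
                          q = NULL) {
  if (is.null(q)) q <- bh_adjust(p)
  tool_score_table(tool, "PQ",
                   data.frame(transcript_id = ids, pvalue = p, qvalue = q))
}

make_ppde_table <- function(tool = "ppde_tool",
                            ids = c("t1", "t2", "t3"),
                            ppde = c(0.99, 0.5, 0.01)) {
  tool_score_table(tool, "PPDE",
                   data.frame(transcript_id = ids, ppde = ppde))
}

make_pplr_table <- function(tool = "pplr_tool",
                            ids = c("t1", "t2", "t3"),
                            pplr = c(0.99, 0.5, 0.01)) {
  tool_score_table(tool, "PPLR",
                   data.frame(transcript_id = ids, pplr = pplr))
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Two Gaussian blobs in 2-D, labelled by blob.
make_blobs <- function(n = 200, separation = 10, sd = 1, seed = 42, p = 2) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(
    matrix(rnorm(half * p, 0, sd), ncol = p),
    matrix(rnorm((n - half) * p, separation, sd), ncol = p)
  )
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c(FALSE, TRUE), c(half, n - half)))
}

# Small simulated dataset: keeps the Set2 DE prevalence (5%) at desk scale.
small_sim <- function(n = 2000, n_de = 100, seed = 7, ...) {
  simulate_scores(sim_config(n_transcripts = n, n_de = n_de, seed = seed, ...))
}

sim_xy <- function(sim) {
  fm <- harmonize(sim$tables, sim$truth$transcript_id)
  list(fm = fm, x = feature_values(fm), y = is_de(sim$truth))
}
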