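#' Harmonization policy
#'
#' Controls how heterogeneous tool scores are mapped onto a common
#' "larger = more evidence of DE" scale and how transcripts missing from a
#' tool's output are handled.
#'
#' Derived features per family:
#' \itemize{
#'   \item PQ: `-log10(pvalue)` and `-log10(qvalue)`, capped at `cap` so
#'     p = 0 maps to the cap rather than infinity;
#'   \item PPDE: the posterior probability passed through unchanged;
#'   \item PPLR: folded evidence `2 * |pplr - 0.5|` in \[0, 1\] plus a
#'     separate signed direction feature `sign(pplr - 0.5)`.
#' }
#'
#' Missing transcripts receive a tool's "no evidence" values before the
#' transform: p = q = 1, ppde = 0, pplr = 0.5 (absence of a call is absence
#' of evidence). Set `impute = FALSE` to instead require every tool to
#' cover the full universe.
#'
#' @param cap Cap for the `-log10` transforms (default 10).
#' @param impute Impute no-evidence values for missing transcripts?
#' @return An object of class `harmonize_policy`.
#' @export
harmonize_policy <- function(cap = 10, impute = TRUE) {
  stopifnot(is.numeric(cap), length(cap) == 1L)
  if (cap <= 0) stop("`cap` must be positive", call. = FALSE)
  structure(list(cap = cap, impute = isTRUE(impute)),
            class = "harmonize_policy")
}

neglog10_capped <- function(x, cap) pmin(-log10(pmax(x, 10^(-cap))), cap)

tool_feature_frame <- function(table, universe, policy) {
  idx <- match(universe, table$scores$transcript_id)
  if (!policy$impute && anyNA(idx)) {
    stop(sprintf("tool '%s' is missing %d universe transcript(s) and the policy forbids imputation",
                 table$tool_name, sum(is.na(idx))), call. = FALSE)
  }
  get <- function(col, fill) {
    v <- table$scores[[col]][idx]
    v[is.na(idx)] <- fill
    v
  }
  tn <- table$tool_name
  out <- switch(
    table$metric_family,
    PQ = {
      p <- get("pvalue", 1)
      q <- get("qvalue", 1)
      stats::setNames(
        data.frame(neglog10_capped(p, policy$cap), neglog10_capped(q, policy$cap)),
        paste0(tn, c("_neglog10_p", "_neglog10_q")))
    },
    PPDE = stats::setNames(data.frame(get("ppde", 0)), paste0(tn, "_ppde")),
    PPLR = {
      pplr <- get("pplr", 0.5)
      stats::setNames(
        data.frame(2 * abs(pplr - 0.5), sign(pplr - 0.5)),
        paste0(tn, c("_evidence", "_direction")))
    }
  )
  out
}

#' Harmonize heterogeneous tool scores into a feature matrix
#'
#' Builds one feature vector per transcript of the universe by applying the
#' policy's per-family transforms to every tool's scores (see
#' [harmonize_policy()]). The result feeds the meta-classifiers.
#'
#' @param tables Non-empty list of [tool_score_table()] objects.
#' @param universe Ordered character vector of transcript identifiers; one
#'   output row per element.
#' @param policy A [harmonize_policy()].
#' @return An object of class `feature_matrix`: a data.frame with a
#'   `transcript_id` column followed by one column per derived feature,
#'   with the policy stored in the `"policy"` attribute.
#' @export
harmonize <- function(tables, universe, policy = harmonize_policy()) {
  if (!length(tables)) stop("`tables` must be a non-empty list", call. = FALSE)
  if (!length(universe)) stop("`universe` must be non-empty", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "tool_score_table")),
            inherits(policy, "harmonize_policy"))
  universe <- as.character(universe)
  tool_names <- vapply(tables, `[[`, character(1), "tool_name")
  if (anyDuplicated(tool_names)) {
    stop("duplicated tool names across tables", call. = FALSE)
  }
  # canonical column order: tools sorted by name, so the matrix does not
  # depend on the order tables are supplied in
  tables <- tables[order(tool_names)]
  feats <- do.call(cbind, lapply(tables, tool_feature_frame,
                                 universe = universe, policy = policy))
  out <- cbind(data.frame(transcript_id = universe), feats)
  attr(out, "policy") <- policy
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Extract the numeric value matrix of a feature matrix
#'
#' @param fm A `feature_matrix` from [harmonize()].
#' @return Numeric matrix with transcript identifiers as row names.
#' @export
feature_values <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- as.matrix(fm[, setdiff(names(fm), "transcript_id"), drop = FALSE])
  rownames(m) <- fm$transcript_id
  m
}

#' Write / read a feature matrix as CSV
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `feature_matrix` for the
#'   reader (with a default-policy attribute).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!"transcript_id" %in% names(raw)) {
    stop(sprintf("%s: missing transcript_id column", path), call. = FALSE)
  }
  raw$transcript_id <- as.character(raw$transcript_id)
  attr(raw, "policy") <- harmonize_policy()
  class(raw) <- c("feature_matrix", "data.frame")
  raw
}

#' Per-family binarization cutoffs
#'
#' Default cutoffs for calling a transcript DE from a single tool's output:
#' q-value at or below 0.05 (PQ), PPDE at or above 0.95, folded PPLR
#' evidence `2|pplr - 0.5|` at or above 0.9. All comparisons are inclusive
#' at the boundary.
#'
#' @param q_cut q-value cutoff for PQ tools.
#' @param ppde_cut PPDE cutoff.
#' @param pplr_evidence_cut folded-PPLR evidence cutoff.
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(q_cut = 0.05, ppde_cut = 0.95,
                          pplr_evidence_cut = 0.9) {
  vals <- c(q_cut = q_cut, ppde_cut = ppde_cut,
            pplr_evidence_cut = pplr_evidence_cut)
  if (any(!is.finite(vals) | vals < 0 | vals > 1)) {
    stop("all cutoffs must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "de_thresholds")
}

#' Binarize one tool's scores into DE / not-DE calls
#'
#' Applies the family-appropriate cutoff: PQ tools call DE when
#' `qvalue <= q_cut`; PPDE tools when `ppde >= ppde_cut`; PPLR tools when
#' `2|pplr - 0.5| >= pplr_evidence_cut`. The returned continuous score is
#' the tool's harmonized evidence feature (capped `-log10(q)` for PQ, the
#' PPDE, or the folded PPLR evidence), so AUC is computable per tool.
#'
#' @param table A [tool_score_table()].
#' @param thresholds A [de_thresholds()].
#' @param policy A [harmonize_policy()] (controls the score cap).
#' @return data.frame with columns `transcript_id`, `de` (logical),
#'   `score`.
#' @export
binarize_tool <- function(table, thresholds = de_thresholds(),
                          policy = harmonize_policy()) {
  stopifnot(inherits(table, "tool_score_table"),
            inherits(thresholds, "de_thresholds"))
  s <- table$scores
  res <- switch(
    table$metric_family,
    PQ = data.frame(transcript_id = s$transcript_id,
                    de = s$qvalue <= thresholds$q_cut,
                    score = neglog10_capped(s$qvalue, policy$cap)),
    PPDE = data.frame(transcript_id = s$transcript_id,
                      de = s$ppde >= thresholds$ppde_cut,
                      score = s$ppde),
    PPLR = {
      ev <- 2 * abs(s$pplr - 0.5)
      data.frame(transcript_id = s$transcript_id,
                 de = ev >= thresholds$pplr_evidence_cut,
                 score = ev)
    }
  )
  res
}
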