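# Score columns implied by each metric family. PQ tools report a p-value and
# an FDR-adjusted q-value; PPDE tools a posterior probability of differential
# expression; PPLR tools the probability of a positive log ratio.
FAMILY_COLUMNS <- list(
  PQ   = c("pvalue", "qvalue"),
  PPDE = "ppde",
  PPLR = "pplr"
)

METRIC_FAMILIES <- names(FAMILY_COLUMNS)

#' Per-tool transcript significance table
#'
#' Container for one DIEA tool's per-transcript output. Different tool
#' families report different significance metrics: `PQ` tools report
#' `pvalue` and `qvalue`, `PPDE` tools report `ppde`, and `PPLR` tools
#' report `pplr` (0.5 = no evidence; near 0/1 = down-/up-regulation).
#' All scores must lie in \[0, 1\] and transcript identifiers must be
#' unique. An optional `direction_signal` column carries a signed effect
#' estimate.
#'
#' @param tool_name Identifier of the tool that produced the scores.
#' @param metric_family One of `"PQ"`, `"PPDE"`, `"PPLR"`.
#' @param scores A data.frame with a `transcript_id` column plus the
#'   family's score columns, optionally `direction_signal`.
#' @return An object of class `tool_score_table`.
#' @export
tool_score_table <- function(tool_name, metric_family, scores) {
  stopifnot(is.character(tool_name), length(tool_name) == 1L, nzchar(tool_name))
  metric_family <- match.arg(metric_family, METRIC_FAMILIES)
  if (!is.data.frame(scores)) {
    stop("`scores` must be a data.frame", call. = FALSE)
  }
  required <- c("transcript_id", FAMILY_COLUMNS[[metric_family]])
  missing <- setdiff(required, names(scores))
  if (length(missing)) {
    stop(sprintf("tool '%s': missing required column(s): %s",
                 tool_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  scores$transcript_id <- as.character(scores$transcript_id)
  dup <- scores$transcript_id[duplicated(scores$transcript_id)]
  if (length(dup)) {
    stop(sprintf("tool '%s': duplicated transcript_id(s): %s",
                 tool_name, paste(utils::head(unique(dup), 5L), collapse = ", ")),
         call. = FALSE)
  }
  for (col in FAMILY_COLUMNS[[metric_family]]) {
    v <- scores[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("tool '%s': column '%s' is not numeric", tool_name, col),
           call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad)) {
      stop(sprintf("tool '%s': column '%s' has value(s) outside [0, 1] at row(s) %s",
                   tool_name, col,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  keep <- intersect(c("transcript_id", FAMILY_COLUMNS[[metric_family]],
                      "direction_signal"), names(scores))
  structure(
    list(tool_name = tool_name,
         metric_family = metric_family,
         scores = scores[, keep, drop = FALSE]),
    class = "tool_score_table"
  )
}

#' @export
print.tool_score_table <- function(x, ...) {
  cat(sprintf("<tool_score_table> %s (%s family), %d transcripts\n",
              x$tool_name, x$metric_family, nrow(x$scores)))
  print(utils::head(x$scores, 4L))
  invisible(x)
}

#' Read one tool's score table from a delimited text file
#'
#' Expects tab-separated text with a header row naming `transcript_id` and
#' the score columns of the tool's metric family. Rows with scores outside
#' \[0, 1\], duplicated transcript identifiers, or non-numeric scores are
#' rejected with an informative error.
#'
#' @param path Path to the TSV file.
#' @param tool_name Tool identifier to attach to the table.
#' @param metric_family One of `"PQ"`, `"PPDE"`, `"PPLR"`.
#' @return A [tool_score_table()].
#' @export
read_tool_table <- function(path, tool_name, metric_family) {
  metric_family <- match.arg(metric_family, METRIC_FAMILIES)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("transcript_id", FAMILY_COLUMNS[[metric_family]])
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), "transcript_id")
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      # +1 for the header row: report the physical line in the file
      stop(sprintf("%s: non-numeric value '%s' in column '%s' at line %d",
                   path, raw[[col]][bad[1L]], col, bad[1L] + 1L), call. = FALSE)
    }
    raw[[col]] <- v
  }
  tool_score_table(tool_name, metric_family, raw)
}

#' Write a tool score table as tab-separated text
#'
#' @param table A [tool_score_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tool_table <- function(table, path) {
  stopifnot(inherits(table, "tool_score_table"))
  utils::write.table(table$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

GT_LEVELS <- c("none", "up", "down")

#' Ground-truth differential-expression labels
#'
#' Per-transcript label in `{none, up, down}` describing the simulated (or
#' otherwise known) condition. `up`/`down` transcripts are differentially
#' expressed; `none` transcripts are not.
#'
#' @param transcript_id Character vector of unique transcript identifiers.
#' @param label Character or factor vector in `{none, up, down}`.
#' @return An object of class `ground_truth`: a data.frame with columns
#'   `transcript_id` and `label`.
#' @export
ground_truth <- function(transcript_id, label) {
  transcript_id <- as.character(transcript_id)
  if (anyDuplicated(transcript_id)) {
    stop("duplicated transcript_id in ground truth", call. = FALSE)
  }
  label <- as.character(label)
  bad <- setdiff(unique(label), GT_LEVELS)
  if (length(bad)) {
    stop(sprintf("invalid ground-truth label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (length(label) != length(transcript_id)) {
    stop("transcript_id and label lengths differ", call. = FALSE)
  }
  structure(
    data.frame(transcript_id = transcript_id,
               label = factor(label, levels = GT_LEVELS)),
    class = c("ground_truth", "data.frame")
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<ground_truth> %d transcripts (%d up, %d down, %d none)\n",
              nrow(x), tab[["up"]], tab[["down"]], tab[["none"]]))
  invisible(x)
}

#' Collapse ground truth to a logical DE indicator
#'
#' @param truth A [ground_truth()] object.
#' @return Named logical vector, `TRUE` for transcripts labelled up or down.
#' @export
is_de <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  stats::setNames(truth$label != "none", truth$transcript_id)
}

#' Read / write ground-truth labels as tab-separated text
#'
#' Files have a header row with columns `transcript_id` and `label`.
#'
#' @param path File path.
#' @return [ground_truth()] for the reader; `path` invisibly for the writer.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  missing <- setdiff(c("transcript_id", "label"), names(raw))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  ground_truth(raw$transcript_id, raw$label)
}

#' @rdname read_ground_truth
#' @param truth A [ground_truth()] object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
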