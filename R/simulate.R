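#' Simulated tool profile
#'
#' Describes one emulated DIEA pipeline: its metric family, how noisy its
#' view of the latent differential-expression signal is, and (for PPDE
#' tools) the logistic calibration mapping evidence to a posterior.
#'
#' @param tool_name Tool identifier.
#' @param metric_family One of `"PQ"`, `"PPDE"`, `"PPLR"`.
#' @param noise_sd Tool-specific noise standard deviation tau (> 0), added
#'   on top of unit baseline measurement noise.
#' @param a,b PPDE logistic calibration: `ppde = plogis(a * |z| - b)`.
#' @param dropout Fraction of transcripts the tool fails to report
#'   (default 0).
#' @param direction_signal For PQ tools, include a signed `direction_signal`
#'   column carrying the observed effect?
#' @return An object of class `tool_profile`.
#' @export
tool_profile <- function(tool_name, metric_family, noise_sd,
                         a = 2, b = 2, dropout = 0,
                         direction_signal = (metric_family == "PQ")) {
  metric_family <- match.arg(metric_family, METRIC_FAMILIES)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  structure(list(tool_name = tool_name, metric_family = metric_family,
                 noise_sd = noise_sd, a = a, b = b, dropout = dropout,
                 direction_signal = isTRUE(direction_signal)),
            class = "tool_profile")
}

#' Default profiles: six heterogeneous emulated pipelines
#'
#' Mirrors the usual DIEA landscape of six imperfect voters with distinct
#' noise levels so no single tool dominates: three PQ pipelines (a
#' pseudo-alignment pipeline, a classic assembly/Cuffdiff-style pipeline,
#' and a noisier count-based stage), two PPDE tools and one PPLR tool.
#'
#' @return List of six [tool_profile()] objects.
#' @export
default_tool_profiles <- function() {
  list(
    tool_profile("sleuth_like",     "PQ",   noise_sd = 0.8),
    tool_profile("tuxedo_like",     "PQ",   noise_sd = 0.6),
    tool_profile("new_tuxedo_like", "PQ",   noise_sd = 1.1),
    tool_profile("ebseq_like",      "PPDE", noise_sd = 0.9),
    tool_profile("rsem_like",       "PPDE", noise_sd = 1.1),
    tool_profile("bitseq_like",     "PPLR", noise_sd = 1.0)
  )
}

#' Simulation configuration
#'
#' Defines the simulated condition: universe size, number of DE transcripts
#' (half up-, half down-regulated by default), latent effect size, and the
#' tool profiles whose outputs are emulated. Presets `set1`/`set2`/`set3`
#' give 500/1000/2000 DE transcripts over a 20,000-transcript universe.
#'
#' @param n_transcripts Universe size (default 20000).
#' @param n_de Number of differentially expressed transcripts.
#' @param up_fraction Fraction of DE transcripts that are up-regulated.
#' @param effect_mean Latent signal strength mu (unitless, default 3).
#' @param tool_profiles List of [tool_profile()] objects.
#' @param seed Master seed; everything downstream is deterministic in it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 20000, n_de = 1000, up_fraction = 0.5,
                       effect_mean = 3.0,
                       tool_profiles = default_tool_profiles(), seed = 1) {
  stopifnot(length(tool_profiles) >= 1L,
            all(vapply(tool_profiles, inherits, logical(1), "tool_profile")))
  if (n_de > n_transcripts) {
    stop("`n_de` cannot exceed `n_transcripts`", call. = FALSE)
  }
  if (up_fraction < 0 || up_fraction > 1) {
    stop("`up_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 n_de = as.integer(n_de),
                 up_fraction = up_fraction,
                 effect_mean = effect_mean,
                 tool_profiles = tool_profiles,
                 seed = as.integer(seed)),
            class = "sim_config")
}

SIM_PRESETS <- c(set1 = 500L, set2 = 1000L, set3 = 2000L)

#' @rdname sim_config
#' @param preset One of `"set1"`, `"set2"`, `"set3"`.
#' @param ... Passed on to [sim_config()] (e.g. `seed`, `tool_profiles`).
#' @export
sim_preset <- function(preset, ...) {
  if (length(preset) != 1L || !preset %in% names(SIM_PRESETS)) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 paste(preset, collapse = ","),
                 paste(names(SIM_PRESETS), collapse = ", ")), call. = FALSE)
  }
  sim_config(n_de = SIM_PRESETS[[preset]], ...)
}

# One pseudo-random stream per tool, derived from the master seed so that
# appending a profile never changes earlier tools' scores.
derive_tool_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 9973 * as.numeric(k)) %% 2147483647)
}

#' Simulate ground truth and correlated multi-tool score tables
#'
#' Shared-latent-signal model of six heterogeneous pipelines run on the
#' same experiment. Each transcript carries a latent signal
#' `s = mu * d` with direction `d` in `{+1, -1, 0}`; tool `k` observes
#' `z = s + e` with `e ~ Normal(0, 1 + tau_k^2)` (unit baseline measurement
#' noise plus tool-specific noise), independently across tools, which makes
#' tool scores positively correlated on DE transcripts and independent on
#' nulls. Observations map to each family's native metric:
#' \itemize{
#'   \item PQ: `p` = two-sided tail probability of `z` under the null
#'     `Normal(0, 1 + tau^2)` (exactly uniform for null transcripts);
#'     `q` = Benjamini-Hochberg adjustment of the p column;
#'   \item PPDE: `plogis(a * |z| - b)`;
#'   \item PPLR: `pnorm(z / sqrt(1 + tau^2))` (0.5 at no evidence).
#' }
#' Label counts are exact: `count(up) = round(up_fraction * n_de)` and
#' `count(down) = n_de - count(up)`. Identical seeds give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return List with elements `truth` (a [ground_truth()]) and `tables`
#'   (list of [tool_score_table()], one per profile).
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  ids <- sprintf("TX%06d", seq_len(n))

  set.seed(config$seed)
  d <- integer(n)
  de_idx <- sample.int(n, config$n_de)
  n_up <- round(config$up_fraction * config$n_de)
  d[de_idx[seq_len(n_up)]] <- 1L
  if (config$n_de > n_up) d[de_idx[(n_up + 1L):config$n_de]] <- -1L
  label <- c("down", "none", "up")[d + 2L]
  truth <- ground_truth(ids, label)

  s <- config$effect_mean * d
  tables <- vector("list", length(config$tool_profiles))
  for (k in seq_along(config$tool_profiles)) {
    prof <- config$tool_profiles[[k]]
    set.seed(derive_tool_seed(config$seed, k))
    total_sd <- sqrt(1 + prof$noise_sd^2)
    z <- s + stats::rnorm(n, 0, total_sd)
    df <- switch(
      prof$metric_family,
      PQ = {
        p <- 2 * stats::pnorm(-abs(z) / total_sd)
        data.frame(transcript_id = ids, pvalue = p, qvalue = bh_adjust(p))
      },
      PPDE = data.frame(transcript_id = ids,
                        ppde = stats::plogis(prof$a * abs(z) - prof$b)),
      PPLR = data.frame(transcript_id = ids,
                        pplr = stats::pnorm(z / total_sd))
    )
    if (prof$metric_family == "PQ" && prof$direction_signal) {
      df$direction_signal <- z
    }
    if (prof$dropout > 0) {
      keep <- stats::runif(n) >= prof$dropout
      df <- df[keep, , drop = FALSE]
    }
    tables[[k]] <- tool_score_table(prof$tool_name, prof$metric_family, df)
  }
  list(truth = truth, tables = tables)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: with ordered p-values p_(1) <=
#' ... <= p_(m), `q_(i) = min over j >= i of min(1, m * p_(j) / j)`,
#' returned in the original order. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order; empty input gives empty output.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (!is.numeric(pvalues) || any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
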