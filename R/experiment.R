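#' @name experiment
#' @title Replicated dosing experiments and concentration-time profiles
#' @description
#' The experiment layer turns raw per-step systemic amount series into
#' clinical-style concentration-time profiles: a centred moving-average
#' smooth (half-window `smoothN` steps) is applied to each replicate series,
#' the smoothed amounts at the clinical sampling steps are scaled by
#' `MeasureScale` (ng/mL per drug object) and the steps by `TimeScale`
#' (hours per step), and replicates are summarized pointwise as mean, SD
#' and n.
NULL

#' Smoothed amount at a step
#'
#' Arithmetic mean of the raw amounts over steps `S - N .. S + N` (a
#' `2N + 1`-step window). Step 0 is the dosing instant and is returned
#' unsmoothed.
#'
#' @param amounts Integer vector of per-step amounts, `amounts[i]` being the
#'   amount at step `i - 1` (so the series starts at step 0).
#' @param S Step (or vector of steps) at which to evaluate the smooth.
#' @param N Half-window in steps (default 10).
#' @return Smoothed amount(s) at `S`.
#' @examples
#' smooth_at(0:200, S = 100, N = 10) # mean of 90..110 = 100
#' @export
smooth_at <- function(amounts, S, N = 10L) {
  n_steps <- length(amounts) - 1L
  vapply(S, function(s) {
    if (s == 0) return(as.numeric(amounts[1]))
    if (s < 0 || s - N < 0 || s + N > n_steps) {
      abort(sprintf("smoothing window [%d, %d] out of range [0, %d]",
                    s - N, s + N, n_steps))
    }
    mean(amounts[(s - N):(s + N) + 1L])
  }, numeric(1))
}

#' Map an amount series to a concentration-time profile
#'
#' Smooths the raw series at the experiment's sampling steps, then scales
#' amounts to concentrations (`MeasureScale`, ng/mL per object) and steps to
#' hours (`TimeScale`).
#'
#' @param amounts Per-step amount series (step 0 first).
#' @param experiment The `experiment` block of an `oralsim_model` (needs
#'   `TimeScale`, `MeasureScale`, `samplingSteps`, `smoothN`).
#' @return A tibble with columns `time` (h) and `concentration` (ng/mL).
#' @export
to_profile <- function(amounts, experiment) {
  steps <- experiment$samplingSteps
  tibble(
    time = steps * experiment$TimeScale,
    concentration = smooth_at(amounts, steps, experiment$smoothN) *
      experiment$MeasureScale
  )
}

#' Run a replicated experiment and return tidy profiles
#'
#' Convenience pipeline: [run_replicates()], then per-replicate smoothing and
#' scaling at the clinical sampling steps.
#'
#' @inheritParams run_replicates
#' @return A tibble with columns `replicate`, `seed`, `time`,
#'   `concentration`, plus `raw_amount` and `smoothed_amount` for provenance.
#' @examples
#' \donttest{
#' prof <- simulate_profiles(drug_model("midazolam"), base_seed = 1)
#' summarize_profiles(prof)
#' }
#' @export
simulate_profiles <- function(spec, route = NULL, seeds = NULL,
                              base_seed = 20180831L) {
  runs <- run_replicates(spec, route = route, seeds = seeds,
                         base_seed = base_seed)
  exp <- spec$experiment
  runs |>
    dplyr::group_by(.data$replicate, .data$seed) |>
    dplyr::reframe(
      time = exp$samplingSteps * exp$TimeScale,
      raw_amount = .data$amount[exp$samplingSteps + 1L],
      smoothed_amount = smooth_at(.data$amount, exp$samplingSteps, exp$smoothN),
      concentration = smoothed_amount * exp$MeasureScale
    )
}

#' Summarize replicate profiles as mean, SD and n
#'
#' @param profiles Tibble with `replicate`, `time`, `concentration` (as from
#'   [simulate_profiles()]).
#' @return A tibble with columns `time`, `mean`, `sd`, `n`.
#' @export
summarize_profiles <- function(profiles) {
  grids <- profiles |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(g = paste(.data$time, collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) > 1) {
    abort("replicate profiles must share the same time grid")
  }
  profiles |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      mean = mean(.data$concentration),
      sd = stats::sd(.data$concentration),
      n = dplyr::n(),
      .groups = "drop"
    )
}
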