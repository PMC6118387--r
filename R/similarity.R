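#' @name similarity
#' @title Three-level similarity between referent and simulated profiles
#' @description
#' Simulated mean concentration-time profiles are judged against a referent
#' clinical profile at three pre-specified levels: (1) visual band coverage -
#' every simulated mean should lie within the referent mean +/- 1 SD; (2)
#' quantitative indices - the SD-weighted root-mean-square error (threshold
#' 2.5) and the SD-weighted mean absolute percentage error (threshold 33%);
#' (3) descriptive similarity - less than 25% relative difference on each
#' noncompartmental PK parameter. The time-zero point (both profiles zero,
#' SD zero) is excluded from all three levels.
NULL

RMSE_THRESHOLD <- 2.5
MAPE_THRESHOLD <- 33
PK_DIFF_THRESHOLD <- 25

check_grids <- function(ref, sim) {
  if (length(ref$time) != length(sim$time) ||
      any(abs(ref$time - sim$time) > 1e-9)) {
    abort("referent and simulated profiles must share the same time grid")
  }
}

included_points <- function(ref) {
  which(ref$time > 0)
}

#' Visual band coverage
#'
#' Fraction of post-dose sampling points at which the simulated mean lies
#' inside the referent mean +/- 1 SD band, and the times violating it.
#'
#' @param ref Referent profile: tibble with `time`, `mean`, `sd`.
#' @param sim Simulated mean profile: tibble with `time` and `mean` (or
#'   `concentration`).
#' @return List with `coverage` (fraction in `[0, 1]`) and `outside` (times).
#' @export
band_coverage <- function(ref, sim) {
  sim_mean <- sim$mean %||% sim$concentration
  check_grids(ref, sim)
  idx <- included_points(ref)
  inside <- abs(sim_mean[idx] - ref$mean[idx]) <= ref$sd[idx]
  list(coverage = mean(inside), outside = ref$time[idx][!inside])
}

#' SD-weighted root-mean-square error
#'
#' `sqrt( mean( (ref - sim)^2 / sd^2 ) )` over post-dose sampling points:
#' each squared deviation is weighted by the referent variance at that point,
#' so the statistic reads as a typical deviation in referent-SD units.
#'
#' @inheritParams band_coverage
#' @return Nonnegative scalar; 0 iff the profiles agree at every included
#'   point.
#' @export
weighted_rmse <- function(ref, sim) {
  sim_mean <- sim$mean %||% sim$concentration
  check_grids(ref, sim)
  idx <- included_points(ref)
  if (any(ref$sd[idx] <= 0)) {
    abort("referent SD must be positive at all post-dose points")
  }
  sqrt(mean((ref$mean[idx] - sim_mean[idx])^2 / ref$sd[idx]^2))
}

#' SD-weighted mean absolute percentage error
#'
#' `mean( (1/sd) * |ref - sim| / ref ) * 100` over post-dose points: the
#' absolute percentage error at each point down-weighted where the clinical
#' data are more variable.
#'
#' @inheritParams band_coverage
#' @return Percentage (nonnegative).
#' @export
weighted_mape <- function(ref, sim) {
  sim_mean <- sim$mean %||% sim$concentration
  check_grids(ref, sim)
  idx <- included_points(ref)
  if (any(ref$sd[idx] <= 0) || any(ref$mean[idx] <= 0)) {
    abort("referent mean and SD must be positive at all post-dose points")
  }
  mean(abs(ref$mean[idx] - sim_mean[idx]) / ref$mean[idx] / ref$sd[idx]) * 100
}

#' Descriptive similarity of PK parameters
#'
#' Absolute (`sim - ref`) and relative (`|sim - ref| / ref * 100`)
#' differences for the seven NCA parameters; the verdict requires every
#' relative difference below 25%. Tmax is compared in absolute terms only
#' (it is grid-quantized and highly variable), mirroring how such
#' comparisons are reported.
#'
#' @param ref_pk,sim_pk One-row tibbles (or named lists) with `AUC`, `Cmax`,
#'   `Tmax`, `Kel`, `T1_2`, `CL_F`, `V_F`.
#' @return List with `diffs` (tibble: parameter, ref, sim, absolute,
#'   relative) and `verdict` (logical).
#' @export
descriptive_similarity <- function(ref_pk, sim_pk) {
  pars <- c("AUC", "Cmax", "Tmax", "Kel", "T1_2", "CL_F", "V_F")
  ref_v <- unname(vapply(pars, function(p) as.numeric(ref_pk[[p]]), 0))
  sim_v <- unname(vapply(pars, function(p) as.numeric(sim_pk[[p]]), 0))
  rel <- abs(sim_v - ref_v) / ref_v * 100
  rel[pars == "Tmax"] <- NA_real_
  diffs <- tibble(parameter = pars, ref = ref_v, sim = sim_v,
                  absolute = sim_v - ref_v, relative = rel)
  verdict <- all(diffs$relative < PK_DIFF_THRESHOLD, na.rm = TRUE)
  list(diffs = diffs, verdict = verdict)
}

#' Full three-level similarity report
#'
#' @param ref Referent summary profile (`time`, `mean`, `sd`, optionally `n`).
#' @param sim Simulated summary profile (`time`, `mean` or `concentration`).
#' @param ref_pk,sim_pk Optional PK parameter sets for level 3.
#' @return An `oralsim_similarity` object with the three-level verdicts;
#'   print mirrors the tabular layout of similarity criteria reports.
#' @examples
#' ref <- one_compartment_profile(ka = 2, ke = 0.28, doseScale = 120,
#'                                grid = c(0, 0.5, 1, 2, 4, 8, 12, 24),
#'                                noise_cv = 0.2, n_subjects = 12, seed = 1)
#' similarity_report(ref, ref) # a profile is perfectly similar to itself
#' @export
similarity_report <- function(ref, sim, ref_pk = NULL, sim_pk = NULL) {
  bc <- band_coverage(ref, sim)
  rmse <- weighted_rmse(ref, sim)
  mape <- weighted_mape(ref, sim)
  lvl3 <- if (!is.null(ref_pk) && !is.null(sim_pk)) {
    descriptive_similarity(ref_pk, sim_pk)
  } else {
    NULL
  }
  structure(
    list(
      bandCoverage = bc$coverage, pointsOutside = bc$outside,
      weightedRMSE = rmse, weightedMAPE = mape,
      pkDiffs = lvl3$diffs,
      verdicts = list(
        level1 = bc$coverage == 1,
        level2 = rmse <= RMSE_THRESHOLD && mape <= MAPE_THRESHOLD,
        level3 = if (is.null(lvl3)) NA else lvl3$verdict
      ),
      thresholds = list(rmse = RMSE_THRESHOLD, mape = MAPE_THRESHOLD,
                        pk_rel = PK_DIFF_THRESHOLD)
    ),
    class = "oralsim_similarity"
  )
}

#' @rdname similarity_report
#' @param x An `oralsim_similarity` object.
#' @param ... Unused.
#' @export
glance.oralsim_similarity <- function(x, ...) {
  tibble(
    bandCoverage = x$bandCoverage,
    weightedRMSE = x$weightedRMSE,
    weightedMAPE = x$weightedMAPE,
    level1 = x$verdicts$level1,
    level2 = x$verdicts$level2,
    level3 = x$verdicts$level3
  )
}

#' @rdname similarity_report
#' @export
tidy.oralsim_similarity <- function(x, ...) {
  if (is.null(x$pkDiffs)) return(tibble())
  x$pkDiffs
}

#' @export
print.oralsim_similarity <- function(x, ...) {
  cat("Similarity criteria\n")
  cat(sprintf(
    "1. Qualitative (visual) - simulated mean within referent mean +/- 1 SD:\n   %s\n",
    if (x$verdicts$level1) "met by all sampling points" else
      sprintf("%d point(s) outside, at %s h", length(x$pointsOutside),
              paste(x$pointsOutside, collapse = ", "))))
  cat(sprintf("2. Quantitative\n   weighted RMSE  %.3f (threshold %.1f)\n   weighted MAPE  %.2f%% (threshold %.0f%%)\n",
              x$weightedRMSE, x$thresholds$rmse, x$weightedMAPE,
              x$thresholds$mape))
  if (!is.null(x$pkDiffs)) {
    cat(sprintf("3. Descriptive - absolute (relative) PK differences [< %d%%]\n",
                x$thresholds$pk_rel))
    d <- x$pkDiffs
    for (i in seq_len(nrow(d))) {
      rel <- if (is.na(d$relative[i])) "" else sprintf(" (%.1f%%)", d$relative[i])
      cat(sprintf("   %-5s %+.3g%s\n", d$parameter[i], d$absolute[i], rel))
    }
    cat(sprintf("   verdict: %s\n", if (x$verdicts$level3) "met" else "not met"))
  }
  invisible(x)
}
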