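#' @name pk_nca
#' @title Noncompartmental analysis and bioavailability decomposition
#' @description
#' Standard noncompartmental analysis (NCA) of a concentration-time profile:
#' AUC by the linear trapezoid rule from time 0 to the last sampling time,
#' Cmax / Tmax from the observed maximum, the terminal elimination rate
#' constant Kel from a log-linear least-squares fit of the terminal points,
#' T1/2 = ln(2) / Kel, apparent oral clearance CL/F = dose / AUC and apparent
#' volume V/F = (CL/F) / Kel. Bioavailability is decomposed from the AUCs of
#' oral, hepatic-portal-vein and intravenous dosing routes:
#' F = AUC_oral / AUC_iv, Fa.Fg = AUC_oral / AUC_hpv,
#' Fh = AUC_hpv / AUC_iv (all x 100%), so that F = Fa.Fg x Fh / 100.
NULL

#' Noncompartmental analysis of one profile
#'
#' @param profile Tibble/data frame with columns `time` (h) and
#'   `concentration` (ng/mL), time strictly increasing from 0.
#' @param dose_mg Administered dose in mg (used for CL/F and V/F); `NA`
#'   leaves the dose-dependent parameters undefined.
#' @param terminal_n Number of terminal positive-concentration points (the
#'   Cmax point excluded) used for the log-linear Kel regression. Default 4.
#' @param extrapolate If `TRUE`, add the tail `C_last / Kel` to the AUC
#'   (AUC to infinity); default `FALSE` reports AUC(0-tlast).
#' @return An object of class `oralsim_pk`: a list with `params` (a one-row
#'   tibble: AUC, Cmax, Tmax, Kel, T1_2, CL_F, V_F), the regression points
#'   used, and the input profile. `tidy()` and `glance()` methods are
#'   provided.
#' @examples
#' tt <- c(0, 0.5, 1, 2, 4, 6, 8, 12, 24)
#' prof <- data.frame(time = tt, concentration = 100 * exp(-0.28 * tt))
#' glance(nca(prof, dose_mg = 15))
#' @export
nca <- function(profile, dose_mg = NA_real_, terminal_n = 4L,
                extrapolate = FALSE) {
  tt <- as.numeric(profile$time)
  cc <- as.numeric(profile$concentration)
  # tolerate duplicated t = 0 zero rows (prepended dosing records)
  dup0 <- which(tt == 0)
  if (length(dup0) > 1) {
    drop <- dup0[-1][cc[dup0[-1]] == cc[dup0[1]]]
    if (length(drop)) { tt <- tt[-drop]; cc <- cc[-drop] }
  }
  if (length(tt) < 2) abort("NCA needs at least 2 sampling points")
  if (is.unsorted(tt, strictly = TRUE)) abort("`time` must be strictly increasing")

  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  imax <- which.max(cc) # ties resolve to the earliest time
  cmax <- cc[imax]
  tmax <- tt[imax]

  pos <- which(cc > 0)
  pos <- setdiff(pos, imax)
  term <- utils::tail(pos, terminal_n)
  kel <- NA_real_
  if (length(term) >= 3) {
    fit <- stats::lm(log(cc[term]) ~ tt[term])
    slope <- unname(stats::coef(fit)[2])
    if (is.finite(slope) && slope < 0) kel <- -slope
  }
  t12 <- if (is.finite(kel)) log(2) / kel else NA_real_
  if (extrapolate && is.finite(kel)) {
    auc <- auc + cc[length(cc)] / kel
  }
  # dose mg -> ng (1e6), AUC ng.h/mL -> CL in mL/h -> L (1e-3)
  cl_f <- if (is.finite(dose_mg) && auc > 0) dose_mg * 1e6 / auc / 1e3 else NA_real_
  v_f <- if (is.finite(cl_f) && is.finite(kel)) cl_f / kel else NA_real_

  structure(
    list(
      params = tibble(AUC = auc, Cmax = cmax, Tmax = tmax, Kel = kel,
                      T1_2 = t12, CL_F = cl_f, V_F = v_f),
      terminal_points = tibble(time = tt[term], concentration = cc[term]),
      profile = tibble(time = tt, concentration = cc),
      dose_mg = dose_mg
    ),
    class = "oralsim_pk"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname nca
#' @param x An `oralsim_pk` object.
#' @param ... Unused.
#' @export
tidy.oralsim_pk <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "parameter", values_to = "estimate")
}

#' @rdname nca
#' @export
glance.oralsim_pk <- function(x, ...) x$params

#' @export
print.oralsim_pk <- function(x, ...) {
  cat("<oralsim_pk> noncompartmental parameters\n")
  print(x$params)
  invisible(x)
}

#' Per-replicate NCA
#'
#' Runs [nca()] on each replicate of a tidy profile table and returns one row
#' of PK parameters per replicate.
#'
#' @param profiles Tibble with `replicate`, `time`, `concentration`.
#' @param dose_mg Dose in mg.
#' @param ... Passed to [nca()].
#' @return Tibble with `replicate` plus the seven NCA parameters.
#' @export
pk_by_replicate <- function(profiles, dose_mg = NA_real_, ...) {
  profiles |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      glance(nca(df, dose_mg = dose_mg, ...))
    }) |>
    dplyr::ungroup()
}

#' Summarize per-replicate PK parameters
#'
#' Mean and SD across replicates for every parameter; Tmax is summarized by
#' its median, the conventional location summary for a coarse-gridded,
#' highly variable statistic.
#'
#' @param pk Tibble from [pk_by_replicate()].
#' @return Tibble with `parameter`, `mean`, `sd`, `median`, `n`.
#' @export
summarize_pk <- function(pk) {
  pk |>
    dplyr::select(-dplyr::any_of(c("replicate", "seed"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      n = sum(is.finite(.data$value)),
      .groups = "drop"
    )
}

#' Bioavailability decomposition from route AUCs
#'
#' @param auc_oral,auc_hpv,auc_iv AUCs (ng.h/mL) after oral, hepatic-portal
#'   and intravenous dosing. Vectorized (e.g. per-replicate pairs).
#' @return A tibble with `F`, `FaFg`, `Fh` (percent) and the input AUCs.
#'   The identity `F = FaFg * Fh / 100` holds exactly.
#' @examples
#' bioavailability(318.83, 329.16, 687.72)
#' @export
bioavailability <- function(auc_oral, auc_hpv, auc_iv) {
  if (any(auc_oral <= 0) || any(auc_hpv <= 0) || any(auc_iv <= 0)) {
    abort("all AUCs must be positive")
  }
  tibble(
    F = auc_oral / auc_iv * 100,
    FaFg = auc_oral / auc_hpv * 100,
    Fh = auc_hpv / auc_iv * 100,
    AUC_oral = auc_oral, AUC_hpv = auc_hpv, AUC_iv = auc_iv
  )
}

#' Simulated bioavailability experiment over the three dosing routes
#'
#' Runs matched replicate sets for oral (stomach), hepatic-portal-vein and
#' intravenous (systemic blood) dosing, computes per-replicate smoothed
#' trapezoid AUCs on the clinical sampling grid, pairs the routes replicate
#' by replicate (Eq. F = AUC_oral/AUC_iv etc.), and averages.
#'
#' @param spec A validated `oralsim_model`.
#' @param base_seed Base seed; route r, replicate i uses an offset stream so
#'   all runs are independent.
#' @param replicates Number of replicates per route (default: experiment
#'   block).
#' @return An object of class `oralsim_bioavailability`: list with
#'   `by_replicate` (tibble of per-replicate AUCs and F / FaFg / Fh),
#'   `summary` (mean and SD), and the route PK tables.
#' @export
bioavailability_experiment <- function(spec, base_seed = 20180831L,
                                       replicates = NULL) {
  replicates <- replicates %||% spec$experiment$replicates
  routes <- c(oral = "stomach", hpv = "portal_vein", iv = "systemic_blood")
  aucs <- purrr::imap(routes, function(space, label) {
    seeds <- base_seed + match(label, names(routes)) * 1000003L +
      seq_len(replicates)
    prof <- simulate_profiles(spec, route = space, seeds = seeds)
    pk_by_replicate(prof, dose_mg = spec$experiment$clinicalDose) |>
      dplyr::mutate(route = label)
  })
  by_rep <- bioavailability(aucs$oral$AUC, aucs$hpv$AUC, aucs$iv$AUC) |>
    dplyr::mutate(replicate = dplyr::row_number(), .before = 1)
  summary <- by_rep |>
    dplyr::select("F", "FaFg", "Fh", "AUC_oral", "AUC_hpv", "AUC_iv") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "quantity") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(
    list(by_replicate = by_rep, summary = summary,
         pk = dplyr::bind_rows(aucs), drug = spec$drug$name,
         base_seed = base_seed),
    class = "oralsim_bioavailability"
  )
}

#' @rdname bioavailability_experiment
#' @param x An `oralsim_bioavailability` object.
#' @param ... Unused.
#' @export
tidy.oralsim_bioavailability <- function(x, ...) x$by_replicate

#' @rdname bioavailability_experiment
#' @export
glance.oralsim_bioavailability <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "quantity",
                     values_from = c("mean", "sd"))
}

#' @export
print.oralsim_bioavailability <- function(x, ...) {
  cat(sprintf("<oralsim_bioavailability> %s, %d replicate pairs\n",
              x$drug, nrow(x$by_replicate)))
  print(x$summary)
  invisible(x)
}
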