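#' @name fixtures
#' @title Synthetic referent profiles and miniature worlds
#' @description
#' Self-contained substitutes for external data: an analytic one-compartment
#' oral-absorption profile generator that produces referent-style summary
#' tables (time, mean, sd, n), and a miniature agent world for fast engine
#' tests.
NULL

#' Analytic one-compartment oral-absorption referent profile
#'
#' Concentrations follow the classical one-compartment first-order model
#' `C(t) = doseScale * ka / (ka - ke) * (exp(-ke t) - exp(-ka t))`.
#' Per-subject profiles receive multiplicative log-normal noise with
#' coefficient of variation `noise_cv` (keeping concentrations positive),
#' and are summarized pointwise as mean, sample SD and n.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param ke First-order elimination rate constant (1/h); must differ
#'   from `ka`.
#' @param doseScale Amplitude (ng/mL); the scale of `C(t)`, absorbing dose,
#'   bioavailability and volume.
#' @param grid Sampling times in hours (first element 0 by convention).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for a noiseless profile).
#' @param n_subjects Number of synthetic subjects.
#' @param seed RNG seed.
#' @return Tibble with `time`, `mean`, `sd`, `n` (referent CSV schema).
#' @examples
#' one_compartment_profile(ka = 3, ke = 0.28, doseScale = 100,
#'                         grid = c(0, 1, 2, 4, 8, 24),
#'                         noise_cv = 0, n_subjects = 1, seed = 1)
#' @export
one_compartment_profile <- function(ka, ke, doseScale, grid,
                                    noise_cv = 0, n_subjects = 12,
                                    seed = 1L) {
  if (ka <= 0 || ke <= 0) abort("`ka` and `ke` must be positive")
  if (abs(ka - ke) < 1e-12) abort("`ka` must differ from `ke`")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  ct <- doseScale * ka / (ka - ke) * (exp(-ke * grid) - exp(-ka * grid))
  sdlog <- sqrt(log(1 + noise_cv^2))
  mat <- withr::with_seed(seed, {
    vapply(seq_len(n_subjects), function(i) {
      if (noise_cv == 0) return(ct)
      ct * stats::rlnorm(length(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }, numeric(length(grid)))
  })
  tibble(
    time = grid,
    mean = rowMeans(mat),
    sd = apply(mat, 1, stats::sd),
    n = n_subjects
  )
}

#' Miniature agent world for fast tests
#'
#' A structurally complete model (all thirteen spaces, the full membrane and
#' flow topology, every site kind) shrunk to small lattices, few drug
#' objects and short runs, so engine properties can be exercised in
#' milliseconds. All fields are overridable via nested lists.
#'
#' @param ... Named overrides merged into the specification before
#'   validation, e.g. `toy_world(experiment = list(numSolutes = 50L))` or
#'   `drug = list(metabolizeProbCyp = 1)`.
#' @param dims Lattice size used for every space (default `c(5, 5, 5)`).
#' @param steps,numSolutes Run length and number of drug objects.
#' @return A validated `oralsim_model`.
#' @examples
#' tw <- toy_world()
#' run <- run_simulation(tw, seed = 1)
#' length(run$amounts)
#' @export
toy_world <- function(..., dims = c(5L, 5L, 5L), steps = 100L,
                      numSolutes = 10L) {
  spec <- drug_model("midazolam")
  for (nm in names(spec$system$spaces)) {
    spec$system$spaces[[nm]]$dims <- as.integer(dims)
  }
  spec$system$systemSize <- as.integer(dims)
  spec$experiment$steps <- as.integer(steps)
  spec$experiment$numSolutes <- as.integer(numSolutes)
  spec$experiment$replicates <- 2L
  spec$experiment$smoothN <- min(2L, as.integer(steps %/% 4))
  # sampling grid spanning the run, with the smoothing window inside it
  hi <- max(0L, as.integer(steps) - spec$experiment$smoothN)
  spec$experiment$samplingSteps <- unique(as.integer(round(
    seq(0, hi, length.out = min(5, hi + 1)))))
  spec$experiment$samplingTimes <- spec$experiment$samplingSteps *
    spec$experiment$TimeScale
  # scale down site counts so a 125-cell space is not saturated with sites
  for (i in seq_along(spec$system$sites)) {
    spec$system$sites[[i]]$count <-
      max(1L, as.integer(ceiling(spec$system$sites[[i]]$count / 20)))
  }
  overrides <- list(...)
  for (block in names(overrides)) {
    spec[[block]] <- utils::modifyList(spec[[block]], overrides[[block]])
  }
  validate_model(spec)
  spec
}
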