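#' @name engine
#' @title Agent world and step dynamics
#' @description
#' The engine advances the agent world in discrete steps with a fixed event
#' order: (1) bound drugs metabolize/release, (2) unbound drugs move by a
#' biased random walk, (3) membrane permeation attempts, (4) inter-space flow
#' transfers, (5) binding attempts, (6) step counter increment. All
#' randomness is drawn from one seeded stream, so a given specification and
#' seed reproduce bit-identical amount series. The step loop is compiled
#' (Rcpp); [build_world()] translates a validated model into the flat
#' numeric form the compiled kernel consumes.
NULL

# neighborhood "number of grids" -> lattice realization code:
# 1 -> the site's own cell; 3 -> 3-point line along X; 9 -> 3x3 X-Y block;
# >= 27 -> full 3x3x3 cube. Matches the printed grid counts exactly.
neighborhood_code <- function(n) {
  if (n >= 27) 3L else if (n >= 9) 2L else if (n >= 3) 1L else 0L
}

#' Compile a model specification into engine form
#'
#' Precomputes everything the step kernel needs: space table, flow and
#' membrane tables with effective directional crossing probabilities, and the
#' site placement table. Directional crossing probabilities combine three
#' channels: paracellular pores (`poresFrac`, ionization-independent),
#' passive transcellular permeation ([permeation_probability()] at the pH of
#' the origin space), and carrier-mediated uptake
#' (`uptakeProb * uptakeFrac`, only in the membrane's `from -> to`
#' direction).
#'
#' @param spec A validated `oralsim_model`.
#' @return A list consumed by the compiled kernel.
#' @keywords internal
#' @export
build_world <- function(spec) {
  sys <- spec$system
  idx <- stats::setNames(seq_along(SPACE_NAMES) - 1L, SPACE_NAMES)

  dims <- t(vapply(sys$spaces, function(sp) sp$dims, integer(3)))
  flow_rate <- vapply(sys$spaces, function(sp) sp$flowRate, 0)
  terminal <- names(sys$spaces) == "colon_egested"

  efflux_target <- rep(-1L, length(SPACE_NAMES))
  for (ent in names(APICAL_LUMEN)) {
    efflux_target[idx[ent] + 1L] <- idx[[APICAL_LUMEN[[ent]]]]
  }

  flows <- do.call(rbind, lapply(sys$flows, function(fl) {
    c(idx[[fl$from]], idx[[fl$to]], fl$flowDepthFrac, fl$flowFrac)
  }))

  drug <- spec$drug
  membranes <- do.call(rbind, lapply(sys$membranes, function(m) {
    pH_from <- sys$spaces[[m$from]]$pH
    pH_to <- sys$spaces[[m$to]]$pH
    pab <- min(1, m$poresFrac + permeation_probability(drug, m, pH_from))
    pba <- min(1, m$poresFrac + permeation_probability(drug, m, pH_to))
    # carrier-mediated uptake is flow-limited: an advected drug samples
    # ~flowRate grid points per step, each an independent contact with
    # carrier-bearing membrane area
    contacts <- max(1, round(sys$spaces[[m$from]]$flowRate))
    uptake <- 1 - (1 - m$uptakeProb * m$uptakeFrac)^contacts
    c(idx[[m$from]], idx[[m$to]], pab, pba, m$interfaceDepthFrac, uptake)
  }))

  sites <- do.call(rbind, lapply(sys$sites, function(s) {
    kind <- match(s$kind, c("cyp", "pgp", "binder")) - 1L
    m <- matrix(rep(c(kind, idx[[s$space]], s$maxActiveSites,
                      neighborhood_code(s$neighborhood)), s$count),
                ncol = 4, byrow = TRUE)
    m
  }))

  kind_params <- rbind(
    cyp = c(drug$affinityCyp, drug$releaseProbCyp, drug$metabolizeProbCyp,
            as.numeric(drug$cypSubstrate)),
    pgp = c(drug$affinityPgp, drug$releaseProbPgp, 0,
            as.numeric(drug$pgpSubstrate)),
    binder = c(drug$affinityBinder, drug$releaseProbBinder, 0,
               as.numeric(drug$binderSubstrate))
  )

  list(space_dims = dims, space_flow = flow_rate, space_terminal = terminal,
       efflux_target = efflux_target, flows = flows, membranes = membranes,
       sites = sites, kind_params = kind_params,
       move_prob = min(1, sqrt(325.7 / drug$MW)),
       space_index = idx)
}

#' Run one simulated dosing experiment
#'
#' Doses `numSolutes` parent drug objects uniformly at random into the route
#' space at step 0, advances the world for `steps` steps, and records the
#' amount of parent drug in systemic blood (bound or free) at every step.
#'
#' @param spec A validated `oralsim_model`.
#' @param route Dosing space: `"stomach"` (oral), `"portal_vein"`
#'   (hepatic-portal) or `"systemic_blood"` (intravenous). Defaults to the
#'   experiment block's route.
#' @param seed Integer seed for the run's random stream.
#' @param steps Number of steps (defaults to the experiment block).
#' @param return_state Also return the final agent and site state (for
#'   diagnostics and invariant checks).
#' @return A list with `amounts` (integer vector of length `steps + 1`),
#'   `metabolized` (count of conversion events) and, optionally, `state` and
#'   `sites` tibbles.
#' @examples
#' \donttest{
#' run <- run_simulation(drug_model("midazolam"), seed = 1)
#' max(run$amounts)
#' }
#' @export
run_simulation <- function(spec, route = NULL, seed = 1L, steps = NULL,
                           return_state = FALSE) {
  validate_model(spec)
  route <- route %||% spec$experiment$route
  if (!route %in% c("stomach", "portal_vein", "systemic_blood")) {
    abort(sprintf("unknown route `%s`", route))
  }
  steps <- as.integer(steps %||% spec$experiment$steps)
  world <- build_world(spec)
  res <- cpp_run_sim(world, steps, world$space_index[[route]],
                     spec$experiment$numSolutes, world$move_prob,
                     world$space_index[["systemic_blood"]],
                     as.double(seed), return_state)
  out <- list(amounts = res$amounts, metabolized = res$metabolized,
              seed = seed, route = route)
  if (return_state) {
    out$state <- as_tibble(res$state)
    out$state$space <- SPACE_NAMES[out$state$space + 1L]
    out$sites <- as_tibble(res$sites)
    out$sites$kind <- c("cyp", "pgp", "binder")[out$sites$kind + 1L]
    out$sites$space <- SPACE_NAMES[out$sites$space + 1L]
  }
  out
}

#' Run replicated dosing experiments
#'
#' One independent run per seed; amounts are recorded every step so smoothing
#' windows can be centred on any sampling step.
#'
#' @param spec A validated `oralsim_model`.
#' @param route Dosing space (default: the experiment block's route).
#' @param seeds Integer vector of distinct seeds, one per replicate. Defaults
#'   to `base_seed + 1:replicates`.
#' @param base_seed Base seed used when `seeds` is not given.
#' @return A tibble with columns `replicate`, `seed`, `step`, `amount`.
#' @export
run_replicates <- function(spec, route = NULL, seeds = NULL, base_seed = 20180831L) {
  if (is.null(seeds)) {
    seeds <- base_seed + seq_len(spec$experiment$replicates)
  }
  if (anyDuplicated(seeds)) {
    abort("`seeds` must be distinct")
  }
  steps <- spec$experiment$steps
  runs <- purrr::map(seeds, function(s) {
    run_simulation(spec, route = route, seed = s)$amounts
  })
  tibble(
    replicate = rep(seq_along(seeds), each = steps + 1L),
    seed = rep(as.integer(seeds), each = steps + 1L),
    step = rep(0:steps, times = length(seeds)),
    amount = unlist(runs)
  )
}

#' Amount of parent drug in systemic blood
#'
#' Counts parent-species drug objects (bound or free) in the systemic blood
#' space of a final engine state.
#'
#' @param state The `state` tibble from `run_simulation(..., return_state = TRUE)`.
#' @return Integer count.
#' @export
measure_systemic <- function(state) {
  sum(state$space == "systemic_blood" & state$species == 0)
}
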