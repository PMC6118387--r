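# Shared fixtures for the test suite. Everything is generated in code.

# A sealed world: no movement (enormous MW), no flow, no permeation, no
# binding. Used for null-dynamics and conservation checks.
sealed_world <- function(n = 10L, steps = 50L) {
  tw <- toy_world(steps = steps, numSolutes = n)
  tw$drug$MW <- 3.257e20 # move probability ~ 1e-9
  tw$drug$pgpSubstrate <- FALSE
  tw$drug$cypSubstrate <- FALSE
  tw$drug$binderSubstrate <- FALSE
  for (i in seq_along(tw$system$flows)) tw$system$flows[[i]]$flowFrac <- 0
  for (i in seq_along(tw$system$membranes)) {
    tw$system$membranes[[i]]$leakinessFrac <- 0
    tw$system$membranes[[i]]$poresFrac <- 0
    tw$system$membranes[[i]]$uptakeProb <- 0
  }
  for (nm in names(tw$system$spaces)) tw$system$spaces[[nm]]$flowRate <- 0
  validate_model(tw)
  tw
}

# One-trial-per-object flow oracle: n objects dosed in the stomach, the
# stomach->duodenum connection set to (depth 1, frac p), everything else
# sealed. After one step the duodenum count is Binomial(n, p).
flow_oracle_world <- function(n, p) {
  tw <- sealed_world(n = n, steps = 2L)
  tw$system$flows[[1]]$flowFrac <- p
  tw$system$flows[[1]]$flowDepthFrac <- 1
  validate_model(tw)
  tw
}

# Oracle world for passive permeation: all objects are flushed from the
# stomach into the duodenum at step 1; at step 2 each gets exactly one
# membrane crossing attempt with probability leak * nf(pH) * sigma(logP).
permeation_oracle_world <- function(n, leak, pH = 7.4) {
  tw <- sealed_world(n = n, steps = 2L)
  tw$system$flows[[1]]$flowFrac <- 1
  tw$system$flows[[1]]$flowDepthFrac <- 1
  tw$system$spaces$duodenum$pH <- pH
  for (i in seq_along(tw$system$membranes)) {
    m <- tw$system$membranes[[i]]
    if (m$from == "duodenum") {
      tw$system$membranes[[i]]$leakinessFrac <- leak
      tw$system$membranes[[i]]$poresFrac <- 0.02
      tw$system$membranes[[i]]$interfaceDepthFrac <- 1
    }
  }
  tw$drug$MW <- 3.257e20
  validate_model(tw)
  tw
}

# Oracle world for carrier uptake / enzyme binding / metabolism: objects are
# dosed in the portal vein, flushed into the sinusoid at step 1, taken up
# into the hepatocyte at step 2 (probability `uptake`), where binding /
# metabolism can be observed with saturating site coverage.
hepatocyte_oracle_world <- function(n, uptake = 1, affinity = 1,
                                    metabolizeProb = 0, releaseProb = 1,
                                    cyp_count = 300L, cyp_cap = 5L,
                                    steps = 3L) {
  tw <- sealed_world(n = n, steps = steps)
  set_flow <- function(tw, from, to, frac, depth = 1) {
    for (i in seq_along(tw$system$flows)) {
      fl <- tw$system$flows[[i]]
      if (fl$from == from && fl$to == to) {
        tw$system$flows[[i]]$flowFrac <- frac
        tw$system$flows[[i]]$flowDepthFrac <- depth
      }
    }
    tw
  }
  tw <- set_flow(tw, "portal_vein", "sinusoid", 1)
  tw$system$spaces$sinusoid$flowRate <- 0
  for (i in seq_along(tw$system$membranes)) {
    m <- tw$system$membranes[[i]]
    if (m$from == "sinusoid") {
      tw$system$membranes[[i]]$uptakeProb <- uptake
      tw$system$membranes[[i]]$uptakeFrac <- 1
      tw$system$membranes[[i]]$leakinessFrac <- 0
    }
  }
  for (i in seq_along(tw$system$sites)) {
    s <- tw$system$sites[[i]]
    if (s$kind == "cyp" && s$space == "hepatocyte") {
      tw$system$sites[[i]]$count <- cyp_count
      tw$system$sites[[i]]$neighborhood <- 27L
      tw$system$sites[[i]]$maxActiveSites <- cyp_cap
    }
  }
  tw$drug$cypSubstrate <- TRUE
  tw$drug$affinityCyp <- affinity
  tw$drug$metabolizeProbCyp <- metabolizeProb
  tw$drug$releaseProbCyp <- releaseProb
  tw$experiment$route <- "portal_vein"
  validate_model(tw)
  tw
}

# Oracle world for binder kinetics: objects dosed directly into systemic
# blood with frozen movement; binders have own-cell neighbourhoods so the
# marginal binding probability has the closed form 1 - (1 - a/C)^count for a
# C-cell space.
binder_oracle_world <- function(n, count, cap, affinity, release) {
  tw <- sealed_world(n = n, steps = 2L)
  for (i in seq_along(tw$system$sites)) {
    s <- tw$system$sites[[i]]
    if (s$kind == "binder" && s$space == "systemic_blood") {
      tw$system$sites[[i]]$count <- as.integer(count)
      tw$system$sites[[i]]$maxActiveSites <- as.integer(cap)
      tw$system$sites[[i]]$neighborhood <- 1L
    }
  }
  tw$drug$binderSubstrate <- TRUE
  tw$drug$affinityBinder <- affinity
  tw$drug$releaseProbBinder <- release
  tw$experiment$route <- "systemic_blood"
  validate_model(tw)
  tw
}

# 4-standard-error binomial check
expect_binomial <- function(observed, n, p, label = "binomial oracle") {
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(observed - n * p), 4 * se + 1e-9,
            label = sprintf("%s: |%d - %.1f| vs 4*SE %.1f",
                            label, observed, n * p, 4 * se))
}

# analytic mono-exponential profile on a clinical-style grid
mono_profile <- function(c0 = 100, kel = 0.28,
                         grid = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8,
                                  10, 12, 24)) {
  tibble::tibble(time = grid, concentration = c0 * exp(-kel * grid))
}
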