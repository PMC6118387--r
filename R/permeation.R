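#' Henderson-Hasselbalch neutral fraction
#'
#' Fraction of drug molecules in the neutral (un-ionized) state at a given pH.
#' For a monoprotic base the neutral fraction is `1 / (1 + 10^(pKa - pH))`;
#' for a monoprotic acid it is `1 / (1 + 10^(pH - pKa))`. For polyprotic
#' drugs the product of the per-group neutral fractions is returned, which
#' treats ionizable groups as independent.
#'
#' @param pH Ambient pH, in `[0, 14]`. Vectorized.
#' @param pKa A data frame (or list coercible to one) with columns `value`
#'   (the pKa) and `type` (`"acid"` or `"base"`), one row per ionizable group.
#' @return Neutral fraction in `[0, 1]`, same length as `pH`.
#' @examples
#' neutral_fraction(7.4, data.frame(value = 6.1, type = "base"))
#' @export
neutral_fraction <- function(pH, pKa) {
  if (any(pH < 0 | pH > 14)) {
    abort("`pH` must lie in [0, 14].")
  }
  pKa <- normalize_pka(pKa)
  out <- rep(1, length(pH))
  for (i in seq_len(nrow(pKa))) {
    delta <- if (pKa$type[i] == "base") pKa$value[i] - pH else pH - pKa$value[i]
    out <- out / (1 + 10^delta)
  }
  out
}

normalize_pka <- function(pKa) {
  if (is.data.frame(pKa)) {
    df <- pKa
  } else if (is.list(pKa)) {
    df <- do.call(rbind, lapply(pKa, function(g) {
      data.frame(value = as.numeric(g$value), type = as.character(g$type))
    }))
  } else {
    abort("`pKa` must be a data frame or list of groups with `value` and `type`.")
  }
  if (!all(c("value", "type") %in% names(df))) {
    abort("`pKa` needs columns `value` and `type`.")
  }
  if (!all(df$type %in% c("acid", "base"))) {
    abort("pKa `type` must be \"acid\" or \"base\".")
  }
  df
}

#' Lipophilicity factor of the passive permeation probability
#'
#' A logistic map of logP onto `(0, 1)` that saturates near 1 for logP >= 2,
#' so that highly lipophilic drugs are membrane-permeable regardless of small
#' logP differences: `1 / (1 + 10^(1 - logP))`.
#'
#' @param logP Octanol-water partition coefficient (log10).
#' @return Value in `(0, 1)`, nondecreasing in `logP`.
#' @export
logp_permeability <- function(logP) {
  1 / (1 + 10^(1 - logP))
}

#' Passive transcellular permeation probability
#'
#' Per-step probability that a drug adjacent to a membrane crosses it by
#' passive transcellular diffusion. The probability reflects the partition
#' equilibrium: only the neutral species partitions into the membrane, and the
#' innate permeability grows with lipophilicity. It is the product of the
#' membrane leakiness (fraction of permeable membrane area), the
#' Henderson-Hasselbalch neutral fraction at the ambient pH, and the
#' logistic lipophilicity factor [logp_permeability()].
#'
#' Paracellular (pore) passage and carrier-mediated uptake are separate,
#' additive channels handled by the engine; see the methods vignette.
#'
#' @param drug A drug block from a model specification (needs `logP`, `pKa`).
#' @param membrane A membrane block (needs `leakinessFrac`).
#' @param pH Ambient pH on the drug's side of the membrane.
#' @return Crossing probability in `[0, 1]`, monotone nondecreasing in logP
#'   and in the neutral fraction.
#' @export
permeation_probability <- function(drug, membrane, pH) {
  p <- membrane$leakinessFrac * neutral_fraction(pH, drug$pKa) *
    logp_permeability(drug$logP)
  pmin(pmax(p, 0), 1)
}
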