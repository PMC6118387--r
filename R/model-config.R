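#' @name model_config
#' @title Model configuration: spaces, membranes, sites, drug, experiment
#' @description
#' A model specification (`oralsim_model`) is a nested, validated list with
#' five blocks: `system$spaces` (lattice spaces with pH and flow rate),
#' `system$flows` (advective connections between spaces), `system$membranes`
#' (permeation barriers), `system$sites` (enzyme / transporter / binder
#' placements) and the per-drug `drug` and `experiment` blocks. Packaged
#' parameterizations for midazolam and clonazepam ship as YAML files under
#' `inst/extdata/`; the system block is identical for both drugs.
NULL

# canonical space order used by the engine
SPACE_NAMES <- c(
  "stomach", "duodenum", "jejunum", "ileum", "colon_egested",
  "enterocytes_duodenum", "enterocytes_jejunum", "enterocytes_ileum",
  "portal_vein", "sinusoid", "hepatocyte", "systemic_blood", "other_organs"
)

LUMEN_SPACES <- c("stomach", "duodenum", "jejunum", "ileum")
ENTEROCYTE_SPACES <- c("enterocytes_duodenum", "enterocytes_jejunum",
                       "enterocytes_ileum")
BLOOD_SPACES <- c("portal_vein", "sinusoid", "systemic_blood")

APICAL_LUMEN <- c(enterocytes_duodenum = "duodenum",
                  enterocytes_jejunum = "jejunum",
                  enterocytes_ileum = "ileum")

#' Load a model specification
#'
#' Reads a hierarchical YAML configuration (system + drug + experiment
#' blocks), validates every field and returns an `oralsim_model`.
#'
#' @param config Path to a YAML file, a YAML string, or an already-parsed
#'   list with `system`, `drug` and `experiment` blocks.
#' @return A validated `oralsim_model` list.
#' @seealso [drug_model()] for the packaged midazolam / clonazepam models,
#'   [apply_scenario()] for what-if modifications.
#' @examples
#' spec <- drug_model("midazolam")
#' spec$drug$logP
#' @export
load_model <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (file.exists(config)) {
      config <- yaml::read_yaml(config)
    } else {
      config <- yaml::yaml.load(config)
    }
  }
  if (!is.list(config)) {
    abort("`config` must be a file path, YAML text, or a list.")
  }
  spec <- normalize_model(config)
  validate_model(spec)
  spec
}

#' Packaged drug models
#'
#' @param drug `"midazolam"` or `"clonazepam"`.
#' @return The packaged `oralsim_model` for that drug.
#' @export
drug_model <- function(drug = c("midazolam", "clonazepam")) {
  drug <- match.arg(drug)
  path <- system.file("extdata", paste0(drug, ".yaml"), package = "oralsim")
  if (!nzchar(path)) {
    abort(sprintf("packaged configuration for %s not found", drug))
  }
  load_model(path)
}

# fill defaults, coerce types, and attach class
normalize_model <- function(config) {
  for (block in c("system", "drug", "experiment")) {
    if (is.null(config[[block]])) {
      abort(sprintf("configuration is missing the `%s` block", block))
    }
  }
  sys <- config$system
  if (is.null(sys$systemSize)) sys$systemSize <- c(20L, 20L, 20L)
  sys$systemSize <- as.integer(sys$systemSize)

  spaces <- lapply(SPACE_NAMES, function(nm) {
    sp <- sys$spaces[[nm]]
    if (is.null(sp)) abort(sprintf("system$spaces is missing `%s`", nm))
    list(
      name = nm,
      dims = as.integer(sp$dims %||% sys$systemSize),
      pH = as.numeric(sp$spacepH %||% sp$pH %||% 7.4),
      flowRate = as.numeric(sp$flowRate %||% 0)
    )
  })
  names(spaces) <- SPACE_NAMES

  flows <- lapply(sys$flows, function(fl) {
    list(from = fl$from, to = fl$to,
         flowDepthFrac = as.numeric(fl$flowDepthFrac),
         flowFrac = as.numeric(fl$flowFrac))
  })

  membranes <- lapply(sys$membranes, function(m) {
    list(from = m$from, to = m$to,
         poresFrac = as.numeric(m$poresFrac %||% 0),
         interfaceDepthFrac = as.numeric(m$interfaceDepthFrac),
         leakinessFrac = as.numeric(m$leakinessFrac),
         uptakeProb = as.numeric(m$uptakeProb %||% 0),
         uptakeFrac = as.numeric(m$uptakeFrac %||% 0))
  })

  sites <- lapply(sys$sites, function(s) {
    list(kind = s$kind, space = s$space,
         count = as.integer(s$count),
         maxActiveSites = as.integer(s$maxActiveSites),
         neighborhood = as.integer(s$Neighborhood %||% s$neighborhood))
  })

  drug <- config$drug
  drug$MW <- as.numeric(drug$MW)
  drug$logP <- as.numeric(drug$logP)
  drug$pKa <- normalize_pka(drug$pKa)
  for (fld in c("affinityPgp", "releaseProbPgp", "affinityCyp",
                "releaseProbCyp", "metabolizeProbCyp", "affinityBinder",
                "releaseProbBinder")) {
    drug[[fld]] <- as.numeric(drug[[fld]])
  }
  for (fld in c("pgpSubstrate", "cypSubstrate", "binderSubstrate")) {
    drug[[fld]] <- isTRUE(drug[[fld]])
  }

  exp <- config$experiment
  exp$steps <- as.integer(exp$Steps %||% exp$steps)
  exp$TimeScale <- as.numeric(exp$TimeScale)
  exp$numSolutes <- as.integer(exp$numSolutes)
  exp$MeasureScale <- as.numeric(exp$MeasureScale)
  exp$clinicalDose <- as.numeric(exp$clinicalDose)
  exp$samplingTimes <- as.numeric(exp$samplingTimes)
  exp$samplingSteps <- as.integer(round(exp$samplingTimes / exp$TimeScale))
  exp$replicates <- as.integer(exp$replicates %||% 1L)
  exp$smoothN <- as.integer(exp$smoothN %||% 10L)
  exp$route <- exp$route %||% "stomach"
  exp$Steps <- NULL

  structure(
    list(system = list(systemSize = sys$systemSize, spaces = spaces,
                       flows = flows, membranes = membranes, sites = sites),
         drug = drug, experiment = exp),
    class = "oralsim_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_frac <- function(x, what) {
  if (is.null(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1] (got %s)", what,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

#' Validate a model specification
#'
#' Checks value ranges (probabilities and fractions in `[0, 1]`, pH in
#' `[0, 14]`, positive counts) and the space topology: the luminal chain
#' stomach -> duodenum -> jejunum -> ileum -> colon, enterocytes bridging each
#' small-intestinal segment to the portal vein, the portal vein -> sinusoid ->
#' systemic blood path with the hepatocyte lining the sinusoid, recirculation
#' back to the portal vein, and exchange with the other-organs space.
#' Errors name the offending field.
#'
#' @param spec An `oralsim_model`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_model <- function(spec) {
  if (!inherits(spec, "oralsim_model")) {
    abort("`spec` must be an `oralsim_model` (see `load_model()`).")
  }
  sys <- spec$system
  for (sp in sys$spaces) {
    if (length(sp$dims) != 3 || any(sp$dims < 1)) {
      abort(sprintf("dims of space `%s` must be a positive integer triple", sp$name))
    }
    if (sp$pH < 0 || sp$pH > 14) {
      abort(sprintf("spacepH of `%s` out of [0, 14]", sp$name))
    }
    if (sp$flowRate < 0) abort(sprintf("flowRate of `%s` must be >= 0", sp$name))
  }
  space_names <- names(sys$spaces)
  for (fl in sys$flows) {
    if (!fl$from %in% space_names) abort(sprintf("flow `from` space `%s` undeclared", fl$from))
    if (!fl$to %in% space_names) abort(sprintf("flow `to` space `%s` undeclared", fl$to))
    check_frac(fl$flowDepthFrac, sprintf("flowDepthFrac (%s->%s)", fl$from, fl$to))
    check_frac(fl$flowFrac, sprintf("flowFrac (%s->%s)", fl$from, fl$to))
  }
  for (m in sys$membranes) {
    if (!m$from %in% space_names || !m$to %in% space_names) {
      abort(sprintf("membrane %s->%s references an undeclared space", m$from, m$to))
    }
    for (fld in c("poresFrac", "interfaceDepthFrac", "leakinessFrac",
                  "uptakeProb", "uptakeFrac")) {
      check_frac(m[[fld]], sprintf("%s (%s/%s)", fld, m$from, m$to))
    }
  }
  for (s in sys$sites) {
    if (!s$kind %in% c("cyp", "pgp", "binder")) {
      abort(sprintf("unknown site kind `%s`", s$kind))
    }
    allowed <- switch(s$kind,
      cyp = c(ENTEROCYTE_SPACES, "hepatocyte"),
      pgp = ENTEROCYTE_SPACES,
      binder = c("systemic_blood", "other_organs"))
    if (!s$space %in% allowed) {
      abort(sprintf("site kind `%s` not allowed in space `%s`", s$kind, s$space))
    }
    for (fld in c("count", "maxActiveSites", "neighborhood")) {
      if (is.na(s[[fld]]) || s[[fld]] < 1) {
        abort(sprintf("%s of %s site in `%s` must be a positive integer",
                      fld, s$kind, s$space))
      }
    }
  }
  # topology: required connections must all exist
  need_flow <- list(
    c("stomach", "duodenum"), c("duodenum", "jejunum"), c("jejunum", "ileum"),
    c("ileum", "colon_egested"), c("portal_vein", "sinusoid"),
    c("sinusoid", "systemic_blood"), c("systemic_blood", "portal_vein"),
    c("systemic_blood", "other_organs"), c("other_organs", "systemic_blood"))
  have_flow <- vapply(sys$flows, function(fl) paste(fl$from, fl$to, sep = ">"), "")
  for (nf in need_flow) {
    if (!paste(nf[1], nf[2], sep = ">") %in% have_flow) {
      abort(sprintf("topology violation: missing flow %s -> %s", nf[1], nf[2]))
    }
  }
  need_mem <- list(
    c("duodenum", "enterocytes_duodenum"), c("jejunum", "enterocytes_jejunum"),
    c("ileum", "enterocytes_ileum"),
    c("enterocytes_duodenum", "portal_vein"),
    c("enterocytes_jejunum", "portal_vein"),
    c("enterocytes_ileum", "portal_vein"),
    c("sinusoid", "hepatocyte"))
  have_mem <- vapply(sys$membranes, function(m) paste(m$from, m$to, sep = ">"), "")
  for (nm in need_mem) {
    if (!paste(nm[1], nm[2], sep = ">") %in% have_mem) {
      abort(sprintf("topology violation: missing membrane %s / %s", nm[1], nm[2]))
    }
  }

  drug <- spec$drug
  if (is.na(drug$MW) || drug$MW <= 0) abort("drug `MW` must be > 0")
  for (fld in c("affinityPgp", "releaseProbPgp", "affinityCyp",
                "releaseProbCyp", "metabolizeProbCyp", "affinityBinder",
                "releaseProbBinder")) {
    check_frac(drug[[fld]], fld)
  }

  exp <- spec$experiment
  if (exp$TimeScale <= 0) abort("`TimeScale` must be > 0")
  if (exp$MeasureScale <= 0) abort("`MeasureScale` must be > 0")
  if (exp$replicates < 1) abort("`replicates` must be >= 1")
  if (exp$numSolutes < 1) abort("`numSolutes` must be >= 1")
  if (exp$steps < max(exp$samplingSteps) + exp$smoothN) {
    abort("`Steps` must be >= max(samplingSteps) + smoothN")
  }
  if (!exp$route %in% c("stomach", "portal_vein", "systemic_blood")) {
    abort(sprintf("unknown route `%s`", exp$route))
  }
  invisible(spec)
}

#' Apply a what-if scenario to a model
#'
#' Returns a new specification with one targeted physiological change;
#' the input is unchanged (the operation is pure).
#'
#' * `stomach_flow_scale`: scales gastric motility, i.e. the stomach
#'   `flowRate` and the stomach -> duodenum `flowFrac` (clipped to 1).
#' * `cyp_activity_scale`: scales the drug's `metabolizeProbCyp` (clipped
#'   to 1), emulating altered metabolic activity.
#' * `hepatic_cyp_count_scale`: scales the hepatocyte cyp expression level,
#'   rounded to the nearest integer, floor 1.
#'
#' @param spec An `oralsim_model`.
#' @param scenario One of `"stomach_flow_scale"`, `"cyp_activity_scale"`,
#'   `"hepatic_cyp_count_scale"`.
#' @param magnitude Positive multiplier (e.g. `0.01` for flow retarded to 1%).
#' @return A new validated `oralsim_model`.
#' @examples
#' slow <- apply_scenario(drug_model("midazolam"), "stomach_flow_scale", 0.01)
#' slow$system$spaces$stomach$flowRate
#' @export
apply_scenario <- function(spec,
                           scenario = c("stomach_flow_scale",
                                        "cyp_activity_scale",
                                        "hepatic_cyp_count_scale"),
                           magnitude) {
  scenario <- match.arg(scenario)
  if (!is.numeric(magnitude) || magnitude <= 0) {
    abort("`magnitude` must be a positive number")
  }
  out <- spec
  if (scenario == "stomach_flow_scale") {
    out$system$spaces$stomach$flowRate <-
      spec$system$spaces$stomach$flowRate * magnitude
    for (i in seq_along(out$system$flows)) {
      fl <- out$system$flows[[i]]
      if (fl$from == "stomach" && fl$to == "duodenum") {
        out$system$flows[[i]]$flowFrac <- min(1, fl$flowFrac * magnitude)
      }
    }
  } else if (scenario == "cyp_activity_scale") {
    out$drug$metabolizeProbCyp <- min(1, spec$drug$metabolizeProbCyp * magnitude)
  } else {
    for (i in seq_along(out$system$sites)) {
      s <- out$system$sites[[i]]
      if (s$kind == "cyp" && s$space == "hepatocyte") {
        out$system$sites[[i]]$count <- max(1L, as.integer(round(s$count * magnitude)))
      }
    }
  }
  validate_model(out)
  out
}

#' Serialize a model specification back to YAML
#'
#' Produces a normalized YAML echo of a model for provenance logging;
#' `load_model(serialize_model(spec))` round-trips.
#'
#' @param spec An `oralsim_model`.
#' @param path Optional file to write to.
#' @return The YAML text, invisibly if `path` is given.
#' @export
serialize_model <- function(spec, path = NULL) {
  sys <- spec$system
  doc <- list(
    system = list(
      systemSize = as.integer(sys$systemSize),
      spaces = lapply(sys$spaces, function(sp) {
        list(spacepH = sp$pH, flowRate = sp$flowRate)
      }),
      flows = lapply(sys$flows, function(fl) {
        list(from = fl$from, to = fl$to,
             flowDepthFrac = fl$flowDepthFrac, flowFrac = fl$flowFrac)
      }),
      membranes = lapply(sys$membranes, function(m) {
        m[c("from", "to", "poresFrac", "interfaceDepthFrac", "leakinessFrac",
            "uptakeProb", "uptakeFrac")]
      }),
      sites = lapply(sys$sites, function(s) {
        list(kind = s$kind, space = s$space, count = s$count,
             maxActiveSites = s$maxActiveSites, Neighborhood = s$neighborhood)
      })
    ),
    drug = c(
      spec$drug[c("name", "MW", "logP")],
      list(pKa = lapply(seq_len(nrow(spec$drug$pKa)), function(i) {
        list(value = spec$drug$pKa$value[i], type = spec$drug$pKa$type[i])
      })),
      spec$drug[c("pgpSubstrate", "affinityPgp", "releaseProbPgp",
                  "cypSubstrate", "affinityCyp", "releaseProbCyp",
                  "metabolizeProbCyp", "binderSubstrate", "affinityBinder",
                  "releaseProbBinder")]
    ),
    experiment = list(
      Steps = spec$experiment$steps,
      TimeScale = spec$experiment$TimeScale,
      numSolutes = spec$experiment$numSolutes,
      MeasureScale = spec$experiment$MeasureScale,
      clinicalDose = spec$experiment$clinicalDose,
      samplingTimes = spec$experiment$samplingTimes,
      replicates = spec$experiment$replicates,
      smoothN = spec$experiment$smoothN,
      route = spec$experiment$route
    )
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.oralsim_model <- function(x, ...) {
  cat(sprintf("<oralsim_model> %s\n", x$drug$name %||% "unnamed drug"))
  cat(sprintf("  drug: MW %.1f, logP %.2f, metabolizeProbCyp %.3g\n",
              x$drug$MW, x$drug$logP, x$drug$metabolizeProbCyp))
  cat(sprintf("  experiment: %d steps x %.3g h/step, %d solutes, route %s\n",
              x$experiment$steps, x$experiment$TimeScale,
              x$experiment$numSolutes, x$experiment$route))
  cat(sprintf("  system: %d spaces, %d flows, %d membranes, %d site groups\n",
              length(x$system$spaces), length(x$system$flows),
              length(x$system$membranes), length(x$system$sites)))
  invisible(x)
}
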