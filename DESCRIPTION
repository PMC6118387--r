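Package: oralsim
Title: Agent-Based Biomimetic Simulation of Human Oral Drug Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, agent-based biomimetic model of human oral drug
    absorption and first-pass metabolism. Drug molecules are autonomous agents
    performing biased random walks on three-dimensional lattice spaces that map
    to the stomach, small-intestinal segments, enterocytes, portal vein, liver
    sinusoid, hepatocyte, systemic blood and peripheral organs; membranes are
    crossed probabilistically according to lipophilicity and
    Henderson-Hasselbalch ionization, and metabolic enzymes, efflux
    transporters and nonspecific binders are spatial site objects with
    probabilistic bind/convert/release rules. The package runs replicated
    in-silico bioavailability experiments (oral, hepatic-portal and
    intravenous dosing), smooths and scales the raw amount series to
    concentration-time profiles, performs noncompartmental pharmacokinetic
    analysis (AUC, Cmax, Tmax, Kel, T1/2, CL/F, V/F), decomposes oral
    bioavailability into F = Fa.Fg x Fh, and scores simulated profiles against
    referent clinical profiles with three-level similarity criteria (visual
    band coverage, SD-weighted RMSE/MAPE, and descriptive PK-parameter
    differences). Packaged parameterizations for midazolam and clonazepam are
    included, together with what-if scenario modifiers and synthetic
    one-compartment referent generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    withr,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
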