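Package: tacropk
Title: Population Pharmacokinetics of Oral Tacrolimus in Mice with
    Treatment-Group Covariates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Steady-state one-compartment population pharmacokinetic
    modelling of whole-blood tacrolimus under repeated oral dosing, as used
    to quantify microbiome-driven changes in drug exposure. Implements the
    closed-form oral one-compartment model, log-normal between-subject
    variability with treatment-group covariates on apparent clearance,
    estimation by the stochastic approximation EM (SAEM) algorithm with
    Metropolis-Hastings sampling of individual random effects,
    importance-sampling marginal likelihood for error-model selection,
    empirical-Bayes conditional modes with derived AUC0-24 and half-life,
    variance-equality and covariate inference on the derived exposures, and
    a synthetic-study generator emulating a sparse mouse design so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
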