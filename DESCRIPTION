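Package: bgicd
Title: Basal Ganglia Network Model of Medication-Induced Impulsivity in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a cortico-basal-ganglia network model of reward and
    punishment learning under dopamine and serotonin modulation, and applies
    it to medication-induced impulse control disorder (ICD) in Parkinson's
    disease.  The striatum learns action values and outcome risk through
    receptor-specific dopamine gain functions; an excitatory-inhibitory
    STN-GPe loop feeding a thalamic race-to-threshold integrator converts
    pathway drives into choices and reaction times.  The package provides
    the probabilistic reward/punishment categorization task, per-subject
    condition parameter sets for healthy controls and three Parkinson's
    cohorts, session and group simulators, a behavioral statistics pipeline
    (optimality proportions, iterative Grubbs outlier screening, one-way
    ANOVA, post-hoc t-tests), a two-step grid-search plus genetic-algorithm
    parameter-fitting procedure, and a synthetic cohort generator for
    end-to-end testing without empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
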