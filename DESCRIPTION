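Package: ttemeta
Title: Model-Based Meta-Analysis of Digitized Survival Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs pseudo individual patient data from digitized
    Kaplan-Meier curves and numbers-at-risk tables, fits hierarchical
    parametric time-to-event models (Weibull, Gompertz, log-logistic) to
    multi-study survival fractions with study-level lognormal random effects,
    screens covariates by Wald tests with AIC model selection, and simulates
    long-term median survival and landmark survival rates with uncertainty.
    Includes a synthetic multi-study trial generator for end-to-end testing
    and published parameter sets for osimertinib first- and second-line
    overall and progression-free survival.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
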