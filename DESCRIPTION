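Package: herdsense
Title: Sensor-Based Feeding and Rumination Phenotyping of Dairy Cows
Version: 0.1.0
Authors@R:
    person("Herdsense", "Maintainers", email = "maintainers@herdsense.example", role = c("aut", "cre"))
Description: An end-to-end pipeline from precision-livestock sensor streams
    (automatic feed-station visits, neck-mounted tri-axial accelerometers,
    per-milking milk yields, locomotion scores) to behavioural phenotypes of
    loose-housed dairy cows and mixed-model estimates of lameness effects.
    Includes a calibrated synthetic-barn generator, two-pass regression
    cleaning of feed-station visits, hidden Markov model classification of
    rumination from windowed variance and Fourier band-power features,
    daily behavioural characteristics with inter- and intra-individual
    coefficients of variation, and single-random-term linear mixed models
    fitted by profiled (restricted) maximum likelihood with likelihood-ratio
    inference and least-square means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
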