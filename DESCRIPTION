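Package: herbiwue
Title: Herbarium-Based Inference of Long-Term CO2 Responses in Tropical Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring long-term plant gas-exchange responses to rising
    atmospheric CO2 from herbarium specimens. Computes the anatomical maximum
    stomatal conductance from stomatal density, pore length and guard-cell width;
    derives carbon isotope discrimination, ci/ca and intrinsic water-use
    efficiency from leaf delta-13C; predicts Rubisco carboxylation capacity from
    leaf functional traits with a mixed-effects model and solves the coupled
    Rubisco-limited photosynthesis-diffusion system per specimen; propagates
    intraspecific regression uncertainty in maximum stomatal conductance through
    the simulation with multivariate-normal Monte-Carlo coefficient draws to put
    confidence intervals on response slopes; compares stomatal phenotypic spaces
    of plant communities with 2-D kernel densities and the Jensen-Shannon
    divergence; and includes a calibrated synthetic herbarium-community generator
    so the whole pipeline is testable without restricted specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
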