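Package: nwlchoice
Title: Mouse-Tracking Food Choice Under Nutrient Warning Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-alternative food-choice
    experiments with front-of-package nutrient warning labels (NWL). Provides
    constrained stimulus-pair sequence generation, mouse-trajectory conflict
    metrics (area under the curve, y-axis crossings, initiation time), trial
    quality-control filters, maximum-likelihood fitting of a four-parameter
    drift-diffusion model via the Wiener first-passage-time density,
    Monte-Carlo parameter-recovery validation, and descriptive behavioral
    estimates (healthy-choice and choice-reversal probabilities, conflict
    changes by decision path) with participant-cluster bootstrap intervals.
    A synthetic-data generator with known ground-truth parameters makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
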