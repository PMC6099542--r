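Package: petkin
Title: Compartmental Kinetic Modelling of TSPO PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for dynamic TSPO PET studies in small
    animals: metabolite-corrected arterial input function construction from
    plasma samples, Hill-model parent-fraction correction of brain
    time-activity curves, a two-tissue-compartment model with an irreversible
    vascular-trapping term (K1, k2, k3, k4, Kb), weighted nonlinear
    least-squares estimation with per-parameter percent standard errors and
    percent-SE-based subject exclusion, total distribution volume (VT) and
    AUC summaries, and Welch group comparisons. Includes a synthetic-cohort
    generator emulating a control vs. LPS neuroinflammation study so the
    whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
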