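Package: prostadss
Title: Perceptron-Based Decision Support for Prostate Cancer Detection and Staging
Version: 0.1.0
Authors@R: person("prostadss", "maintainers", email = "maintainers@prostadss.org",
    role = c("aut", "cre"))
Description: Tools for a rule-and-network decision-support pipeline for
    prostate cancer staging. Quantifies a lesion from a medical image via
    Canny-style edge detection and an eight-direction Freeman chain code
    (pixel area by discrete Green's theorem, mean gray level), validates and
    scales a six-marker serum panel (TPSA, RBC, HB, FPSA, PAP, PSMA),
    trains two small sigmoid perceptrons (marker channel and image channel)
    with momentum gradient descent, and fuses their scores with a four-case
    rule table into a DPC score, a TNM-style clinical stage (I-IV) and a
    treatment recommendation. Includes a reproducible synthetic-cohort
    generator (stage-conditioned marker panels and elliptical lesion images
    with ground truth) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
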