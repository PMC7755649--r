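Package: erythrosim
Title: Erythropoiesis Modeling and Erythropoietin Requirement Analysis in
    Virtual Hemodialysis Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic and phenomenological models of erythropoiesis for
    studying how red-blood-cell life span drives erythropoietin (Epo)
    requirements in hemodialysis patients. Provides a calibrated virtual
    patient population generator (truncated-normal life spans, lognormal
    endogenous Epo), an Epo-regulated age-structured model of the circulating
    red-cell pool with a closed-form steady state and a dynamic simulator, a
    per-patient required-Epo solver targeting a hemoglobin window, and binned
    population summaries (box-plot statistics per life-span bin and mean
    required Epo increase on a life-span by Epo-level grid).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
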