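Package: petdosim
Title: Preclinical PET Radioligand Evaluation and Internal Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for positron emission tomography (PET)
    radioligands from ex vivo counting data: standardized uptake value (SUV)
    biodistribution analysis with blocking statistics, non-compartmental
    plasma pharmacokinetics (terminal half-life, AUC to infinity, clearance),
    receptor saturation binding (Kd/Bmax), internalization time courses,
    quantitative autoradiography calibration, and rat-to-human internal
    dosimetry following the MIRD schema (residence times by trapezoidal
    integration with an exponential tail, organ absorbed doses from S-value
    tables, and the ICRP-60 effective dose). Includes seed-deterministic
    synthetic-data generators emulating the ex vivo study designs so that
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
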