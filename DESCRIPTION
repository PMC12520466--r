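Package: bloodmta
Title: Blood Dosimetry and Activity Planning for Pediatric Radioiodine
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for I-131 blood dosimetry after thyroidectomy in
    pediatric differentiated thyroid cancer. Fits mono-exponential
    whole-body retention from two timed exposure-rate readings at 1 m,
    computes the blood absorbed-dose coefficient from a simplified
    compartment formula (beta self-dose from blood volume plus a photon
    whole-body term scaled by weight^(2/3)), derives the maximum tolerated
    activity under the classical 2 Gy blood-dose and 4.4 GBq 48-h
    whole-body retention limits, and compares empirical risk-stratified,
    body-weight-based and 100 MBq/kg (Dutch) prescription strategies under
    an as-high-as-safe-administration (AHASA) cap. Includes a seeded
    synthetic-cohort generator and cohort-level summaries (strategy means,
    weight-versus-dose regression, safety audit).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
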