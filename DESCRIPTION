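Package: mtplacenta
Title: Multiples of a Normal Term Placenta (Mtp) Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the 'Multiples of a normal term placenta' (Mtp) index
    for the angiogenic biomarkers placental growth factor (PlGF) and soluble
    fms-like tyrosine kinase-1 (sFlt-1), scoring each serum dosage against
    fixed term-pregnancy reference centiles. Classifies the sFlt-1/PlGF
    ratio into four risk classes with cutoffs that switch at 34+0 weeks of
    gestation, assigns measurements to named Mtp categories, and produces
    stratified median/IQR time-to-delivery summary tables and a
    category-by-risk-class cross-tabulation. Includes a seeded synthetic
    cohort generator emulating a hospital cohort of hypertensive pregnancies
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, tidyr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
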