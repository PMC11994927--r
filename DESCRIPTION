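Package: sgltsim
Title: Whole-Body Pharmacokinetics and Renal Glucose Excretion of SGLT2 Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A minimal whole-body physiologically based pharmacokinetic (PBPK)
    model of four sodium-glucose cotransporter 2 (SGLT2) inhibitors
    (dapagliflozin, canagliflozin, empagliflozin, ipragliflozin) coupled to a
    mechanistic three-segment renal-tubule model of glucose reabsorption under
    competitive and slow-binding transporter inhibition. Simulates plasma
    concentration-time profiles and 24-hour urinary glucose excretion (UGE) in
    virtual type 2 diabetes populations across chronic kidney disease stages,
    computes standard prediction-accuracy statistics (fold error, MPE, AFE,
    AAFE, band fractions) against paired observed/predicted tables, generates
    synthetic observed datasets with multiplicative lognormal noise, and runs
    dosage-regimen scenario grids that rank regimens by glucosuric effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
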