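Package: tissueorigin
Title: Real-Time PCR Tissue-of-Origin Testing for Blood and
    Lymphoblastoid Cell Line DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing blood-derived from lymphoblastoid
    cell line (LCL)-derived DNA with a panel of real-time PCR assays:
    amplification- and melting-curve simulation, Cq calling by the
    second-derivative-maximum method, melting-peak (Tm) extraction,
    GAPDH-normalised Ct-ratio classification of EBV load and rearranged
    TCR-gamma with an abstention ("uncertain") class, a Tm rule for
    rearranged TCR-beta, two-of-three vote combination, and diagnostic
    performance evaluation (sensitivity, specificity, PPV, NPV, accuracy,
    annotation concordance). Also implements a three-CpG (ELOVL2, KLF14,
    TRIM59) DNA-methylation age-prediction model and its evaluation on
    blood versus LCL samples, together with a synthetic cohort generator
    that emulates the blood/LCL signal structure so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
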