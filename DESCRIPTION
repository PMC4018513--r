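Package: hdxflow
Title: Automated Peptide-Level Analysis of Hydrogen-Deuterium Exchange
    Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated workflow for bottom-up hydrogen-deuterium
    exchange mass spectrometry (HDX-MS). Detects peptide features de novo in
    an undeuterated reference LC-MS map by sparse regression of Averagine
    isotope patterns (non-negative least angle regression with BIC model
    selection), assigns candidate sequences by mass with internal m/z
    recalibration, pepsin cleavage scoring and target-decoy FDR estimation,
    aligns deuterated maps to the reference by a nonlinear retention-time
    mapping inferred from predicted deuterated masses, and estimates
    per-peptide deuterium-incorporation distributions by boosted Gold
    deconvolution with centroid and back-exchange correction. Includes a
    synthetic-data generator producing centroided LC-MS maps with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
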