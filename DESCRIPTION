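Package: breedgain
Title: Genomic Selection and Genetic Gain Analysis for Plant Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genomic selection in line-breeding
    programs such as irrigated rice: SNP genotype quality control and dosage
    encoding, a single-random-effect REML mixed-model solver (spectral form)
    powering ridge-regression BLUP, pedigree BLUP and genomic BLUP, two-stage
    multi-environment trial analysis (per-trial BLUEs with BIC-driven blocking
    choice, then across-trial BLUPs), cross-validation with training-population
    size optimization, sparse-testing design construction, and genetic-gain
    (era) regression. A breeding-program simulator with known true breeding
    values makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    lme4,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
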