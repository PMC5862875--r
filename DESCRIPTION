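Package: mmcap
Title: Integrative Targeted-Capture Mutation Analysis for Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for a multiple-myeloma targeted-capture sequencing
    panel covering copy number variants, IGH/MYC translocations, and somatic
    point mutations. Calls CNVs from per-probe log2 tumor/normal depth ratios
    via recursive binary segmentation with a Gaussian-mixture diploid-noise
    filter; tunes precision-first split-read/discordant-pair thresholds for
    translocation candidates (including a panel-of-normals mode for MYC);
    applies the variant filtering, VAF concordance, and depth-downsampling
    yield analyses; and performs the integrative statistics: pairwise
    co-occurrence and mutual exclusivity (Fisher exact), the AID WRCY-motif
    binomial signature test, expression outlier detection, and Kaplan-Meier,
    log-rank, and Cox progression analysis. Ships a seeded synthetic-cohort
    generator emulating every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    withr
Config/testthat/edition: 3
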