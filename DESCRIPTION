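Package: pnquant
Title: Quantitative Pronuclear Morphometry from Time-Lapse Embryo Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative assessment of the two pronuclei (PNs) of
    human zygotes from time-lapse incubator imaging. Selects the clearest
    focal plane of each Z-stack by variance of the Laplacian, detects and
    tracks the female and male pronuclei across frames, fits the exponential
    area growth model f(t) = beta1 * beta2^t to extract the fictitious
    area-at-ICSI coefficient beta1 under four fitting-window variants, parses
    preimplantation genetic testing (PGT) karyotype strings into chromosomal
    error categories, and relates within-patient beta1 rankings to
    chromosomal outcomes via rank-stratified rate tables, Woolf odds ratios,
    Pearson chi-square, Spearman correlation and Cochran heterogeneity. A
    seeded simulator generates synthetic zygote trajectories, rendered
    Z-stacks, detector error models and rank-dependent PGT outcomes for
    benchmarking the whole pipeline against known ground truth.
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
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse,
    withr
Config/testthat/edition: 3
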