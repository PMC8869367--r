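Package: rgstab
Title: Reference-Gene Stability Analysis for Small-RNA qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Selects stable reference genes from quantification-cycle (Ct)
    matrices of small-RNA qPCR panels, with an emphasis on low-input designs
    such as extracellular-vesicle miRNA profiling. Implements detection-limit
    censoring and presence filtering, spike-in and global-mean equalization,
    four classical stability algorithms (stepwise pairwise-variation
    exclusion, model-based variance decomposition, descriptive dispersion
    statistics, and the mean pairwise-SD method), comprehensive ranking by
    the geometric mean of per-algorithm ranks, comparative-Ct relative
    quantification of target miRNAs with outlier screening and a compound
    fold-change/significance criterion, and a seeded synthetic panel
    generator with ground truth for benchmarking recovery of stable genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
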