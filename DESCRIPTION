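Package: haplopool
Title: Haplotype Frequency Estimation for Rare Variants from Pooled Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates haplotype frequency distributions of rare variants from
    pooled genotype data (per-pool minor-allele totals). Implements the
    collapsed-data maximum likelihood estimator obtained by inclusion-exclusion
    over zero-pattern frequencies, and EM algorithms restricted to an internal
    candidate haplotype list built from the collapsed data (CD list), with
    single-variant augmentation, per-iteration trimming, and adaptive threshold
    selection benchmarked against the collapsed-data estimate of the ancestral
    haplotype frequency. Includes the design calculations for pooling studies
    (induced collapsed-data distributions, capture probabilities, pool-count
    bounds), a Hardy-Weinberg simulator of pooled datasets, and a simulation
    study driver with tidy outputs and ggplot2 visualisations.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
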