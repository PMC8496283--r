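Package: ascbias
Title: Simulating SNP Ascertainment Bias Under Structured Demographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how SNP ascertainment schemes distort population-genetic
    inference under different demographic histories. Simulates neutral coalescent
    replicates with recombination under island, stepping-stone and serial
    population-split models; applies single-population, merged-panel and
    independent-panel SNP discovery schemes with minor-allele-frequency
    thresholds and random marker selection; and measures the resulting bias in
    the joint site-frequency spectrum, within- and between-population diversity,
    Hudson-style FST and EIGENSTRAT-style principal component analysis, relative
    to full re-sequencing baselines. Replicate haplotype data are generated by
    the msprime coalescent engine through an ms-format text interface and can
    also be read from any ms-compatible simulator output.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with msprime (>= 1.0), available as
    'python' on the PATH, for coalescent simulation. Parsing ms-format input
    requires no external software.
Config/testthat/edition: 3
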