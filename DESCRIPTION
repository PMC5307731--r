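Package: methdeconv
Title: Reference-Based Cell-Type Deconvolution of DNA Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions in heterogeneous tissue samples
    from Illumina-style DNA methylation beta-value profiles. Builds reference
    databases of cell-type-specific differentially methylated CpGs (optionally
    restricted to DNase hypersensitive sites), infers mixture weights by
    ordinary least squares, robust (Huber) regression, nu-support-vector
    regression or inequality-constrained quadratic programming, benchmarks the
    algorithms on in-silico mixtures under M-value Gaussian noise, and adjusts
    epigenome-wide association studies for estimated cell composition with
    sensitivity/specificity scoring against gold-standard CpG lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
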