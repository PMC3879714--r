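Package: micropanel
Title: High-Throughput qPCR Microbiota Panel Quantification and Amplicon
    Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for microbiota profiling with a 24-assay rRNA-gene
    primer panel run on a 48x48 microfluidic singleplex qPCR chip, combined
    with tagged-amplicon sequencing. Covers the primer panel data model with
    degenerate in-silico PCR, raw-Cq calibration and Livak 2^dCq relative
    quantification, a multivariate Gaussian statistics pipeline (EM imputation
    of missing log-abundances, Wilks likelihood-ratio tests for gut section
    and diarrhoeic status, Wilcoxon tests on read densities), a
    barcode/tag/primer demultiplexer with greedy OTU clustering and weighted
    8-mer read-density taxonomy, and a seeded synthetic-data generator that
    emulates chip runs and 454-style reads for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    S4Vectors,
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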