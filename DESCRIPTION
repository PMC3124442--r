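Package: tilemeth
Title: Methylation Region Calling for Enrichment Tiling Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of DNA-methylation enrichment tiling-microarray
    experiments (MBD-chip / MeDIP-chip style). Corrects GC-content probe
    bias using "null probes" from ultra-low-CpG regions, smooths adjusted
    log-ratios with a running median, calls methylated regions with
    additive Z-scores, estimates false discovery rates from replicate
    total-input hybridizations, detects differentially methylated regions
    between two samples, annotates regions by genomic compartment, and
    tests annotation enrichment against length- and coverage-matched
    random region sets. Includes a synthetic-data simulator that emulates
    the saturating CpG-dependent enrichment response, GC-dependent probe
    effects and positional autocorrelation of real arrays, so the whole
    pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
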