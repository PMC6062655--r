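Package: poolhet
Title: Pooled-Heterozygosity Selective-Sweep Scans from Multi-Sample VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective-sweep regions in resequenced
    populations with the pooled-heterozygosity (Hp) sliding-window scan.
    Reads multi-sample VCFs, pools per-site major/minor allele counts within
    each population, computes windowed Hp and its genome-wide Z transform,
    calls and merges significant windows into candidate sweep regions, and
    classifies regions shared across populations. Includes a synthetic-data
    generator that plants sweeps into a neutral background so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
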