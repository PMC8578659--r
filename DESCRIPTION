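Package: hicarch
Title: Chromatin Architecture Statistics for Cis Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("hicarch", "developers", email = "hicarch@example.org",
           role = c("aut", "cre"))
Description: Statistics for cis Hi-C contact matrices aimed at comparing
    higher-order chromatin architecture between conditions: Knight-Ruiz style
    matrix balancing, observed/expected and Pearson-correlation transforms,
    A/B compartment eigenvector profiles with GC-content sign orientation,
    five-quantile saddle maps and bootstrapped compartment strength,
    normalized insulation scores with boundary calls, rescaled TAD and loop
    aggregate maps with strength statistics, region-set contact enrichment
    against random-region nulls (Mann-Whitney U), Pearson-correlation
    differences and contact log2 fold-changes, and entropy-based
    stage-specificity scoring with K-means staging clusters. A synthetic
    contact-map and expression generator with planted compartments, TADs,
    loops and a peri-nucleolar-heterochromatin-like block makes every
    statistic verifiable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
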