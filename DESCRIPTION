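Package: spikedomains
Title: Spike-In Calibrated CUT&RUN Domain Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative comparison of CUT&RUN chromatin profiles across
    samples using heterologous spike-in calibration. Implements spike-in
    scale factors (a fixed constant divided by mapped spike-in reads),
    base-pair coverage in genomic bins, a simplified sparse-enrichment
    domain caller, replicate peak merging, partition of merged peak lists
    into disjoint segments with dominant-segment length filtering to define
    differential domains, k-means clustering of region-by-sample signal
    matrices with knee-based selection of k, and fragments-per-kilobase
    spike-scaled region quantification. A seeded fragment simulator plants
    broad silenced domains, promoter turnover peaks, uniform
    replication-coupled background, and spike-in chromatin at a controlled
    cell ratio, so the whole pipeline is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
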