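Package: hkgscout
Title: Housekeeping Gene Discovery from RNA-Seq Counts by
    Normalization-Stratified Coefficient-of-Variation Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate housekeeping genes from bulk RNA-seq count
    matrices. Implements nine count normalization schemes (library size, total
    count, upper quartile, median, quantile, RPKM, TPM, trimmed mean of
    M-values, and median-of-ratios size factors), selects genes whose
    expression coefficient of variation falls below a percentile threshold
    (default the 2nd percentile), intersects per-method selections into a
    consensus set, scores normalizations by log-ratio bias and variance,
    summarizes expression-ratio distributions, and validates selections by
    overlap with external gene lists. A seeded negative-binomial simulator
    with planted housekeeping and differentially expressed genes provides
    ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    DESeq2,
    optparse
Config/testthat/edition: 3
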