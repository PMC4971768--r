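Package: segloop
Title: Sub-Kilobase Chromatin Loop Calling from Restriction-Fragment Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies small (2-25 kb) chromatin loops from restriction-fragment
    resolution Hi-C contact data. The genome is digested in silico and fragments are
    merged into 500 bp - 1 kb segments; a monotone log-log smoothing-spline model of
    contact-frequency decay with genomic distance is fitted on equal-occupancy
    distance bins; per-segment sequencing bias and fragment-end-density effects enter
    a factor model of bias-adjusted contact probabilities; each observed segment pair
    is tested with a negative-binomial convolution test and calls are selected by
    Benjamini-Hochberg q-value. Includes classification of gene self-loops (5'/3')
    from TSS-anchored focal points, shift-coordinate permutation nulls for feature
    enrichment, and a fully seeded synthetic Hi-C generator with planted loops for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
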