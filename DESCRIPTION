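Package: dhsatlas
Title: Cross-Sample Integration of DNase-I Hypersensitive Site Peak Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a consensus atlas of replicable open-chromatin sites from
    per-sample DNase-I hypersensitive site (DHS) peak calls. Peaks from
    hundreds of samples are aligned across samples by Markov clustering of an
    interval-overlap (Jaccard) similarity graph, every aligned site is quality
    checked with a replicate-concordance chi-squared test combined over
    randomized replicate pairings, and the surviving sites are assembled into
    a batch-corrected per-cell-type accessibility matrix via per-sample
    scaling, subsampled quantile normalization and median collapse. Includes a
    fully seeded synthetic peak-call simulator with ground truth for
    end-to-end validation, and exporters for BED, GFF3 and TSV matrix formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    IRanges,
    withr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
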