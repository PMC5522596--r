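Package: enhscan
Title: Predicting Active Intergenic Enhancers from Chromatin Accessibility,
    H3K9ac and DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates DNase I hypersensitive sites, H3K9ac ChIP-seq
    enrichment and low DNA methylation (CG and CHG contexts) into
    intergenic enhancer candidate predictions for plant genomes profiled
    in two tissues. Provides replicate consensus peak filtering with a
    reciprocal 70% overlap rule, a run-based segmenter for low and
    unmethylated regions, genome partitioning into promoter, exon,
    intron, flanking, TE and distal classes, tissue-specificity ranking
    with permutation p-values, H3K9ac asymmetry orientation and k-means
    signal-profile categories, target-gene linking from differential
    expression, transposable-element family and motif enrichment tests,
    permutation enrichment within the mappable genome, and a
    truth-annotated synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
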