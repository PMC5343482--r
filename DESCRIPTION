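Package: enhancerscape
Title: Differential Enhancer Landscape Analysis from ChIP-seq Tag Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cis-regulatory elements from ChIP-seq aligned-tag
    data: tag filtering and blacklist masking, windowed enrichment-region
    calling with replicate reproducibility assessment (IDR-style), promoter
    and enhancer classification from H3K27ac and H3K4me3 marks, super-enhancer
    stitching and ranking, transcribed-region segmentation from PolII counts,
    immunoprecipitation-efficiency corrected differential signal
    quantification via promoter-mode normalization, GC-corrected transcription
    factor motif enrichment, and enhancer-to-gene expression linkage with gene
    ontology enrichment. Includes a synthetic-data generator reproducing the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
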