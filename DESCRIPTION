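Package: saltnet
Title: Construction of Salt-Stress ceRNA Networks from Whole-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building miRNA-centric competing endogenous RNA (ceRNA)
    networks from whole-transcriptome RNA-seq of a two-condition plant stress
    experiment. Provides count normalization (FPKM, CPM, SRPBM) and a
    negative-binomial exact test for per-class differential expression;
    positional filtering and classification of lncRNA candidates with cis-target
    pairing; back-splice junction calling and typing of circRNAs from
    chimeric-segment alignments; plant-style miRNA target prediction with an
    Allen complementarity score and a nearest-neighbor duplex free-energy model;
    endogenous target mimic (miRNA sponge) detection; and assembly, hub/sponge
    annotation and export (SIF, GraphML) of the resulting network. A fully
    deterministic synthetic-data generator with planted ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    xml2,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
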