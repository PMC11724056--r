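Package: scarscreen
Title: Integrated Multiomics Screening of Inflammation-Related Scarring Genes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated multiomics pipeline for identifying
    inflammation-related scarring genes in skin wound healing. Combines
    single-cell RNA-seq clustering, subclustering and marker detection;
    negative-binomial differential expression of bulk wound samples from
    wild-type versus inflammation-deficient mice; reference-based spot
    deconvolution of Visium-style spatial transcriptomics by multinomial
    EM; region-level spatial differential expression; ligand-receptor
    communication scoring with permutation nulls and optimal-transport
    signaling direction fields; and a cross-modality intersection screen
    that prioritizes fibroblast scarring genes against a collagen anchor.
    A synthetic-data module generates all three modalities with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
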