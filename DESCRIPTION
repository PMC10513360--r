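Package: compot
Title: Compositional Annotation Transfer by Entropic Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers categorical annotations (for example cell types) from an
    annotated single-cell reference to unannotated observations such as spatial
    beads, single cells with technical artifacts, or binned single-molecule
    data, as compositional (fractional) annotations. The core solver is
    entropically regularized, semi-unbalanced optimal transport on
    expression-space dissimilarities, combined with boosters for platform
    normalization, multi-center reference profiles and bisectioned recursive
    annotation. Includes count splitting into pure per-category contributions
    by matrix equivalence scaling, segmentation-free single-molecule annotation
    and image-free segmentation, spatial co-occurrence and neighborhood
    statistics, region definition, annotation coordinates, enrichment tests,
    and simulators for bead mixtures, dropout and ambient-RNA perturbed
    single-cell counts, and clonal fate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
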