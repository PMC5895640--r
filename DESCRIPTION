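Package: stressnet
Title: Integrative Co-Expression Network and Causal Orienting Analysis for
    Recombinant Inbred Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end systems-genetics pipeline for strain-mean
    transcriptomes of recombinant inbred panels measured under multiple
    treatment conditions. Selects highly variable genes by decomposing the
    coefficient-of-variation distribution into two normal components with an
    EM algorithm, builds weighted gene co-expression networks (soft
    thresholding, topological overlap, average-linkage module detection,
    module eigengenes), classifies module condition-response patterns and
    tests them by one-way ANOVA, correlates module eigengenes with
    behavioral traits, measures cross-condition module preservation and
    specificity by Fisher exact overlap tests, overlays high-confidence
    protein-protein interactions to extract intramodular subnetworks, and
    orients genotype-gene-phenotype causal chains with single-marker
    regression (LRS/LOD) and structural-equation-model based local edge
    orienting (LEO) scores. Ships a synthetic-data generator emulating a
    BXD-like study design with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
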