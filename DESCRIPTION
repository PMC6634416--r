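Package: visgrad
Title: Transcriptomic Gradient Analysis of Human Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing regional gene-expression gradients across the
    cytoarchitectonic areas of human occipitotemporal cortex. Implements the
    full analysis chain for Allen-Human-Brain-Atlas-style microarray data:
    probe filtering and collapsing, donor-wise z-scoring, MNI-coordinate
    assignment of tissue samples to regions of interest, one-way-ANOVA gene
    ranking with a PCA alternative, partition of selected genes into opposed
    ascending and descending expression gradients, a bootstrap test of the
    gradient structure against a linear hypothesis matrix, a rooted-leaf WPGMA
    hierarchy of regions with an ordering bootstrap, a leave-one-out
    winner-take-all tissue-origin classifier, anatomy (cortical thickness and
    T1w/T2w) correlations and regressions, a hypergeometric cell-type-marker
    overlap test, and developmental and cross-species expression-slope
    analyses. A synthetic-data module generates every input the pipeline
    consumes, with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
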