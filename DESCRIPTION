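Package: phenorev
Title: Reversal Probabilities, Signature Algebra, Behavioral Discrimination
    and Inclusion-Body Quantification for Disease-Modification Studies
Version: 0.1.0
Authors@R:
    person("Phenorev", "Developers", email = "maintainer@phenorev.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how far a therapeutic intervention pushes
    a disease model back toward the healthy state, across three readouts.
    For transcriptomics, a posterior-probability classifier expresses each
    gene's treatment effect as a multiple (alpha) of its disease effect and
    integrates the joint normal uncertainty on a quantile grid to assign
    five reversal classes and an overall reversal probability; companion
    functions build differential-expression signatures (BH adjustment,
    fold-change filters, responder exclusion, set algebra) and run
    hypergeometric gene-set overrepresentation with per-set reversal
    summaries. For high-content behavioral data, decorrelated ranked
    feature analysis fits Gaussian group clouds in a whitened feature
    space and scores group separation with an overlap-based Discrimination
    Index (50-100 percent), permutation p-values, projections of treated
    groups onto a reference space, and 0-100 rescue scores. For
    fluorescence microscopy, a scripted recipe quantifies protein
    aggregate spots: sliding-parabola background removal, nuclei
    detection with an area floor, texture-based spot segmentation with
    size, intensity and ring-contrast filters, and densities per square
    millimetre. Synthetic generators with known ground truth cover all
    three data types so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
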