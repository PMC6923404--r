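Package: cytoda
Title: Multiplexed Mass Cytometry Preprocessing, Clustering and
    Differential Abundance
Version: 0.1.0
Authors@R:
    person("Cytoda", "Developers", email = "cytoda@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed single-cell mass cytometry
    (CyTOF) experiments: reading and writing FCS event files, EQ-bead
    time-interval normalization of instrument sensitivity drift, DNA and
    event-length singlet gating, Boolean mass-tag debarcoding, spillover
    compensation by non-negative least squares, arcsinh transformation,
    two-level self-organizing-map consensus meta-clustering, bin-wise
    differential-abundance testing on a t-SNE embedding with a negative
    binomial GLM, and cluster-level differential abundance with a binomial
    generalized linear mixed model.  Includes a synthetic-data generator
    with known ground truth (barcoded pooled acquisitions, beads, drift,
    spillover, doublets, spike-in abundance shifts) so every stage can be
    validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    Rtsne,
    jsonlite,
    lme4,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    edgeR,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
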