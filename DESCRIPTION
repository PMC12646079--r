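Package: neuroperm
Title: Permutation Inference for Longitudinal Mouse Brain MRI Connectivity
    and Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of longitudinal mouse MRI studies with
    permutation-based inference throughout. Converts regional BOLD time
    courses into Fisher-z functional connectivity graphs, applies
    proportional sparsity thresholding, and summarises mean connectivity,
    global efficiency and clustering coefficient as area-under-curve
    statistics tested with label permutation. Provides edge-wise t tests
    with Benjamini-Hochberg correction, the network-based statistic with a
    permutation null of maximal component size, a threshold-free cluster
    enhancement (TFCE) engine with max-statistic family-wise error
    correction for 3D maps, Jacobian-based regional volumetry with a
    coefficient-of-variation audit, fractional anisotropy change
    statistics, mixed-design ANOVA, and minimum-detectable-effect power
    calculations. A synthetic data module generates cohorts, modular
    correlated time series, regional volume and FA tables, and 3D stat
    images with known ground truth so every stage can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
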