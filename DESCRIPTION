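Package: dynfc
Title: Static and Dynamic Functional Network Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying time-varying functional network connectivity
    from independent-component time courses. Provides time-course conditioning
    (despiking, zero-phase Butterworth low-pass filtering, framewise
    displacement, motion quality control and nuisance regression), static
    Fisher-z connectivity matrices, tapered sliding-window connectivity with
    L1-penalised inverse-covariance (graphical lasso) estimation,
    connectivity-state discovery by k-means clustering under the Manhattan
    distance with elbow-based model-order selection, state temporal properties
    (fraction time, mean dwell time, transition number, state-entry
    percentage), covariate-adjusted group comparisons with false-discovery-rate
    control, rank-based discrimination (Mann-Whitney U, ROC/AUC), partial
    Spearman association, a compact group ICA front end (PCA reduction,
    Infomax, ICASSO stability, GICA3 back-reconstruction), and a synthetic
    multi-group cohort generator with planted connectivity states and group
    effects for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
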