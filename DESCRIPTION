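Package: mapalign
Title: Stochastic Simulation and Alignment Metrics for Retino- and
    Cortico-Collicular Topographic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the sequential formation of the retino-collicular and
    cortico-collicular topographic projections in the mouse superior
    colliculus as stochastic energy minimization under Eph receptor and
    ephrin-A ligand gradients, axon competition (a bijective assignment of
    axons to termination zones) and correlated spontaneous activity. The
    wild-type gradients and the Isl2-driven EphA3 and ephrin-A3 knock-in
    perturbations are built in; the retinal ephrin-A gradient carried into
    the colliculus by retinal axons provides the ligand field read by the
    cortical projection, so collicular map duplications propagate from the
    retinal to the cortical map. Includes the map-organization statistics
    used to quantify the resulting phenotypes: intrinsic dispersion index,
    local intrinsic dispersion variation along the rostral-caudal axis,
    retino/cortico alignment index, duplication threshold, Jaccard and
    covariance comparison of dispersion profiles, LOESS leave-one-out map
    profiling, branch collapse-point estimation and two-sample
    Kolmogorov-Smirnov map comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
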