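Package: calreg
Title: Calcium-Dependent Co-Regulation of Ion Channel Expression Under Cell Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of homeostatic ion-channel regulation in a
    single-compartment, eight-conductance bursting neuron model with thin-shell
    calcium dynamics. Implements the calcium-target master-regulation feedback
    that co-regulates all conductances, linear growth of membrane area, fixed-point
    analysis along the uniform-scaling (growth) ray over random model databases,
    adaptive Delaunay sampling of calcium level sets and basins of attraction in
    two-dimensional projections of conductance space, an analytical solver for
    homeostatically trapped silent states, and mean/variance-parameterised
    high-dimensional perturbation-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deldir,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
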