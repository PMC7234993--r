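Package: rmfm
Title: Relaxed Mean-Field Modelling of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-brain neural dynamics and BOLD functional
    connectivity from a structural connectome with a relaxed mean-field
    neural-mass model coupled to a Balloon-Windkessel hemodynamic model,
    inverts the model to estimate region-specific recurrent
    excitation-inhibition and subcortical input by maximising the similarity
    between simulated and empirical functional connectivity, and provides the
    accompanying group-level statistical battery (hemisphere pooling,
    z-scoring against controls, covariate-adjusted contrasts with
    max-statistic permutation family-wise error control, Mahalanobis and
    Hotelling T-squared multivariate tests, and network-normalised parameter
    contrasts). Includes generators for synthetic modular connectomes and
    cohorts with known ground truth so the full pipeline is testable without
    any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
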