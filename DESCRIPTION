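Package: covnet
Title: Structural Covariance Network Analysis of Regional Gray-Matter Volumes
Version: 0.1.0
Authors@R:
    person("Covnet", "Developers", email = "covnet@example.org", role = c("aut", "cre"))
Description: Group-level graph-theoretical analysis of structural covariance
    networks built from regional gray-matter volumes. Regresses nuisance
    covariates (age, total brain volume) out of per-region volumes, forms
    group association matrices of inter-regional Pearson correlations,
    binarizes them across a grid of network densities (including the minimum
    density at which every group's network is fully connected), computes
    small-world metrics normalized by degree-preserving random ensembles,
    identifies betweenness-centrality hubs, and tests between-group
    differences with a Fisher r-to-z strength comparison and label-permutation
    inference. Includes a synthetic two-group cohort generator with planted
    modular covariance and linear confounds so the whole pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
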