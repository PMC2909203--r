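Package: ConsensusFold
Title: Consensus Multi-Template Protein Model Refinement and Functional
    Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Refines an ensemble of candidate protein models by extracting
    consensus interatomic distances, scoring them with a residue-specific
    all-atom probability discriminatory function (RAPDF), rebuilding
    conformations by distance-restrained simulated annealing in torsion
    space under Ramachandran-like priors, filtering decoys with a
    sequential four-term filter, and selecting representatives by
    iterative density clustering. Also provides sequence- and
    surface-level functional-site analyses: amphipathic helix and
    hydrophobic-moment detection, basic-residue (lysine) cluster
    mapping, heptad-repeat register assignment, solvent-accessible
    surface areas, and desolvation-based surface patch ranking, applied
    here to the PDCD10 (CCM3) six-helix bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
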