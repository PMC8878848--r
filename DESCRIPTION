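Package: pacsmd
Title: Parallel Cascade Selection Sampling of Ligand-Binding Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive path-sampling of ligand binding by parallel cascade
    selection: short stochastic-dynamics segments are repeatedly reseeded from
    the snapshots closest to a binding target, ranked by a reaction coordinate
    such as the ligand-to-site center-of-mass distance. Includes a reduced
    Langevin engine (funnel binding site, multiple ligand copies, BAOAB
    integration) so the full protocol runs on one CPU, reaction-coordinate
    functions (COM distance, superposition RMSD, distance-matrix difference,
    radius of gyration, weighted composites), and Markov-state-model
    post-analysis: k-means microstates, implied-timescale lag selection,
    reversible transition-matrix estimation under detailed balance, and
    free-energy profiles from the stationary distribution.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
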