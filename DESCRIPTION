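Package: cleftscope
Title: Interaction Fingerprints, NOE Comparison and Well-Tempered
    Metadynamics for Protein-Ligand Trajectories
Version: 0.1.0
Authors@R:
    person("cleftscope", "developers", email = "cleftscope@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics studies of small
    ligands (such as the green-tea catechin EGCg) binding protein clefts
    (such as the C-terminal domain of cardiac troponin C). Detects
    hydrogen bonds, salt bridges and pi-pi stacking with geometric
    criteria; computes NOE-style r^-6 effective proton-proton distances
    over equivalence groups and compares them with experimental distance
    classes; measures backbone RMSD, terminal-strand RMSF, calcium-ion
    mobility distributions and ligand dihedral populations; runs
    well-tempered metadynamics on toy potentials with free-energy
    reconstruction, profile averaging and Boltzmann projection; and
    performs MM/PBSA-style free-energy bookkeeping with quadrature
    uncertainty propagation. A synthetic-data module generates every
    input (toy complexes, trajectories with planted interactions, ion
    mobility models, analytic free-energy surfaces, energy-component
    tables) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
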