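Package: pocketEDA
Title: Hydrogen-Bond Statistics and Hartree-Fock Interaction Energy
    Decomposition for Protein-Ligand Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the physical nature of intermolecular
    interactions in a protein-ligand binding pocket. Generates synthetic
    trajectories with prescribed hydrogen-bond length distributions, computes
    binned frequency-of-occurrence tables, occupancies, ring-centroid distance
    and RMSD series, selects a representative frame by modal-interval and
    minimal-total-length criteria, extracts capped residue-ligand dimers, and
    decomposes their restricted Hartree-Fock interaction energy into
    first-order electrostatic, Heitler-London exchange and delocalization
    components in the dimer-centered basis set (BSSE-free). Includes Spearman
    rank-correlation and covalency-ratio post-processing of component tables.
    The Gaussian-integral engine (McMurchie-Davidson) and SCF solver are
    implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
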