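Package: pbcoords
Title: Structural Coordinates for Protein Backbone Fragments via Protein Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents five-residue protein backbone fragments by their 16
    Kabsch-superposition RMSD distances to the Protein Blocks structural
    alphabet ("structural coordinates"). Provides an internal-coordinate
    (NeRF) backbone builder under standard covalent geometry, dihedral
    extraction, RMSD and RMSDA metrics, nearest-block assignment under
    either metric, reconstruction of backbone dihedrals from the 16
    distances by quasi-Newton or conjugate-gradient loss minimization,
    degrees-of-freedom accounting for minimal alphabet sizes, Structural
    Word catalogs for nine-residue stretches, and a homology-free
    sequence-to-structure Q16 predictor built from reduced-alphabet RMSD
    statistics and physicochemical features via bidirectional stepwise
    linear regression. Includes a synthetic-corpus generator for end-to-end
    validation and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
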