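Package: enmunfold
Title: Elastic-Network Bond-Breaking Simulations of Protein Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulation of thermal and force-induced protein
    unfolding with Gaussian Network Models (GNM). Residues are beads connected
    by springs through a Kirchhoff connectivity matrix; bonds are broken one at
    a time, either at the pair with the largest thermal distance fluctuation or
    at the pair stretched most under a terminal pulling force. Alongside the
    trajectory the package tracks the fraction of native contacts Q, the mean
    coordination number, and the number of floppy modes of the Anisotropic
    Network Model (ANM) Hessian; computes per-residue shear energy fields from
    soft-mode displacements via a discrete deformation gradient and Eulerian
    strain; encodes bond-breaking sequences region-wise for comparing unfolding
    pathways across a protein family; and scores structural similarity with a
    TM-score on a supplied residue correspondence. Includes generators for
    synthetic bead-spring structures with analytically known rigidity so the
    whole pipeline is testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
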