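Package: cgpmf
Title: Coarse-Grained Many-Body Potentials of Mean Force by Linear Force Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up coarse-graining of spherical colloidal particles.
    Learns effective many-body potentials of mean force by linearly
    regressing vectorial mean forces, sampled in fine-grained reference
    simulations, onto analytic gradients of Behler-Parrinello symmetry
    functions. The scalar many-body potential follows in closed form from
    the fitted weights and can be exercised directly in Metropolis Monte
    Carlo simulations (equations of state, pair correlation functions,
    rigid-geometry potential scans). Ships two fine-grained reference
    simulators: a ligand-capped nanoparticle bead model with a
    solvent-quality-modified Lennard-Jones interaction sampled by Langevin
    dynamics, and an ideal-polymer (Asakura-Oosawa) colloid-polymer model
    with an exact depletion-force oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
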