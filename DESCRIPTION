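Package: coronaforge
Title: Multiscale Prediction of the Nanoparticle Biomolecular Corona
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes orientation-resolved adsorption free energies of rigid
    coarse-grained biomolecules on single- and multicomponent nanoparticles from
    tabulated bead-surface potentials of mean force, Hamaker-like dispersion
    terms and screened Debye-Hueckel electrostatics, and predicts the
    time-resolved and steady-state biomolecular corona by kinetic Monte Carlo
    simulation of competitive hard-disk adsorption. Includes Lifshitz and
    force-field routes to Hamaker constants, bead-radius estimators, material
    library input/output, synthetic fixture generators and an end-to-end
    pipeline driver with corona summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
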