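Package: cionmc
Title: Monte Carlo Dose Engine for Carbon-Ion Beams with a Data-Driven
    Fragmentation Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale Monte Carlo transport engine for therapeutic
    carbon-ion beams in voxelized phantoms.  Continuous processes
    (Bethe ionization energy loss, Bohr energy-loss straggling and
    Highland multiple Coulomb scattering with an empirical per-species
    scaling factor) are combined with a phenomenological nuclear model:
    a fitted carbon-carbon non-elastic cross-section with Kox-ratio
    scaling to other targets, isotropic centre-of-mass elastic
    scattering on hydrogen, and a data-driven fragmentation event
    generator built from packaged production-probability and
    energy-angle emission tables with energy/angle rescaling to
    arbitrary beam energies.  Includes absorbed-dose scoring, Bragg
    curve and lateral profile analysis, spread-out Bragg peak weight
    optimisation and gamma-index dose comparison for quality assurance.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    graphics,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
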