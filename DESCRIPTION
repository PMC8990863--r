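Package: protonfid
Title: Proton Fluence and Dose Perturbations from Fiducial Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the perturbation of therapeutic proton beams by
    implanted fiducial markers. Provides a condensed-history Monte Carlo
    proton transport engine (Bethe stopping power, Bohr energy-loss
    straggling, Highland multiple Coulomb scattering), a layered beamline
    and marker-catalog geometry model, a virtual CMOS pixel-tracker chain
    (digitization, cluster finding, software alignment, straight-line track
    reconstruction), track back-projection into 3D fluence grids with a
    maximum-perturbation statistic, spread-out Bragg peak construction with
    cold-spot quantification in water, and CT streak-artifact / radiograph
    contrast metrics on synthetic phantom images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
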