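# protonfid

Fiducial markers are implanted near tumours so that daily X-ray or CT
imaging can verify the target position before each radiotherapy fraction.
In proton therapy the same marker is a liability: a dense, high-Z object in
the beam scatters protons off axis and can stop the slowest ones, carving a
localized fluence and dose deficit ("cold spot") immediately downstream.
Marker selection is therefore a trade-off between imaging visibility
(better for heavy, dense markers) and dose perturbation (worse for them).

`protonfid` is an R package for quantifying both sides of that trade-off
with simulation:

* **Proton transport** - a condensed-history Monte Carlo engine (compiled
  core) with Bethe stopping power, Bohr energy-loss straggling, and
  Highland multiple Coulomb scattering with Fermi-Eyges-correlated lateral
  displacements. Water-phantom CSDA ranges reproduce published clinical
  beam values (142.10 MeV -> 143.6 mm, 169.02 MeV -> 194.3 mm) to ~0.15%.
* **A marker catalog** - clinical gold/platinum coil markers (modelled as
  mass-consistent tubes), a linear gold anchor wire, and a carbon-coated
  ZrO2 marker (mass-consistent cylinders).
* **A virtual pixel tracker** - binary-output 928 x 960 CMOS sensors at
  20.7 um pitch: charge-cloud digitization, 8-connected cluster finding,
  software alignment, straight-line triplet tracking (sub-10 um residuals).
* **Fluence-perturbation analysis** - tracks back-projected into a
  20 x 20 x 200 um voxel grid at the marker; 2D fluence maps; a
  maximum-perturbation statistic (percent deficit vs a matched reference or
  a dip-masked triple-Gaussian baseline fit) with its depth.
* **SOBP dose analysis** - spread-out Bragg peak construction from 12
  weighted pristine peaks (142-169 MeV, flat to ~1.4% over 140-190 mm),
  2D dose maps with an implanted marker, and the central-line cold-spot
  statistic.
* **Imaging metrics** - synthetic CT slices with streak artifacts,
  square-ring min/max profiles with a 3%-of-background artifact extent,
  and windowed radiograph contrast `C = |I_max - I_b| +/- sigma sqrt(2/N)`.

## Tests

```r
testthat::test_dir("tests/testthat", package = "protonfid",
                   load_package = "installed")
```

## Worked example

Transport a 169.02 MeV beam (3.5 mm FWHM, 7.5 mrad divergence at the
vacuum window) through the experimental beamline - effective nozzle,
90 mm polyethylene block, 40 mm water aquarium, PMMA mounting plate - with
a 0.5 mm gold coil marker glued behind the plate, then run the full
measurement chain and compare with a matched marker-free reference:

```r
library(protonfid)

geo <- build_experiment_geometry("experiment")
mk  <- marker_from_catalog(2)          # gold tube, 5 mm x 0.5 mm, 10.8 mg
st  <- sample_beam(standard_beam("169"), 2e5, seed = 42)

run <- function(null) {
  tr <- transport(st, geo, marker = mk, seed = 42, null_marker = null)
  dg <- digitize(tr$hits[tr$hits$sensor %in% 5:7, ], seed = 7)
  cl <- find_clusters(dg$pixels)
  tk <- reconstruct_tracks(cl, geo, z_ref = tr$marker_center)
  integrate_map(backproject(tk, fluence_grid_spec(y_half = 2)))
}
max_perturbation(run(FALSE), run(TRUE), rebin = 5)
#> max perturbation 12.4% +/- 6.3 at z = 8.1 +/- 1.5 mm (x = 0.05 mm)
```

Read: behind this marker the proton fluence drops by ~13% about 8 mm
downstream - consistent with the published measurement for this marker and
energy (14.5 +/- 1.3 % at 8 +/- 1.5 mm). The quoted +/- is the per-bin
counting uncertainty; the shared-seed reference makes the estimate itself
much more stable than that bound suggests.

The SOBP side, for the same marker implanted at 15 cm depth at the start
of a 14-19 cm plateau:

```r
plan <- standard_sobp_plan(seed = 1)              # 12 peaks, NNLS weights
maps <- sobp_dose_maps(plan, mk, n = 2e6, seed = 11)
cold_spot(maps)
#> max cold spot 6.9% +/- 2.1 at 6.8 mm behind the marker
```

The published reference value for this marker is 7.5 +/- 1.4 %.

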