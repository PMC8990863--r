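---
title: "Models and methods: proton fluence and dose perturbations from fiducial markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Implanted fiducial markers let daily imaging verify a tumour's position, but
a dense metal object sitting in a proton field scatters and stops protons
and carves a small fluence (and hence dose) deficit behind itself. This
package quantifies that trade-off end to end: a condensed-history Monte
Carlo engine transports protons through a layered beamline or a water
phantom containing a marker; a virtual CMOS pixel-tracker chain measures the
fluence field the way a sensor telescope would; and dedicated statistics
summarise the perturbation as a single maximum-deficit value with its depth.
This vignette records the models, the defaults, and the reasoning behind
every choice that was genuinely open.

## Single-proton physics

Stopping power uses the Bethe formula without shell or Barkas corrections,
with standard mean excitation energies (75 eV for water). At 100-170 MeV
these corrections change ranges by far less than the 1% tolerance the
package targets; `csda_range()` integrates the reciprocal stopping power on
a log-spaced grid from a 0.5 MeV cutoff (the sub-cutoff residual is below
0.01 mm) and reproduces published clinical beam ranges in water (143.6 mm
at 142.10 MeV, 194.3 mm at 169.02 MeV) to about 0.15%.

Energy-loss straggling is Gaussian with the Bohr variance (relativistic
correction included); range straggling then emerges from the per-step
energy straggling, with no separate term. A consequence worth knowing: the
argmax of a simulated Bragg curve sits ~1.4 mm upstream of the CSDA range,
which is real straggling physics, not a bug.

Multiple Coulomb scattering is the Gaussian Highland core,

theta0 = 13.6 MeV / (beta c p) * sqrt(x/X0) * (1 + 0.038 ln(x/X0)),

applied per step in two orthogonal planes with the Fermi-Eyges-correlated
lateral displacement (correlation sqrt(3)/2). Single-scattering (Moliere)
tails are not modelled.

### The log-factor subtlety

Highland's logarithmic factor is a *whole-slab* correction, so a per-step
implementation must decide which cumulative thickness feeds it. The engine
accumulates radiological depth along the whole path (the Highland-integral
treatment for composite targets): this reproduces a closed-form Fermi-Eyges
evaluation of beam-width growth within 5% and the expected ~10 mm FWHM at
the isocenter for a 3.5 mm / 7.5 mrad beam at the exit window, and it
locates the maximum of the back-projected fluence deficit at the expected
depth behind the marker. The alternative - giving the thin high-Z marker
crossing its own slab-local factor (~0.89 for a 0.05-radiation-length gold
chord vs ~0.97 cumulative, an 18% difference in added variance) - was
implemented and compared during development; it lowers every perturbation
statistic by 15-25% relative and shifts the deficit maximum several mm
downstream. The cumulative treatment is the standard reference prescription
for inserts inside a thick stack and ships as the only behaviour; its known
consequence is a mild *overestimate* of dose cold spots, because the
compensating diffuse secondary-particle halo (which dilutes relative dose
deficits in full-physics Monte Carlo codes) is deliberately out of scope
here.

## Transport mechanics

Paraxial slope coordinates (x, y, tx, ty) with z along the beam; layers are
z-slabs, and the marker is a tube or cylinder with its axis vertical (y).
Steps are at most 1 mm in solids, cut exactly at layer boundaries and sensor
planes, 0.02 mm inside a 2 mm neighbourhood of the marker (sub-diameter
resolution for 0.28-1 mm markers), and shrunk wherever the mean energy loss
would exceed 15% of the current energy. Energy loss uses a midpoint
re-evaluation of the stopping power (second order in the step). Protons are
killed below 0.5 MeV with local deposition of the residual. Dose deposits
are split exactly over the depth bins a step spans.

Randomness is *counter-based*: every draw is a hash of (seed, primary id,
step index, draw index). Two runs with the same seed - one with the marker,
one with the marker's volume filled by the host medium - therefore follow
bit-identical histories for every proton that never meets the marker
material, and those protons cancel exactly in any with/without comparison.
This is the package's main variance-reduction device; it changes no
expectation value, only the noise of the *difference*.

## The virtual tracker

The sensor model is a binary-output monolithic pixel sensor: 928 x 960
pixels at 20.7 um pitch, ~2 x 2 cm active area, 50 um silicon in the beam.
Digitization integrates a Gaussian charge cloud (sigma 10 um default) over
pixel areas and fires pixels whose charge fraction crosses a threshold
(0.1), plus uniform noise pixels (1e-6 per pixel per frame). Clusters are
8-connected components; their centre of mass gives sub-pixel resolution.
Primaries are batched ~20 per readout frame so the combinatorics of triplet
matching stay trivial; matching uses a 200 um middle-plane gate, a
least-squares straight line, and greedy chi2-ordered assignment with each
cluster used once. Alignment works from a no-target run: the first and last
sensors define the gauge axis, middle sensors are corrected by their mean
residual (and optionally a residual-vs-position rotation) until updates fall
below 0.1 um; injected 50 um offsets are recovered to ~1 um.

The PCB frame that surrounds each sensor is *not* placed in the beam by
default (`include_pcb` switches it on): a 1.7 mm FR-4 board in front of all
seven sensors would add ~20 mm water-equivalent thickness, and a 142 MeV
beam (range 143.6 mm in water) could then never reach the last sensor -
inconsistent with the residual energies the geometry is required to
reproduce (~80 MeV behind the aquarium at 169 MeV, ~10 MeV at 142 MeV,
which the default stack matches).

## Fluence maps and the maximum-perturbation statistic

Tracks reconstructed on the downstream telescope are extrapolated as
infinite straight lines into a voxel grid at the marker (20 x 20 x 200 um
voxels; exact Amanatides-Woo traversal, each crossed voxel counted once).
Maps integrate the grid over a y window, by default the central 80% of the
marker length - the ends of the marker see a diluted perturbation, and the
published window choice ("according to the marker length") leaves the exact
fraction open.

The perturbation at (x, z) is 100 (ref - with)/ref over bins where the
reference exceeds 20% of its slice maximum (a tail guard; configurable).
Only deficits are reported: a local underdosage risks tumour recurrence,
an equally small overdosage is clinically less critical. Profiles are
rebinned transversally (factor 5 by default at desk-scale statistics,
i.e. 0.1 mm bins) so reference bins hold >= 100 counts.

Two estimator details matter at finite statistics, and both are documented
here because they were chosen on estimator-theory grounds:

* the per-bin maximum of a noisy ratio field is an upward-biased order
  statistic, so the reported maximum (and its depth) is the argmax of a
  short moving average over 7 z-slices (1.4 mm, matching the method's
  1.5 mm z uncertainty);
* behind a marker in air the deficit deepens with z and then largely
  *saturates* (straight lines do not re-mix; only the growing track
  extrapolation error reverses the trend), so the depth of the maximum is
  intrinsically weakly identified at moderate statistics - expect a few mm
  of seed-to-seed scatter at 2e5 primaries.

When a trustworthy reference run is unavailable (e.g. beam drift between
runs), `fit_reference()` builds the baseline from the perturbed profile
itself: a *sum* of three Gaussians, fitted by Poisson-weighted least squares
with the dip region masked (automatically, via a robust single-Gaussian
pre-fit, or by hand). A convolution of three Gaussians would collapse to a
single Gaussian and could not describe the tilted, skewed profiles a
shifted beam produces; the three-component sum is the minimal shape with
enough freedom, and it is exactly nested above the single-Gaussian case.

## Marker catalog

Tube markers (the coiled gold/platinum designs) take their inner diameter
from the quoted mass - the coil's fine structure is not resolved, but its
mass, and therefore its total stopping and scattering material, is exact.
Cylinder markers (the notched linear gold wire and the carbon-coated ZrO2
"bone") similarly carry a mass-consistent *effective density* (13.3 and
2.33 g/cm3): their envelope dimensions with bulk density would overstate
the mass by 45% and 145% respectively. Geometry is always the Table-style
envelope (length, outer diameter); folded markers have no well-defined
transport geometry and are excluded. The thin gelatin film around a mounted
marker has no published thickness and defaults to absent.

## SOBP construction and cold spots

Twelve pristine peaks, equally spaced in range between 142 and 169 MeV, are
simulated at 1e5 primaries each (laterally integrated depth-dose curves);
plateau weights come from non-negative least squares against a uniform
target on 140-190 mm. Flatness is evaluated on 2 mm depth averages - the
plateau criterion is macroscopic and should not hinge on single-bin MC
noise - and reaches ~1.4%, holding within 1 percentage point on an
independently seeded re-simulation (the weights are not overfit to library
noise).

Dose maps score 0.02 mm (x) by 0.4 mm (z) cells integrated over the marker
length in y, with the marker centre at 150 mm depth in water. The
"central line" on which the cold spot is evaluated defaults to the interior
of the marker's geometric shadow, `|x| <= min(od/2, 0.25 mm)`: a much
narrower line is dominated by the few end-of-range Bragg peaks that happen
to stop inside it, and its maximum swings coherently by several percentage
points between seeds at 1e6-scale primary counts. Primaries are
sampled uniformly over the central 30 x 30 mm of the nominal 5 x 5 cm
field: with ~4 mm of lateral scattering sigma at depth, protons starting
beyond 15 mm off-axis cannot influence the central-line scorer, so the
restriction is pure variance reduction. The cold spot is the percent deficit
of the central line (|x| <= 0.1 mm) of the with-marker map relative to the
matched reference, maximised between the marker's downstream face and the
end of the plateau on a 2 mm (5-bin) moving average - the physical cold
spot extends over 10-20 mm, and at 2e6-primary scale the raw 0.4 mm-bin
maximum reads 2-3 percentage points high on pure order-statistic bias
(verified by comparing against 6e6-primary runs).

## Imaging metrics

The synthetic CT slice is an *appearance* model, not a reconstruction
model: a uniform gelatin background (~30 HU), saturated marker pixels, an
alternating-sign radial streak field A exp(-r/lambda) cos(k theta), and
Gaussian noise, clipped to [-1024, 3060]. Square rings (Chebyshev annuli
one pixel thick, ring 0 being the ~2 mm square at the HU maximum) give
min/max-vs-distance curves; the artifact extent is the smallest ring
distance beyond which all outer rings stay within a threshold of the
background. The "3% of background" criterion needs a reference scale - 3%
of a ~30 HU background would drown in noise - so the threshold is anchored
at the water-air span: 0.03 (background + 1000) HU, explicit and
overridable. Radiograph contrast follows the windowed-profile definition
C = |I_max - I_b| +/- sigma sqrt(2/N) with 3 x 6 mm windows, the profile
integrated perpendicular to a vertically placed marker.

Real scanner streaks, vendor artifact-reduction behaviour and radiograph
physics are out of scope; the metrics are exercised against constructed
images and the generator's known decay law.

## Problem sizes and reproducibility

Default study sizes: 2e5 primaries for beamline/tracker runs, 2e6-4e6 per
SOBP cold-spot pair (shared-seed with/reference), 1e5 per pristine peak.
These sizes resolve every statistic above its counting noise on a single
CPU in minutes. All stages take explicit seeds (no wall-clock defaults);
end-to-end reruns with the same configuration are bit-identical, which the
test suite asserts via artifact checksums.

## Known limitations

* No nuclear interactions or secondary particles: reference Monte Carlo
  codes include a diffuse secondary-dose halo that slightly dilutes
  relative dose deficits; our cold spots carry no such dilution.
* Gaussian scattering core only; Moliere tails would mildly broaden and
  shallow the fluence dips.
* Paraxial transport; accuracy degrades in the final sub-millimetre of
  range where slopes grow, with negligible effect on the statistics
  reported here.
* The pixel-sensor model is geometric (charge cloud + threshold); no
  delta-rays, charge sharing nonlinearity, or readout pile-up.
* Synthetic images emulate the look of streak artifacts, not CT physics;
  measured scanner values are outside what desk-scale synthesis can
  reproduce.
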