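---
title: "Models and methods behind centriolr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind centriolr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centriolr)
```

`centriolr` packages the quantification machinery used in fluorescence
studies of the centriole's distal appendages and the first steps of
ciliogenesis: per-centrosome intensity measurement, ninefold-ring diameter
measurement, two-colour 3D single-molecule localization (SMLM)
post-processing, categorical assay scoring, and a small statistical layer
built around nested (replicate-aware) comparisons. Every pipeline can be
exercised on synthetic data with exact ground truth, which is how the
package tests itself. This vignette explains the models, the defaults, and
the design decisions — including the places where a published procedure is
under-specified and the package had to commit to an explicit rule.

## Synthetic data: what is emulated, and what is not

All generators produce outputs with a *truth* record sufficient to score
any downstream estimator without re-reading the configuration.

**Centrosome fields** (`sim_centrosome_field()`). Centrosomes are rendered
as isotropic 2D Gaussian spots (FWHM = 2.355 sigma) on a constant
background with additive Gaussian read noise. Spot amplitudes are
*integrated* intensities, so pixel sums are directly comparable with the
injected truth (mass conservation). A configurable fraction of each spot's
mass can be redistributed into a wider "pericentriolar haze" (default 25%
into a 4x wider Gaussian). Defaults emulate a wide-field 63x/1.4 NA
acquisition: 100 nm pixels, 250 nm PSF FWHM, 256^2 frames. Centrosomes are
placed with a minimum separation of 25 px (~2.5 um), reflecting that each
belongs to a different cell; without this the mask-merging step of the
measurement pipeline occasionally fuses unrelated centrosomes, which is a
feature of the measurement being tested, not of the simulation. The
generator does **not** model camera EM gain, photon shot noise, or a
physically rigorous PSF; passing tests therefore demonstrate correctness
of the measurement logic, not robustness to every camera artefact.

**Appendage rings** (`sim_ring_image()`). `n_blades` (default 9) point
puncta are spaced equally on a circle of the requested peak-to-peak
diameter (default 513.4 nm, mirroring the outer CEP83 ring), blurred with
a Gaussian PSF (default 120 nm FWHM at 40 nm pixels — SIM scale). Tilted
rings are simulated by foreshortening blade coordinates along one axis by
cos(tilt) before projection, matching how a tilted ring appears in a top
view.

**SMLM scenes** (`sim_smlm_scene()`). A scene contains, per channel: a
shared reference ring (FOP-like; radius 150 nm, 10 nm radial and 25 nm
axial scatter — values chosen as plausible for a proximal centriole marker,
since no published density or radius was available for this structure),
anisotropic Gaussian clouds for the vesicle (red, RAB34-like) and its
partner (green, MYO5A-like; true COM offset default 89 nm along the unit
diagonal), and fiducial beads localized in every frame. Stage drift is a
cubic polynomial per axis (smooth and spline-recoverable, as slow
mechanical drift is), applied to every emitter; the green channel is then
transformed by a planar affine (rotation, scale, translation, plus a z
shift) and a residual 3D shift — the quantity cross-correlation refinement
must recover. Localization noise jitters each true position by
N(0, CRLB) laterally and N(0, 2 CRLB) axially, with CRLB drawn per
localization (mean 10 nm); the doubled axial factor reflects the ~2x worse
axial precision of astigmatic/engineered-PSF 3D localization. A
configurable fraction of uniform spurious localizations is added.

**Nested datasets** (`sim_nested_dataset()`). The hierarchical model is
`value = grand_mean + condition_effect + N(0, replicate_sd) + N(0,
cell_sd)`, with the replicate intercept shared by all cells of a
replicate. Defaults (3 replicates, 30 cells/replicate, replicate SD 5,
cell SD 15 on a grand mean of 100) give the intra-class correlation
regime where naive per-cell tests would badly inflate false positives.

## Intensity quantification

The pipeline composes: rolling-ball background subtraction, thresholding
of the reference and POI channels, mask combination, particle analysis,
and ROUT outlier flagging.

* **Rolling ball** is implemented exactly as the grayscale opening with a
  non-flat ball structuring element (radius 5 px default), i.e. a
  top-hat. Constants are removed exactly; structures narrower than the
  ball survive at full height. Because the ball has a fixed height in
  counts, the subtraction is homogeneous under intensity scaling only to
  ~1%; the tests account for this.
* **Thresholding** replaces a manual per-image choice with recorded
  strategies. The default (`mean_sd`) uses mean + 5 SD of the
  *background*, sampled as the dimmest 95% of pixels so bright objects
  cannot inflate the threshold; a noise-free background (SD 0) falls back
  to a token positive threshold. `absolute` and `percentile` strategies
  are available; the strategy and parameter are recorded in the output's
  provenance attribute.
* **Mask combination**: the two masks are united (the max projection of a
  two-mask stack), dilated with a 3x3 box while each dilation still
  reduces the connected-component count (i.e. until the reference and POI
  footprints of the same centrosome merge; cap 10 iterations), labeled at
  the merged stage, then eroded the same number of iterations. Labeling
  before erosion keeps merged pairs paired even if erosion re-splits the
  footprint.
* **Particle analysis** gates on area and circularity
  `4 pi A / P^2` with EBImage's boundary-pixel perimeter estimator,
  clamped at 1, and discards border-touching components. This estimator
  rates a digital disk of radius 10 px at ~0.99 and short thick rods at up
  to ~0.75, which is why the ciliary variant's default circularity gate is
  `[0, 0.8]` while the centrosomal gate is `[0.5, 1]`. The gates were
  calibrated once on the synthetic defaults and recorded here; they are
  configuration, not constants.
* **ROUT flags are never deletions.** The `outlier` column marks rows;
  exclusion is an explicit downstream step.

## Ring diameters and the molecular ruler

`peak_to_peak_diameter()` extracts intensity profiles along four full
lines through the ring centre at 0/45/90/135 degrees (equally spaced
angles minimize orientation bias; the number four follows the measurement
convention it reimplements), finds on each side of the centre the
strongest local maximum above 10% of the profile's peak, refines it with a
3-point parabola (sub-pixel precision is needed to resolve ~20 nm
differences at 40 nm pixels), and averages the four per-angle diameters.
The centre defaults to the intensity centroid after subtracting the median
(50th percentile). Averaging over angles reduces — but does not model out —
tilt; no deprojection is attempted, matching the source procedure.

Two systematic effects are worth knowing. PSF convolution pulls the radial
peak of a curved ring inward by roughly sigma^2 / (2R), and discrete
blades place the profile peak slightly inside the circle whenever a
profile ray passes between blades. At the outer-ring scale (513.4 nm, 120
nm FWHM) the combined bias is ~19 nm — inside the half-pixel (20 nm)
acceptance band, and the reason the recovery tests quote half-pixel rather
than arbitrary precision.

`molecular_ruler()` is the linear extension model used to reconcile two
antibodies against the same protein labelling different ring diameters:
helical residues contribute 0.15 nm each (3.6 residues per turn),
disordered residues up to their 0.4 nm contour length, and each IgG ~8 nm.
400 helical + 40 disordered residues give exactly 76 nm; four IgG give
32 nm.

## SMLM post-processing

* **Drift.** Fiducial positions are averaged per frame and smoothed per
  axis with a cubic smoothing spline in the `csaps` convention
  (`p * RSS + (1 - p) * curvature`; p = 1e-6 on the frame-index abscissa,
  i.e. very close to a least-squares line over 1000 frames). The spline is
  solved exactly in the Reinsch penalty-matrix form; the tests verify it
  against `stats::smooth.spline` through the lambda mapping
  `lambda = (1 - p) / p / range(x)^3` (smooth.spline rescales x to
  [0, 1]). The trace is zero-referenced to frame 1. Beads must be present
  in >= 80% of frames with no gap longer than 50 frames (the gap rule is
  this package's explicit choice; blinking-fiducial handling was not
  specified upstream).
* **Quality filter.** Localizations with lateral CRLB above 20 nm are
  removed. The published wording reads "below 20 nm", which would discard
  the most precise localizations; it is treated here as a wording slip and
  the filter keeps the precise ones. The neighbour filter removes
  localizations whose mean distance to their 8 nearest neighbours exceeds
  200 nm (a default chosen to sit far above intra-cluster spacings and far
  below the typical isolation of spurious localizations).
* **Registration** composes a bead-estimated planar affine (closed-form
  least squares; >= 3 non-collinear beads) with iterative 3D
  cross-correlation fine-tuning: both channels are histogrammed at 10 nm
  voxels, cross-correlated by FFT, the peak is refined per axis with a
  3-point parabola, and the moving channel is shifted until the
  incremental shift is below 2 nm on every axis. No z-dependent affine is
  modelled.
* **Clusters.** Manual structure isolation is replaced by an explicit,
  recorded axis-aligned box ROI. Per-axis histograms (10 nm bins) are fit
  with a single Gaussian; 1/e^2 full width = 4 sigma (a Gaussian falls to
  e^-2 at 2 sigma); fit failures fall back to sample moments with a flag.
  The vesicle-candidate rule is inclusive: all three widths >= 120 nm
  pass. COM offsets fit one Gaussian per species per axis ("two Gaussians"
  per histogram pair is read as one per species, not a two-component
  mixture) and report the per-axis differences and their Euclidean norm.

## Statistics

* `welch_t()` and `fisher_exact_2x2()` are the standard tests;
  the Fisher two-sided p uses the probability-mass convention (sum of all
  tables with probability <= observed, fixed margins), which is also what
  `stats::fisher.test` computes; the doubling convention would give
  different values on asymmetric tables.
* `nested_t()` and `nested_anova_dunnett()` operate on replicate means:
  for the balanced 2-5-replicate designs these tools target, testing
  replicate means is equivalent to the one-level random-effects model and
  avoids pseudo-replication without requiring a mixed-model fitter.
  Dunnett's familywise adjustment is computed by Monte-Carlo sampling of
  the max-|t| null under the pooled-variance model (default 1e5 draws,
  seeded; adjusted p standard error < 0.002), because tabulated critical
  values cover few df combinations; adjusted p-values are floored at the
  unadjusted ones.
* `rout_outliers()` specializes ROUT to a constant model: centre =
  median, scale = RSDR (68.27th percentile of |residuals|, small-sample
  corrected by n/(n-1)), candidates tested from the most extreme inward
  with t statistics against the FDR-style sequence
  `alpha_i = q (n - i + 1) / n`, stopping at the first failure. On clean
  normal data this flags on the order of q of the points, within the
  <= 2q calibration the tests enforce.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a single CPU: SMLM scenes
use 10-12k ring localizations per channel (enough for sub-nanometre
cross-correlation peaks), clouds of 500-2,000 localizations (the regime
where 10% width recovery is expected), 10^4 null simulations for the
nested-t error rate, 200 x n=1000 draws for the ROUT calibration, and
full enumeration of all 2x2 tables with N <= 30 for Fisher equality.

## Known limitations

* The intensity pipeline performs no cell segmentation; per-cell
  assignment of centrosomes is out of scope.
* Ring measurement assumes top views; side-view axial offsets are not
  measured.
* The registration model is planar-affine plus a global 3D translation;
  field-dependent or z-dependent distortions are not corrected.
* The ROUT adaptation is the constant-model specialization; it is not the
  original nonlinear-regression procedure.
* Colocalization scoring uses a fixed 500 nm radius as an explicit stand-in
  for by-eye judgement; centrosome association of cilia likewise uses an
  explicit distance rule.
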