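---
title: "Quantifying measurement error in tractography-guided DBS distance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying measurement error in tractography-guided DBS distance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractgap)
```

## The measurement problem

When probabilistic tractography is used to guide deep brain stimulation
(DBS) targeting, the clinically relevant quantity is a distance in
millimeters: how far is each electrode contact from a fiber bundle such as
the crossing (c-DRTT) or non-decussating (nd-DRTT) part of the
dentato-rubro-thalamic tract? That number is not a direct measurement. It
is the end product of a processing chain — streamline counting,
binarization of the count map, distance computation, and often
normalization into a standard space — and several links in that chain
inject error of the same order as the clinical margins (a few millimeters).

`tractgap` isolates three of those links and turns each into a measurable,
reproducible error statistic:

1. **Binarization threshold.** A streamline-count map must be cut at some
   intensity to become a binary tract. The package expresses thresholds as
   a percentage `p` of the *robust range* of the image histogram and
   quantifies, per contact and tract, how much the measured distance moves
   as `p` sweeps a candidate set.
2. **Measurement technique.** Distances can be read automatically from a
   3D Euclidean distance map, or manually on the single axial slice
   containing the contact. The package emulates the manual reading and
   reports the difference against the automated one.
3. **Normalization.** Coordinates are often mapped into a standard space
   before distances are measured. The package measures the same
   landmark-based distance (electrode tip to a red-nucleus-like landmark)
   in native and normalized space and reports the discrepancy.

None of this requires patient data: a synthetic phantom generator produces
cohorts with the statistical structure the analysis assumes, so every
stage is testable end to end.

## The procedures, precisely

### Robust-range thresholding

For a volume `V`, the robust range is `(rmin, rmax)` = the 2nd and 98th
percentile of all voxel values, computed with linear interpolation between
order statistics (the conventional sample-quantile definition). The
binarization threshold at percentage `p` is

```
t(p) = rmin + (p / 100) * (rmax - rmin)
```

and the mask keeps voxels with value `>= t(p)` (the `>=` is fixed for
determinism). In streamline-count maps the overwhelming majority of voxels
are zero and a few carry counts in the thousands, so the robust range sits
far below the global maximum — which is why percentages of 400–1000 are
meaningful rather than vacuous, and why the mask at a higher `p` is always
a subset of the mask at a lower `p` (the threshold is affine-increasing in
`p`).

Two policy decisions are exposed rather than hidden:

* Zeros are included in the percentile computation by default, following
  the plain definition of an image histogram. Because binarization tools
  differ on this point, `robust_range_nonzero_only = TRUE` restricts the
  histogram to positive voxels instead.
* The per-patient threshold is selected *for the whole brain*, never per
  hemisphere. The selection rule is an explicit stand-in for visual
  inspection: among candidates at which all four masks (c/nd × left/right)
  are non-empty, pick the one minimizing the mean of the two
  per-hemisphere Dice overlaps between the c- and nd-masks; ties go to the
  lowest candidate. Visual selection cannot be reproduced in code; a
  minimized-overlap criterion is a defensible, testable proxy and is
  labeled as such.

### Distance maps and the step-down rule

`compute_distance_map()` computes the exact Euclidean distance transform
of a mask in world millimeters, honoring anisotropic voxel spacing (the
separable lower-envelope algorithm applied per axis on squared distances,
implemented in C++). Each voxel stores the distance from its center to the
nearest mask-voxel center; distances are to voxel *centers*, not surfaces,
consistently across the automated, manual, and oracle paths so their
comparisons are internally coherent.

The automated measurement samples the map at the contact coordinate with
nearest-neighbor lookup (the value stored at the voxel containing the
contact), matching how per-coordinate values are exported from precomputed
maps; the sampled value can differ from the true point-to-mask distance by
at most half a voxel diagonal, and a trilinear option exists for
sensitivity analyses. If the automated distance exceeds 10 mm (strict
`>`), the tract's threshold is switched exactly one candidate lower — once,
and only for that tract — and the distance re-measured; the record keeps
both the initial and final threshold. The reported distance is the one at
the final threshold.

### Emulated manual measurement

The manual reading is restricted to the axial slice (k-plane) of the
contact's nearest voxel: the returned value is the Euclidean distance from
the pole coordinate to the closest tract voxel center *visible on that
slice*. Because the visible tract is a subset of the whole tract, this
subset-restricted minimum can never undercut the true 3D distance — the
axial-restriction error is non-negative by construction, which the test
suite checks for every phantom contact. When the tract does not intersect
the slice, the reading is not measurable and the record drops out of the
manual comparison, mirroring what happens at the workstation. An optional
seeded uniform jitter (default 0, i.e. deterministic) stands in for human
reading variability; it is an emulation knob, not a model of any specific
reader.

A worked 3-voxel geometry in the tests pins the mechanism down: with mask
voxels at indices (10,10,10) and (10,14,11) on a 2 mm grid and the contact
at the center of voxel (10,10,11), the automated distance is 2.0 mm (one
slice below), the manual reading is 8.0 mm (four in-plane steps), and the
axial restriction alone contributes 6.0 mm of error.

### Landmark-based normalization error

A normalization is modeled as `T(x) = A x + w(x)`: a 4×4 affine plus a
smooth sinusoidal residual field. Each of the three warp components is a
single sinusoid, `w_j(x) = a_j sin(2π <x, u_j> / λ + φ_j)`, with amplitude
`a_j` drawn uniformly from `[0, warp_amplitude_mm]`, a random unit
wavevector `u_j`, wavelength `λ`, and random phase — so the displacement
norm is bounded by `sqrt(3) * max(a)` and a zero amplitude gives a pure
affine. The error statistic mirrors the landmark protocol: `d_native` is
the tip-to-landmark distance in native space, `d_norm` the distance from
the transformed tip to the atlas landmark, and the error is
`|d_norm - d_native|` — the difference of two scalar distances, not the
displacement of points. Rigid transforms with a homologous atlas landmark
therefore give exactly zero error, isotropic scaling by `s` gives exactly
`|s - 1| * d_native`, and the mean error grows with the warp amplitude;
all three facts are tested.

Cases with error above `outlier_cutoff_mm` are excluded as presumed
misnormalizations before summarizing. The cutoff defaults to 5 mm and is a
package decision: published retained errors of this protocol top out near
2.3 mm while gross registration failures produce errors several times
larger, so any cutoff in the gap between those regimes yields the same
partition; 5 mm sits comfortably inside it and is exposed as a
configuration key.

## What the phantom emulates — and what it does not

`generate_cohort()` builds, per patient and hemisphere:

* **Tract probability maps.** A piecewise-linear centerline with a
  Gaussian transverse profile: voxel value
  `round(n_samples * exp(-r² / 2σ²))`, `r` the world-mm distance to the
  centerline, values below 1 zeroed. The true transverse profile of
  streamline-count maps is not documented; any monotone-decaying profile
  would serve, and the Gaussian is chosen because its mask radius at
  threshold `t` has the closed form `σ sqrt(2 ln(n_samples / t))`, making
  tests analytic. Defaults: peak `n_samples = 5000` (the conventional
  per-seed sample count), `σ = 2` mm on a 96³ grid of 2 mm isotropic
  voxels (the standard DTI acquisition resolution).
* **Background noise.** A seeded 5% of zero voxels receive counts drawn
  uniformly from 1–50 (`n_samples/100`). The fraction matters: the tract
  tube occupies only ~0.2% of the volume, so without noise the 98th
  percentile — and with it the whole robust range — collapses to zero and
  every threshold becomes vacuous. Five percent keeps ≥ 90% of voxels
  zero (the heavy-tailed histogram of real count maps) while pinning
  `rmax` in the middle of the noise range, far below the peak.
* **A spurious side branch** per tract: a short, low-count (peak
  `n_samples/16`) branch leaving the tract's upper course toward the lead
  region. Real probabilistic maps contain exactly such false-positive
  bundles; they are visible at permissive thresholds and vanish at strict
  ones, and they are what makes the measured distance a genuinely
  non-linear, hard-to-predict function of the threshold. Without them the
  threshold sweep would only probe the smooth ~1 mm shrinkage of the main
  tube.
* **Leads.** Quadripolar, 2 mm contact spacing by default (configurable
  for directional leads); the tip is placed 0–8 mm off the c-DRTT
  centerline near its thalamic end with a seeded offset, the trajectory
  pointing superior-anterior-lateral as implanted leads do.
* **Landmark and transform.** A red-nucleus-like point placed midway
  between the two tract centerlines; a per-patient normalization built
  from mild anisotropic scaling (±4–6%), small rotations (±3°), a
  translation, and a ~1 mm residual warp. A configured fraction of
  patients (default 5%) receives a grossly shifted transform whose atlas
  landmark stays where a *correct* normalization would have put it — the
  mechanism that produces the excluded-outlier cases.

Determinism is structural: every generator is a pure function of
(parameters, seed), and each patient draws from an RNG stream derived from
the master seed and the patient index alone, so extending a cohort never
perturbs existing patients.

The phantom does **not** simulate diffusion physics, streamline
propagation, anatomy (atlas meshes, cortical folding), scanner effects, or
co-registration error. Consequently, passing tests demonstrate that the
*measurement and summary machinery* is correct under controlled
conditions — nested masks, exact distances, dominance of the axial
restriction, zero error under isometry. They do not certify the clinical
error magnitudes of any real cohort, which depend on acquisition and
tractography choices upstream of everything modeled here.

## Numerical choices worth knowing

* Percentiles: linear interpolation between order statistics (R's default
  sample quantile), verified against a hand-rolled sort-based oracle.
* Voxel indices are 0-based; world space is RAS+ mm as encoded in the
  NIfTI affine (sform). All distances are computed in mm, never voxel
  units, so anisotropic grids need no special-casing.
* `nearest_voxel()` rounds exact half-fractions toward the lower index, a
  fixed tie-break that keeps results platform-independent.
* Empty masks are legal, flagged, and excluded from feasibility and
  sensitivity rather than raising mid-pipeline errors; the distance
  transform itself refuses an empty mask, since its result would be
  meaningless.
* Summary statistics use the sample standard deviation (n−1), with SD
  defined as 0 for a single observation.
* Manual-vs-automated differences are reported as absolute values; the
  directional sign is not informative once jitter is enabled.
* NIfTI volumes are written as 64-bit float with the affine in the sform,
  so data round-trip bit-exactly.

## Problem sizes

The package's own verification runs use: a 2-patient 48³ cohort for unit
tests; the default 10-patient 96³ cohort (160 contact×tract measurements)
for the cohort-level properties (mask nestedness, distance monotonicity,
axial dominance); 50 random masks up to 20³ with random anisotropic
spacings for the distance-transform oracle; and a 200-patient landmark
phantom for the warp-amplitude sweep. These sizes were chosen to exercise
every code path at full fidelity while keeping a complete verification run
in the low minutes on a single core.

## Known limitations

* The Dice-minimizing threshold selection is a proxy; a human reader
  weighing anatomical plausibility may choose differently, and the paper
  trail of such choices cannot be recovered from code.
* Manual measurement is emulated at voxel-center resolution; a human reads
  the tract *edge* on an interpolated display, which this package does not
  model.
* Oblique (sheared) acquisition grids are out of scope: the distance
  transform assumes the affine's axes are orthogonal (rotations are fine,
  shears are not), and axial slices are taken as k-planes.
* The normalization model is a smooth field plus affine; real registration
  error has localized, anatomy-dependent structure that a three-sinusoid
  field cannot represent.
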