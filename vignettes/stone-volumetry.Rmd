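---
title: "Density-window stone volumetry and its reproducibility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-window stone volumetry and its reproducibility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonevol)
```

## The measurement model

Urinary stones are strongly attenuating on non-contrast CT: calcified stone
material typically sits at 400--1800 HU while the surrounding soft tissue and
urine sit near 0--80 HU. The volumetry method implemented here exploits that
contrast directly. The operator chooses a *density window* --- an inclusive HU
interval `[hu_low, hu_high]` that visually fits the stone --- and the stone
volume is then

> (number of voxels with HU inside the window, grouped into connected
> components) x (voxel volume in mm^3^).

No meshing, surface fitting or smoothing is involved: the voxel sum *is* the
measurement. Consequences worth stating explicitly:

* **Exactness with respect to the mask.** `total_volume_mm3` equals the summed
  component voxel counts times `sx*sy*sz` to machine precision; this is a
  tested invariant, not an approximation.
* **Monotonicity.** Because the window is closed on both ends and thresholding
  is per-voxel, enlarging the window can never shrink the segmented volume.
  The sources describing the method do not state whether their interval is
  open or closed; we chose closed on both ends, which matches the "range that
  fits the stone" reading and makes monotonicity exact.
* **Discretization error lives on the surface.** For a digitized sphere of
  radius $r$ at isotropic spacing $h$, the volume error is bounded by the
  surface-layer volume $4\pi r^2 h$ and shrinks as $h$ does; the test suite
  checks this at $h \in \{1, 0.5, 0.25\}$ mm.

The single operator-controlled degree of freedom of the method is the window.
That observation drives both the observer model in the simulator and the
interpretation of the agreement statistics: reproducibility of this method
*is* reproducibility of window choice, plus image noise.

## Segmentation pipeline choices

`segment_stones()` runs threshold -> connected components -> size filter ->
per-component measurement. Where the method description is silent we made
these choices, all overridable:

* **Connectivity 26 by default.** A stone fragmenting across oblique voxel
  corners should remain one object; 6 and 18 are available, and component
  counts are tested to be monotone (26-count <= 18-count <= 6-count).
* **`min_voxels = 1` by default.** No silent noise filtering; a filter, when
  requested, removes the filtered voxels from the total rather than
  reassigning them.
* **Heterogeneity flag.** A segment is flagged heterogeneous when its
  within-segment HU range exceeds 600 HU. The phrasing this threshold comes
  from is directionally ambiguous; the flag here is symmetric around a
  configurable threshold, and it is metadata only --- it never alters the
  volume.
* **Maximum diameter.** The exact maximum pairwise distance between voxel
  centers, computed over the component's 6-connectivity boundary voxels (a
  superset of the convex-hull vertices, so exactness is preserved) in
  compiled code. At desk scale this is fast; bulk simulations can skip it
  (`measure_diameters = FALSE`).
* **Display windows are not analysis windows.** Bone-window viewing advice
  affects what an operator sees, never the voxel sum; the package has no
  display-window dependence anywhere in the computation.
* **Complexity and location are metadata.** Whether a stone is a (partial)
  staghorn, and where it sits, are anatomical judgments involving the renal
  collecting system, not derivable from the stone mask alone; they are
  supplied per case by the user (or by the simulator, which knows the truth).

Input is NIfTI-1 (values assumed to be HU after scanner rescale); masks and
labelmaps are written back as NIfTI-1, per-segment tables as CSV/JSON.

## Geometric estimators

The classical formulas are provided for comparison: spherical
$\tfrac{4}{3}\pi r^3$, ellipsoid $\tfrac{\pi}{6} \, l \, w \, h$, cumulative
diameter, the planar surface estimate $\tfrac{\pi}{4} d w$, and Ackerman's
$0.6 \pi r^2$. Ackerman's formula is implemented verbatim as it circulates in
the clinical literature; note that it is dimensionally an area, not a volume
--- we flag this in the documentation rather than "fixing" a formula that is
always quoted in this form. The worked example the estimators are tested
against: a 12 mm sphere is 904 mm^3^ (truncated) while a 20 x 5 x 5 mm
ellipsoid is 262 mm^3^ (rounded) --- about 3.5x less material despite the
larger maximum diameter.

## Lithotripsy duration

The duration model is deliberately structural:
`duration_s = volume_mm3 / ablation_speed`, with the speed keyed exactly by
(laser source, fiber diameter, composition, pulse energy, frequency). The
published calibration behind the original software's duration estimate is not
reproduced here; no default rate table ships enabled, and a missing key is a
loud error rather than a nearest match. `example_rate_table()` contains
clearly labeled illustrative values so the plumbing is testable. Whether real
procedures add an efficiency factor (duty cycle, basketing pauses) on top of
pure ablation time is outside this model and documented as such.

## Agreement statistics

All statistics are implemented from their defining formulas and unit-tested
against hand computations and independent references:

* **Lin's concordance correlation**, $\rho_c = \dfrac{2\,\mathrm{cov}(x,y)}
  {\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2}$ with population (1/n)
  moments --- the standard definition --- and a Fisher-z confidence interval
  using Lin's large-sample variance. $\rho_c = r \cdot C_b$ with
  $C_b \in (0, 1]$, so a location or scale shift penalizes concordance but
  not correlation; tests check this decomposition, symmetry, and invariance
  under identical rescaling of both series.
* **Kendall's W** with mid-rank tie correction,
  $W = 12 S / (m^2(n^3 - n) - mT)$, significance via
  $\chi^2 = m(n-1)W$ on $n-1$ df. For tie-free data, $W$ equals
  $((m-1)\bar\rho_s + 1)/m$ where $\bar\rho_s$ is the mean pairwise Spearman
  correlation --- tested by brute force --- and the implementation is
  cross-checked against `vegan::kendall.global` with and without ties.
  A fully degenerate matrix (every rater constant) is defined as $W = 1$
  with a warning.
* **Coefficient of variation**: per (case, observer), sample SD of the
  replicates over their mean, in percent. The observer summary is the
  arithmetic mean of that observer's per-case CVs (median also reported);
  subgroup summaries use the *median* of per-case-per-observer CVs. The
  published table this package reproduces prints one CV per observer without
  stating its aggregation; the mean was chosen as the default summary and
  both are returned.
* **Bland--Altman**: bias, sample SD of differences, limits of agreement
  `bias +/- 1.96 SD`, repeatability coefficient `1.96 SD` (the RC/SD ratio
  of 1.96 is an exact construction, which the published values 827.11/422
  also satisfy). A Monte-Carlo test checks ~95% of Normal differences fall
  inside the LoA.
* **Mann--Whitney U** for subgroup CV comparisons: exact two-sided p by full
  enumeration for groups of at most 8 without ties (cross-checked against
  the exact path of `wilcox.test`), otherwise the normal approximation with
  tie correction. **Paired t-tests** delegate to `stats::t.test`.
* Tests are two-sided throughout and no significance threshold is hard-coded
  in library code.

`agreement_study()` binds these into the full analysis of a long-format
measurement table. Two aggregation modes exist because published summary
tables often print only per-case medians while the underlying analysis may
have used all raw replicates: `"median"` collapses replicates to per-case
medians first (the only mode runnable on the packaged per-case-median
fixture), `"raw"` pairs raw values by (case, replicate). Intra-observer
concordance is operationalized as Kendall W across the replicate-wise
rankings of the cases within one observer --- the source material does not
define it precisely, so this assumption is recorded here.

### The packaged clinical fixture

`read_table2b()` loads a verbatim transcription of a published table of
per-case median volumes (50 renal-stone cases x 3 observers of different
experience levels, each the median of 5 blinded repeat measurements). Three
typographic anomalies of the printed table are preserved in a `raw`
provenance column and normalized in the numeric columns: one French decimal
comma, thousands separators, one interval not bracketing its median and one
median outside its printed interval. Running `agreement_study()` on these
medians reproduces the printed agreement levels (overall $W = 0.992$,
pairwise $\rho_c$ 0.988--0.995, and Bland--Altman RCs of 593.5 and 827.1
mm^3^ for the extreme pairs, matching the printed 593.47 and 827.11) ---
which also tells us the published Bland--Altman analysis was run on per-case
medians.

## The phantom simulator

`simulate_phantom()` renders analytic geometry into HU volumes: a Gaussian
soft-tissue background (40 +/- 15 HU), stones painted at their core HU
(900--1600 HU in the default cohort), optional core/shell heterogeneity (the
outer 20% of the normalized radius at a different HU), isotropic Gaussian
blur as a partial-volume surrogate, and additive HU noise. Shapes are
spheres, rotated ellipsoids, and a branched "staghorn-like" template: a
pelvis ellipsoid (semi-axes `size * (1, 0.65, 0.6)`) plus three calyceal
branch ellipsoids at fixed template angles, scaled by one size parameter.

Ground truth is analytic for spheres and ellipsoids ($\tfrac{4}{3}\pi abc$)
and, for branched unions, a fine voxelization of the union indicator at 1/8
of the stated spacing (overlap counted once), evaluated slab-wise to bound
memory. Truth never depends on the noise realization, and every stochastic
operation takes an explicit seed with a bit-identical reproducibility
contract.

**What the simulator emulates and what it does not.** It reproduces the
features that drive threshold-dependent volume error: high stone-tissue
contrast, partial-volume blur at edges, HU noise, internal heterogeneity,
and single/multiple/branched morphology. It does *not* model CT physics
(beam hardening, reconstruction kernels, streaks), patient anatomy
(collecting-system geometry, neighboring bone), or dual-energy behavior.
Passing end-to-end tests therefore demonstrates that the *pipeline* recovers
known volumes and known agreement structure under realistic-looking noise
--- not that clinical images behave identically.

**Observer model.** Since the window is the method's only operator control,
observer variability is modeled solely as jitter of the lower threshold:
`hu_low ~ Normal(mean_o, sd_o)` per replicate, with the upper threshold
fixed (stone HU has a natural ceiling well below bone implants). No
inter-slice relabeling noise is simulated. A drawn threshold above the upper
bound would be degenerate and is redrawn with a warning, with a bounded
number of retries.

**Default study conditions.** The reference design is 50 cases x 3 observers
x 5 replicates = 750 measurements. The default cohort mixes shapes (35%
spheres, 25% ellipsoids, 20% staghorns, 20% two-stone cases) with true
volumes spanning roughly 150--10,000 mm^3^, 0.75 mm isotropic spacing, 0.8 mm
blur sigma and 20 HU noise. The three default observers differ slightly in
habitual threshold (560/600/620 HU) and jitter (52/40/36 HU SD). No
quantitative observer-noise parameters are published for this method, so
these values are illustrative: they were calibrated once so that simulated
per-case CVs land in the low-single-digit-percent range reported for trained
operators (the default study yields mean per-observer CVs of roughly 4--5%),
and are documented as tuning, not ground truth. With them, the simulated
study reproduces the qualitative clinical findings: near-perfect
inter-observer concordance on medians, intra-observer W above 0.99, and
branched stones showing significantly higher replicate CV than plain ones
(the surface-to-volume argument: jitter moves a surface layer, and staghorns
have much more surface per unit volume).

## Numerical and degenerate-input conventions

* Voxel indices are 1-based in R; physical distances are between voxel
  centers in mm. A single-voxel component has diameter 0.
* An all-excluding window is a valid empty segmentation; an empty *volume*
  is an error.
* Lin CCC: both series constant and equal gives 1; both constant and unequal
  gives 0 with a warning; n < 3 is an error; |ccc| = 1 gives a degenerate CI
  at the point estimate.
* CV with zero mean is reported missing, never infinite.
* Zero-variance differences make the paired t-test an error (not p = NA).
* Reported volumes are full-precision doubles; only formatted reports round
  to integer mm^3^. CSV round-trips write full-precision decimal strings.

## Problem sizes used in the checks

The test suite exercises oracles on random grids up to 20^3 voxels, sphere
recovery at 0.25 mm spacing (~100^3 voxels), the full 50-case default cohort
once, and 20-seed averages for the shape-difficulty comparison on small
grids; the acceptance script regenerates the full 750-measurement study.
These sizes were chosen to make every property measurable in seconds to a
couple of minutes while keeping the discretization fine enough for the
surface-bound arguments to be meaningful.

## Known limitations

* DICOM series input is not supported; convert to NIfTI-1 (with HU rescale
  applied) upstream. This keeps the I/O layer small and testable with plain
  files.
* The duration model is a pluggable rate division, not a validated clinical
  calibration.
* The heterogeneity flag is a range threshold, not a composition classifier.
* Simulator realism ends where CT physics begins (see above); absolute CV
  levels from the simulator should not be quoted as expected clinical
  performance, only the relative structure.
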