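---
title: "Quantitative CT of pulmonary congestion and airway structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT of pulmonary congestion and airway structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`lungqct` implements a quantitative chest-CT analysis pipeline for studies
of pulmonary congestion (extravascular lung water, EVLW) and airway
structure, of the kind used to compare stable heart-failure patients with
controls before and after an inhaled beta-2 agonist.  It has three layers:

1. **Measurement** — lung-field segmentation with voxel exclusion rules,
   attenuation-histogram indices of congestion, per-voxel air/tissue
   partitioning, airway-tree segmentation with leak control, and
   per-generation airway morphometry with subject-size normalizations.
2. **Cohort statistics** — Welch and paired t-tests, Bonferroni correction
   across airway generations, and Pearson correlation screens assembling
   the study-style group tables.
3. **A ground-truthed digital thorax phantom** — synthetic volumes and
   cohorts carrying the statistical structure the analysis assumes, so
   every stage can be verified end to end without patient data.

# Density analysis

## Analysis mask

Lung fields are extracted by thresholding at `-320` HU (midway between
aerated parenchyma near `-820` HU and soft tissue near `+30` HU),
discarding components connected to the grid border (ambient air), keeping
the two largest interior components, and closing with a one-voxel
26-connected structuring element.  If only one interior component remains
(lungs fused across a narrow anterior junction, which also happens in
phantoms at coarse voxel sizes) the pipeline warns and proceeds.

The analysis mask then excludes airway-lumen voxels and all voxels outside
`-1000..0` HU.  The range is *inclusive* at both ends: a voxel at exactly
`-1000` or `0` HU participates.  Only the lumen is excluded, not the
airway wall: wall voxels sit above `0` HU in practice and fall to the
range rule, which keeps the two rules nearly orthogonal and their
per-rule exclusion counts interpretable (both counts are reported).

## Histogram indices

All indices are computed on the raw masked voxel values, not on binned
counts; the histogram (default bin width 1 HU) is used only for the FWHM.

* **Mean attenuation** (HU).
* **Skewness** `g1 = m3 / m2^1.5` and **kurtosis** `g2 = m4 / m2^2 - 3`
  from central moments with denominator *n*.  Kurtosis is reported as
  *excess* kurtosis by default — the common convention in scientific
  software — with the raw variant available (`excess = FALSE`); which one
  a given clinical report used is often ambiguous, so both are a keystroke
  apart.  A congested lung has a heavier high-attenuation tail relative to
  its width, hence *lower* skewness and kurtosis.
* **FWHM** (HU): the width between the two half-maximum crossings of the
  histogram, searching outward from the modal bin (ties broken toward
  lower HU) with linear interpolation between adjacent bin centres.  At
  1 HU bins the interpolation error is below 1 HU.  Degenerate conventions
  fall out of the definition: a single occupied bin yields one bin width,
  a flat-top histogram its full width.
* **Congestion index**: the percentage of voxels *strictly above*
  `-500` HU.  The threshold itself does not count.
* **Air and tissue volumes**: each voxel's air fraction is the linear
  attenuation partition `f_air = (55 - HU) / 1055`, clamped to `[0, 1]`
  (pure air at `-1000` HU, pure tissue at `+55` HU), and
  `f_tis = 1 - f_air` exactly; `Vair`/`Vtis` are the mean fractions times
  the masked volume, so `Vair + Vtis` conserves the masked volume to
  machine precision.

## Pre/post percent change

For every index except the mean, percent change is
`100 * (post - pre) / |pre|`.  Mean attenuation uses the magnitude
convention `100 * (|post| - |pre|) / |pre|`, so a leftward shift of the
histogram toward `-1000` HU — fluid clearing — is a *positive* change.
This matches the reporting convention of congestion studies in which all
five indices move "toward dry lung" with positive mean change; the signed
variant is available.

# Airway analysis

## Lumen segmentation

The lumen is grown 6-connected from a tracheal seed over a relaxing
threshold schedule (`-950` to `-500` HU in 25 HU steps).  6-connectivity
is deliberate: sub-threshold noise voxels in parenchyma occupy a few
percent of sites at the early thresholds, far below the ~31% site
percolation threshold of the 6-connected lattice, so noise cannot form
spurious paths, whereas 26-connected growth percolates easily through
diagonal contacts.  After each relaxation step the accepted-volume growth
ratio is compared with `leak_ratio` (default 2 per step): a step that more
than doubles the region is rolled back entirely and growth stops.  This
contains segmentation leaks through thin or defective walls — verified
with a fixture that punches a one-voxel channel through a generation-3
wall, where the contained mask stays within 10% of the true lumen volume.
A seed region that is already enormous at the initial threshold (default
bound 150 mL, several times a real tracheobronchial lumen) raises an
"unsegmentable" error rather than returning a flooded mask.

The tracheal seed can be given explicitly or found automatically as the
first compact interior air region when scanning slices from the cranial
end.

## Centerline tree by wavefront decomposition

Rather than 3-D thinning, the tree is read from a wavefront decomposition:
a 26-connected BFS geodesic distance from the root voxel (lowest slice
index in the mask, ties toward the mask centroid), voxels binned into
one-step distance shells, shells split into connected clusters, and each
cluster linked to its most-contacted cluster one shell closer to the
root.  A wavefront that splits into two clusters marks a bifurcation;
cluster centroids ordered along the cluster tree form the centerlines.
Generations count bifurcation depth from the root with the trachea as
generation 1 (an offset argument accommodates the zero-based convention
some groups use).  All children of a branch point get generation
`parent + 1`, so a trifurcation yields three siblings of the same
generation.  Terminal stubs of a single cluster, or of at most two
clusters spanning less than one voxel, are pruned and the tree re-merged;
anything longer is treated as a resolved branch.  By construction the
cluster graph is a tree, so no cycle breaking is needed.

## Morphometry

At cross-sections perpendicular to the smoothed centerline, rays are cast
outward and HU sampled by trilinear interpolation at quarter-voxel steps.
Edges are located by the half-maximum principle: the luminal edge is the
half-way crossing between the lumen plateau and the wall peak walking
inward from the peak; the outer wall edge is the half-way crossing between
the wall peak and the outer minimum walking outward.  Rays without
sufficient lumen/wall contrast (default 200 HU) are dropped; a
cross-section needs 60% valid rays to count.  Luminal area is the polygon
area of the edge radii; wall thickness the mean outer-minus-inner
distance over rays with outer contrast (default 50 HU).  Cross-sections
within one median radius (half a diameter) of either centerline end —
the bifurcation neighbourhoods — are discarded, and the *medians* across
retained cross-sections are returned, making the estimate robust to the
few oblique sections near junctions.

A segment is flagged `unreliable` when fewer than three cross-sections
survive, when the measured wall is below 1.2 voxels (airways with walls
of roughly two pixels or less cannot be measured credibly), or when
almost no ray finds outer contrast.  On digital cylinders at 0.5 mm
voxels this operator recovers luminal areas within 3% and walls within
0.11 mm, axis-aligned and at 45 degrees, and its area error decreases
monotonically as voxels shrink from 1.0 to 0.25 mm.

Per-generation summaries average segment means within each generation
(segment-mean-then-generation-mean; the alternative of pooling
cross-sections would weight long segments more), dropping generations
deeper than 6, the depth that airway segmentation reaches reliably on
clinical scans.  Two normalizations are emitted: luminal area over the
subject's total lung capacity (mm²/L), and wall thickness over luminal
area at the same generation (mm/mm²).  Because reports disagree on
whether the wall should be normalized by area or by radius, the
wall-over-radius ratio is emitted as well; area is the primary choice as
the dimensionally natural pairing with the area measurements themselves.

# The digital thorax phantom

## Anatomy and rendering

A soft-tissue body ellipsoid (`+30` HU) in an air background contains two
lung ellipsoids and a symmetric dichotomous airway tree: the trachea runs
along the slice axis and every segment splits into two children rotated
by `branch_angle` (default 35°) from the parent direction, the branching
plane alternating between the x–z and y–z planes.  Child directions are
clamped to at most 60° from the slice axis, emulating the generally
caudal heading of real airways and keeping deep generations from curling
outward; one child of a clamped pair continues nearly parallel to its
parent, a monopodial pattern that real airways also show.  Radius, wall
and length decay geometrically per generation; the default radius ratio
0.71 makes luminal *area* halve at each generation (0.71² ≈ 0.5), and the
default wall ratio 0.9 thins walls by about 10% per generation — both
patterns reported for human airway trees.  Defaults (trachea radius
8.8 mm, wall 2.6 mm) give a generation-1 area near 245 mm².

Voxels are assigned by centre-point membership with no antialiasing, so
the truth masks are *exact* but rendered radii carry a known bias of up
to one voxel; walls are rendered first and lumina carved afterwards, so
parent and child lumina connect through the shared junction while distal
tips stay capped by wall.  Tree geometry that would leave the grid raises
an error naming the offending generation, and voxel spacing larger than
the tracheal radius is rejected as unresolvable.

## Parenchymal attenuation model

Each parenchymal voxel draws from a three-component mixture:

* an **aerated** component `base + N(0, sd_eff)`, where
  `base = -1000 f + 30 (1 - f)` is the air/tissue mixing value at air
  fraction `f` (default 0.83, giving a peak near `-820` HU), and
  `sd_eff = sqrt(noise_sd² + (k·w)²)` couples the parenchymal
  heterogeneity to the edema weight `w` (defaults `noise_sd` 16 HU,
  coupling `k` 4400 HU per unit weight);
* a fixed **vascular/interstitial right tail**,
  `base + Exponential(mean 120 HU)` with weight 0.08, giving the healthy
  lung its characteristic right-skewed histogram;
* an **edema (EVLW)** component `N(-300, 100)` HU with weight `w`.

The exponential tail is essential: with a purely Gaussian baseline the
histogram skewness would *rise* from zero as edema is added, the opposite
of what congested lungs show, because observed congestion lowers skewness
and kurtosis from already high baseline values.  The variance coupling
makes the histogram widen with congestion and narrow again when fluid
clears, reproducing the FWHM behaviour of pre/post bronchodilator scans.
The defaults were calibrated once, analytically from the mixture moments,
so that edema weights near 0.010 (control-like) and 0.018 (heart-failure-
like) bracket the published group values of skewness, kurtosis, FWHM and
percent of voxels above -500 HU, with skewness and kurtosis strictly
decreasing in `w` over the working range [0.0005, 0.05] and mean HU and
congestion index strictly increasing over [0, 0.3].

The truth object records every mask (parenchyma, lumen, wall, edema
voxels), the exact tree geometry, the per-voxel true air-fraction map and
the per-voxel mixture bookkeeping, making phantom-versus-measured
comparisons exact.

## Bronchodilator response

`apply_bronchodilator()` resamples a fraction `clearance` of the edema
voxels from the non-edema model, shrinks the coupled noise component of
every aerated voxel to its post-clearance level deterministically (the
same voxel keeps its standardized residual), and thins airway walls by a
fraction with the lumen untouched.  Full clearance therefore reproduces
an edema-free phantom up to sampling noise, and zero effect is the exact
identity.  Wall voxels lost to thinning become parenchyma (inside the
lung regions) or soft tissue (in the mediastinum).  At coarse voxel
sizes thinning may remove no voxels from the thinnest generations — the
measured wall change saturates at the resolution limit, which mirrors
what CT itself does.

## Synthetic cohorts

`cohort_spec()`/`sample_cohort()` draw two groups (defaults n = 29
control, n = 31 heart failure).  Spirometry (% predicted) and
generation-level luminal areas are drawn jointly from a 10-variable
Gaussian copula whose cross-correlations are the targeted area–function
correlations (defaults follow the published control/heart-failure
pattern, with within-block correlations of 0.7); an infeasible (non
positive semi-definite) target set raises an error, and exactly singular
targets such as a perfect correlation are honoured via the symmetric
matrix square root.  Edema weight, TLC, tracheal geometry and the
bronchodilator response are drawn per subject; fractional clearance
increases with baseline edema burden through a logit-linear slope, which
is what produces the published pattern of stronger histogram changes in
wetter lungs (baseline-versus-change correlations positive for mean HU
and negative for the other indices).  Subject-level distributions beyond
means, SDs and the targeted correlations are not identifiable from
published summaries; the cohort model is explicitly first-two-moments
plus copula.

Two consumption paths exist: `simulate_cohort_records()` is a
histogram-level fast path (the subject's voxel sample is drawn directly
from the mixture, no 3-D rendering) for cohort-scale statistics, and
`write_cohort_phantoms()` + `run_cohort()` renders every subject and runs
the full imaging pipeline, deterministically for a fixed seed and
configuration.

## What the phantom does *not* emulate

Lobar anatomy, discrete vascular trees, cardiac structures, breathing
motion, reconstruction kernels and gravitational edema gradients are out
of scope.  Passing tests therefore demonstrate the *internal* correctness
and calibration of the pipeline — segmentation, morphometry, histogram
indices, statistics — not its accuracy on clinical images, where
scanner-dependent blur and anatomy-dependent segmentation failures
dominate.  Two phantom-specific caveats: the tracheal wall abuts
same-attenuation mediastinal tissue, so generation-1 wall thickness is
biased high (rays without outer contrast are dropped, but rays crossing
the thin mediastinal gap to the lung overshoot); and the outermost deep
generations can exit the lung ellipsoids, where their walls lose outer
contrast and are flagged rather than measured.

# Statistics

Group comparisons use the Welch unequal-variance t-test (the safer
default when only "independent t-test" is specified; the same closed form
serves raw samples and printed `(mean, SD, n)` summaries, letting
published tables be re-tested directly).  Pre/post comparisons use the
paired t-test on per-subject differences, with numerically constant
difference vectors handled explicitly.  All tests are two-sided with
alpha 0.05.  Tests across airway generations are Bonferroni-corrected
with m = 6.  Correlation screens use the Pearson coefficient with the
ordinary least-squares line.  Percent-change summaries report the mean ±
SD of per-subject percent changes, not the percent change of group means.
Subjects without a post scan contribute to baseline tables but never to
paired analyses.

# Verification sizes and numerical choices

The test suite verifies: the analytic FWHM of a Gaussian sample and the
analytic skewness/kurtosis limits of an exponential sample at n = 10⁶
(Monte-Carlo SEs estimated by block splitting); cylinder morphometry at
radii 2–6 mm, walls 1–2.5 mm, voxels 1.0/0.5/0.25 mm, axis-aligned and
45° oblique; segmentation, topology (2⁶ − 1 segments to generation 6) and
leak containment on the full-size phantom (188 × 132 × 180 voxels at
0.75 mm); congestion monotonicity across edema weights 0–0.3 on ten
seeds of a reduced single-airway phantom; the bronchodilator sign
pattern end to end; type-I error calibration on 1000 identical-group
cohorts and copula calibration on 200 cohorts; and byte-identical
reproduction of a rendered four-subject cohort run.  These sizes were
chosen as the smallest at which each property is unambiguous.  All
randomness flows through explicit seeds; a phantom is bit-identical for
a fixed seed, and the package never perturbs the caller's RNG state.
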