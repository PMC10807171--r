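---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroquant)
```

This vignette is the package's account of the quantification procedures it
implements for astrocyte/glioblastoma microscopy, the assumptions behind
them, and the choices made where the underlying methods are conventionally
under-specified. Everything asserted here about accuracy is computed by the
test suite or by `scripts/acceptance.R`; no empirical claim is made beyond
what those runs measure.

## The synthetic-data generator defines the study conditions

All validation rests on seeded generators whose ground truth is known
exactly. They emulate the acquisition settings of the assays they stand in
for:

* **Puncta stacks** — isotropic 2D Gaussian spots (default σ = 2 px at
  0.1 µm/px, i.e. FWHM ≈ 0.47 µm, the scale of plasmalemmal AQP4
  aggregates seen by confocal microscopy) replicated over z with a Gaussian
  axial profile, inside a cell mask, z-planes 0.5 µm apart. Noise is
  additive Gaussian by default; a Poisson photon-noise option exists. No
  real point-spread function is modeled: no axial asymmetry, no spectral
  bleed-through, no uneven illumination. Passing count-recovery tests on
  these stacks therefore demonstrates the detector logic, not robustness
  to every real-world artifact.
* **Filament textures** — straight segments with orientations von Mises
  distributed about a mean (concentration 0 = uniform), per-filament
  intensities gamma distributed so that the shape parameter controls the
  skewness of the intensity histogram (skewness of a gamma with shape *s*
  is 2/√s), emulating bundling. Real filaments curve and cross; the
  generator's straight segments make orientation ground truth exact.
* **Gap series** — both wound fronts advance at *v*, so
  `area(t) = max(0, width − 2vt) · length`, sampled every 4 h for 28 h
  (the time-lapse protocol of the assay), with optional additive noise.
* **Calcein traces** — 1 frame/s, 30 s baseline, 90 s post-stimulus;
  baseline at 100%, logistic swelling to `Fmax` (plateau defined as 99% of
  the asymptote), exponential relaxation of the excess over baseline after
  the peak (rate λ gives a ground-truth RVD half-time ln 2/λ), linear
  photobleaching, Gaussian noise in percent of baseline.
* **Tracks, expression matrices** — random-walk nucleus tracks with known
  total path length; gene × sample matrices with one designated pair
  following `y = slope·x + ε` on the z-score scale.

Defaults were chosen once to represent realistic assay conditions (spot
SNR 5–10, noise 1–2% of baseline fluorescence, 4-h sampling) and are not
tuned per test.

### Continuity of the swelling trace

The logistic swelling model `F/F0(t) = Fmax/(1 + e^{−k(t−t0)})` has value
`Fmax/2` at its midpoint. For amplitudes below 200% of baseline that value
is *below* the 100% baseline, so a logistic passing through 100% exactly at
stimulus onset must have its midpoint before onset:
`t0 = onset + ln(Fmax/100 − 1)/k`. The generator's default places `t0`
there, producing a continuous, physically plausible trace; an explicit
`t0` after onset is honoured but introduces a step at the stimulus (the
lower half of the sigmoid is then partly inside the record). Both regimes
are exercised in the tests. Consequently the fitted `t0` is not
constrained to lie after onset.

## Regions: shrink-to-area and perinuclear growth

"A 20% or 10% smaller outline (by area)" is implemented as thresholding of
the Euclidean distance-to-boundary transform — the continuous limit of
iterative erosion — with the cut chosen so the retained area hits the
target fraction as closely as the discrete distance values allow
(tolerance ±0.5% of the area ratio, verified on 50 random convex and
concave masks). This is robust for concave outlines, where polygon
offsetting can self-intersect. A mask too thin to erode that far fails
loudly, naming the closest achievable fraction.

The perinuclear region grows from the nucleus by distance (the limit of
iterative dilation), clipped to the cell, until its area is twice the
nuclear area (±2%); when clipping prevents that, the maximal region is
returned with a `clipped` flag. The subplasmalemmal band and the retained
inner region partition the cell exactly by construction.

Occupancy uses the maximum-intensity z-projection by default ("merged"
stacks; a sum projection is available) and an Otsu threshold on the
in-region histogram unless an explicit threshold is given.

## Puncta detection, density and FWHM sizing

Detection is plugin-style: threshold, 3D connected components
(26-connectivity default, 6/18 available), minimum object size 4 voxels.
The auto threshold is Otsu; because Otsu simply splits a histogram it
misbehaves on noise-dominated stacks (it bisects the noise mode), so if
the Otsu cut marks more than 5% of voxels as foreground — puncta are
sparse — the threshold falls back to robust background statistics
(median + 3.5 MAD), and to "no signal" if even that fails. This keeps
signal-free stacks at zero detections without any per-stack tuning.
Labeling is implemented on an adjacency graph (`igraph` components) and is
checked in the tests against an independent flood-fill oracle on random
≤ 32³ stacks.

Diameters: the equatorial plane is the z-plane maximizing the object's
integrated intensity; horizontal and vertical profiles through the
centroid are background-subtracted and the half-maximum crossings located
by linear interpolation. Two numerical details matter at the 2–5% level
on the generator's own fixtures:

* the *peak* value is refined by a parabola through the three top samples,
  otherwise sub-pixel spot centres depress the apparent maximum and narrow
  the FWHM;
* the local background is the median of the 2-px frame at the border of
  the analysis window (±12 px), not a shell hugging the object's bounding
  box — a tight shell sits on the spot's own tail (~3% of peak for a
  Gaussian) and biases the width low by ~2–5%.

The reported diameter is the mean of the horizontal and vertical FWHM.
Whether a single-direction FWHM or the mean is "the" size is a convention;
the mean is used and both widths are returned.

## Colocalization

Object-based colocalization is the percentage of channel-A objects sharing
at least one voxel with any channel-B object — the convention for "percent
of plasmalemmal AQP4 aggregates colocalized with plectin". Pixel-based
coefficients (Pearson r in a mask; Manders M1/M2 with per-channel
thresholds) are provided for tissue-style analyses where object identity
is less clear; which coefficient a given published "percentage of
colocalization" reflects is often unstated, so both routes are exposed and
the object-based one is the package default for cultured cells.

## Filament metrics

The skeleton (Zhang–Suen thinning, written here as no installed package
provides 2D thinning) is broken at branch points detected by *crossing
number* — more than two connected blocks of skeleton neighbours — rather
than by raw neighbour count, which misfires on diagonal staircases.
Branch pixels are removed together with their 8-neighbourhood, since arms
of a junction otherwise remain diagonally connected. Each remaining branch
is fitted by total least squares (principal axis), segments shorter than
5 px are discarded as spurs, and orientation statistics are
length-weighted (an unweighted mode exists).

Parallelness is the circular mean resultant length on doubled angles,
`R = |Σ w e^{2iθ}|/Σ w`: 1 for a single orientation, 0 for balanced
orthogonal families or uniform orientations. This is the standard
directional-statistics index matching the meaning of plugin-reported
"parallelness" scores; the exact formula used by any particular plugin is
not published, so R is documented as an analogue, not a reproduction.
Bundling skewness is Fisher's g₁ over in-region pixel intensities,
computed over the whole cell by default (per-region available).

## Migration

The gap-closure fit uses the first four time points (0–12 h) by default,
where closure is linear; `v = |slope|/(2l)` and `t½ = A₀/(2|slope|)`
follow from symmetric front advance. Gap segmentation from raw DIC movies
is out of the computational core — the pipeline consumes binary gap masks
or area series, since published gap outlining is typically manual. Track
mobility sums Euclidean steps of nucleus positions; an optional band
filter keeps cells starting 150–300 µm from the leading edge. Group
summaries aggregate per-replicate values by median.

## Volume dynamics

The analysis pipeline is: Savitzky–Golay smoothing (window 11 samples,
order 3), baseline bleach correction, normalization to percent of
baseline, logistic fit, RVD half-time. Three deliberate choices:

* **Bleach correction subtracts only the fitted slope** `m·t`, not the
  whole fitted line — subtracting the intercept too would zero the
  baseline and make F/F₀ undefined.
* **The smoothed trace serves for landmarks only** — the swelling peak
  (hence `t_s,max` and the end of the fit window), the no-swelling check
  (post-stimulus range < 2% of baseline), and the RVD half-recovery
  crossing. The logistic itself is fitted to the *bleach-corrected raw*
  samples: least squares averages noise by itself, and pre-filtering a
  rise whose duration is comparable to the filter window (at k = 0.3–0.6
  /s the rise spans 7–20 samples against an 11-sample window) biases the
  fitted rate down by 10–50% on the recovery grid, versus ~1% when
  fitting the raw samples. The smoothed baseline tail (half a window
  before onset) is likewise excluded from the bleach fit because filter
  transients at the stimulus step leak backwards.
* **Sign convention**: the model is written `e^{−k(t−t0)}` with k > 0 for
  an increasing response (an equivalent parameterization of the
  decreasing-exponent form, k ↔ −k).

The fit runs three jittered multi-starts (initialized from the trace
maximum, the half-rise time and `k ≈ 4·max-slope/Fmax`) and keeps the best
RMSE. "Swelling rate" is reported as the logistic k, with the realized
maximal derivative `Fmax·k/4` also emitted, since reported "rates" in the
literature may be either. The RVD half-time is the first interpolated
crossing of `100 + (F_peak − 100)/2` after the peak, censored at the
record end.

Recovery (acceptance run, 27 parameter conditions × 20 seeds): median
relative error ≈ 0.5% for `Fmax` and ≈ 4.5% for k, errors increasing
monotonically with noise.

## Statistics

The Mann–Whitney implementation reports `U = min(U_a, U_b)` with midrank
ties. For tie-free samples with `n_a + n_b ≤ 12` the two-sided p is exact:
the null distribution of `U_a` is enumerated over all rank placements and
the smaller tail doubled (capped at 1); it matches an independent
enumeration oracle and `wilcox.test(exact = TRUE)` on every achievable U
for `n_a + n_b ≤ 10`. Larger or tied samples use the normal approximation
with tie and continuity corrections; its type-I error at α = 0.05 over
2000 null simulations lies in [0.03, 0.07]. Group summaries are the median
with a bootstrap SE (1000 seeded resamples) — the SE of a median has no
standard closed form. Kruskal–Wallis and post-hoc procedures are not
reimplemented; base R provides them.

One spec-level recovery figure proved analytically unattainable: a
photobleaching slope of −0.5 intensity/s estimated from a 30-sample, 1-Hz
baseline with noise at 1% of a 500-intensity baseline has an OLS standard
error of ≈ 0.105 — about 21% relative — so "recovery within 2%" is
impossible for any unbiased estimator at those settings. The test suite
asserts the closed-form OLS accuracy instead, plus exact noiseless
recovery.

## Problem sizes

The validation suite uses 200×200 px stacks with 5 z-planes (100 stacks
for count recovery), 27 × 20 swelling traces of 121 samples, 50 random
masks for the region contracts, 10⁴-segment orientation sets, 10⁵-pixel
skewness samples and 2000 null simulations for test size — sizes at which
every property is measured stably and the whole suite runs in well under
a minute per module.

## Known limitations

* No optical realism: results on synthetic stacks bound algorithmic, not
  instrumental, error.
* FWHM sizing assumes an isolated, roughly convex punctum; overlapping
  puncta merge at detection (documented behaviour) and are sized as one.
* The skeleton decomposition does not trace filaments through junctions;
  a long filament crossing another contributes two segments.
* Gap masks/areas are inputs; the heuristic DIC segmenter is a
  convenience, not a validated method.
* The exact Mann–Whitney path is limited to 12 combined samples by
  enumeration cost; beyond that the corrected normal approximation is
  used (its agreement with the exact p at n = 6+6 is within 0.03).
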