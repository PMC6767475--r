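---
title: "Methods: arterial-tree morphometry with arbormetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arterial-tree morphometry with arbormetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbormetrics)
```

## The measurement model

A centerline reconstruction represents an arterial tree as a rooted tree of
3D nodes, each carrying a local radius in mm (`centerline_tree`, read from
SWC or CSV node tables). The analysis decomposes the tree into *segments* —
node chains between consecutive branch points, with the branch point shared
between the inbound segment (as its last node) and each outbound segment
(as its first node), so every edge belongs to exactly one segment — and
*bifurcations*, one per branch point.

Per-node radii near a junction systematically under-represent the vessel
calibre (the lumen pinches just before and after a branch point), so
segment end radii are never read off the end nodes. Instead, the first and
last quartiles of each segment's node list are discarded and an ordinary
least-squares line `radius ~ arclength` is fitted through the middle two
quartiles, then evaluated at arclength 0 and L. This estimator is exact on
linear radius profiles and, by construction, completely insensitive to any
radius perturbation confined to the outer quartiles — both properties are
enforced by tests.

Bifurcation radii are then segment-derived: the parent radius `r0` is the
inbound segment's distal estimate and the daughter radii are the outbound
segments' proximal estimates, sorted so `r1 >= r2` (ties are harmless: all
statistics are symmetric in the daughters). From these the package computes
the area ratio `AR = (r1^2 + r2^2)/r0^2` (extended over all daughters for
trifurcations), the asymmetry ratio `AS = r2^2/r1^2` (bifurcations only —
it is undefined for higher-order junctions), the minimum-work statistic
`n = (r1^3 + r2^3)/r0^3`, and the junction exponent solving
`r0^x = r1^x + r2^x`. Tree-level compliance is summarized by the
regression of summed cubed daughter radii on cubed parent radii: slope 1
means the tree as a whole obeys the principle of minimum work; the
analogous squared-radius regression estimates the population area ratio.

### Assumptions

* Nodes within a segment are ordered and roughly evenly spaced along the
  centerline, so "quartiles of nodes" (by index) and "quartiles of
  arclength" nearly coincide. Index-based trimming is the default; mixing
  the two conventions within one analysis is never done.
* Radii and positions share the same unit (mm; µm inputs are converted at
  read time).
* Each tree has a single root; the root-side segment has no parent, so the
  root branch point (if the root itself branches) yields no usable
  bifurcation record.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_diameter_voxels` | 2 | exclusion threshold: segments/bifurcations whose diameter is below this many voxels are dropped (radii near the resolution limit are unreliable); skipped when no voxel size is recorded (dissection/caliper data) |
| `Q` (ROUT) | 0.01 | maximum desired false-discovery rate of outlier calls in regressions and parameter summaries |
| `bracket` (exponent solve) | [0.5, 50] | search interval for the junction exponent; daughters nearly as large as the parent push the root beyond any finite bracket and are reported `no_finite_exponent` |
| `n_directions` (FWHM) | 8 | in-plane profile directions averaged per node |
| `normality_reps` | 10000 | Monte Carlo replicates for the Lilliefors-type normality p-value |

## Robust regression and outlier removal (ROUT)

Straight-line fits are cleaned by the robust-regression-and-outlier-removal
scheme: (1) a robust fit minimizing the Lorentzian merit
`sum(log(1 + (res/RSDR)^2))`, initialized from OLS and iterated with the
robust scale re-estimated between iterations until the merit changes by
less than 1e-9 relatively (at most 500 iterations); (2) the robust standard
deviation of residuals taken as the 68.27th percentile of |residuals| times
`N/(N-K)`; (3) a step-down false-discovery scan from the largest residual,
testing the j-th largest at two-tailed t-probability threshold `j*Q/N`
(df = N-K) and stopping at the first survivor; (4) a plain OLS report
(slope ± SE, intercept, R², p) on the surviving points. A through-origin
variant is available but the default keeps the intercept, matching the
standard behaviour of the curve-fitting software this procedure originates
from. Summaries of single parameters use the constant-model (K = 1)
specialization; the asymmetry ratio is never cleaned because it is bounded
in (0, 1], so its extremes are legitimate values, not artifacts. Outlier
masks are strictly per analysis — each regression and each parameter
summary makes its own calls.

Two numerical guards matter. When the robust residual scale is
indistinguishable from floating-point rounding (below 1e-12 of the data
scale) no outliers are called, so an exactly-fitting dataset is never
mutilated. And `Q = 0` disables calls entirely. Note a structural caveat:
on data whose residual spread grows with the predictor (as cubed radii do
when relative radius errors are constant), the percentile-based scale is
set by the small-radius majority and the scan may trim a substantial
fraction of the large-radius tail; the reported slope SE then reflects the
surviving points only and understates the leverage of the large junctions.
The regression slope itself stays accurate (the minimum-work recovery test
below), but its nominal SE should be read with this in mind.

The p-value reported as `p_value` tests slope ≠ 0; `p_slope_one` tests
slope ≠ 1 (the minimum-work hypothesis). Both are emitted because summary
slopes are conventionally quoted with the slope ≠ 0 test even when the
scientific question is the slope-1 comparison.

## Normality testing and summaries

Because morphometric parameters are typically non-normal, distributions
are summarized as median (n, IQR, range) with type-7 (linearly
interpolated) quartiles. The normality check is a one-sample KS statistic
against a normal with estimated mean/SD; since estimating parameters makes
the classical KS null anticonservative, p-values are Monte-Carlo
(Lilliefors-type), re-simulating the statistic under normal samples of the
same size. Constant input is degenerate and reported non-normal.

## The synthetic generator: what it emulates, and what it does not

The generator exists so every stage has exact ground truth. It grows a
binary tree breadth-first: each branch draws a length-to-radius ratio
`LR ~ lognormal(meanlog = log 8, sdlog = 0.6)`, lays down equal
`node_spacing` (0.05 mm) steps along a bounded-turning random walk (turn
scale 0.25 per step, so arc length ≈ chord length), interpolates radii
linearly to `taper_factor` times the proximal value, and then splits with
an asymmetry ratio `AS ~ Beta(0.8, 1.2)`, daughters solving
`r1 = r0/(1 + AS^{x/2})^{1/x}`, `r2 = r1*sqrt(AS)` — exactly satisfying
`r0^x = r1^x + r2^x` for the configured exponent (default 3). Noise is
multiplicative Gaussian per node (default sd 2%), applied after truth is
recorded. Growth stops below `min_radius` (0.02 mm) or at
`max_bifurcations` (250).

Defaults were chosen once to emulate the measured conditions of cerebral
trees in the 0.03–1.6 mm radius range: a 1 mm root radius; LR medians in
the published 4–10 range with a long upper tail; a side-branch-heavy
asymmetry distribution (density rising towards AS = 0, median ≈ 0.35),
which makes one mechanism — detection-radius censoring of thin branches —
reproduce the reported ordering of median AS across measurement modalities
of increasing resolution; taper 1.0, since measured median tapering is
≈ 0.99; and 2% radius noise, a plausible per-node tracing error. Each
segment is discretized into at least 6 nodes so that quartile trimming
always excludes the junction node shared with the parent (that node
carries the parent's distal radius, the generator's analogue of the
junction dip).

`censor_tree()` removes every subtree whose true proximal radius is below
the detection limit and merges the resulting pass-through junctions, so
surviving bifurcation records are bit-identical to their uncensored
versions — censoring removes records, never alters them.

What the generator does *not* emulate: vascular territories and anatomy
(no named arteries, no realistic 3D embedding or collision avoidance),
correlated tracing errors, junction-localized radius artifacts beyond the
shared-node effect, non-binary junctions (trifurcations are handled by the
analysis but not generated), and inter-subject variability. Passing tests
on generated trees therefore validate the *measurement pipeline* —
segmentation, end-radius estimation, filtering, statistics — not the
anatomical realism of any particular tree.

Tube phantoms for the FWHM estimator are rasterized as signal voids (dark
lumen in bright gel, the appearance of a cast in gadolinium-doped
gelatine) with 3× supersampled partial-volume edges. The FWHM width takes
the background level from the outer 25% of profile samples and the vessel
level from the profile minimum — level estimation from the profile itself
makes the width invariant to affine intensity changes. Radius estimates
with diameters under two voxels are flagged unreliable rather than
silently reported.

## Numerical choices and degenerate inputs

* Junction exponent: bracketed root-finding on
  `f(x) = (r1/r0)^x + (r2/r0)^x - 1` (strictly decreasing when both ratios
  are below 1), accepted only if the defect is below 1e-10 relatively.
* Segments with fewer than 4 nodes use the mean radius for both ends and
  are flagged `too_few_nodes`; middle windows with fewer than 4 nodes are
  widened symmetrically to the middle `ceiling(n/2) + 2` nodes. Flags are
  carried into the output so such records stay auditable.
* Coincident nodes contribute zero length; `LR = 0` is a legal value.
* Tie between equal daughter radii: `r1 = r2`, `AS = 1`; no statistic
  depends on the ordering.
* Pooling of same-label inputs is plain concatenation before any
  statistic, and outlier removal happens after pooling.
* All generator randomness flows from one integer seed; a fixed seed gives
  byte-identical SWC output and report tables.

## Problem sizes

The test suite exercises trees of 10–600 bifurcations; parameter-recovery
checks use a 600-bifurcation tree with 2% noise (the same condition the
acceptance script regenerates), ROUT calibration uses 200 replicates of
100-point fits, and phantom recovery uses 31³ volumes at 0.1 mm voxels
with tube radii 0.08–0.3 mm. These sizes were chosen to make every
statistical claim testable in seconds while keeping sampling error well
below the tested tolerances.

## Known limitations

* The end-radius estimator assumes an approximately linear radius profile
  over the middle half of a segment; strong mid-segment stenoses would
  bias both end estimates.
* ROUT's SE caveat on heteroscedastic regressions (above).
* The FWHM estimator assumes a single dominant dip per profile; adjacent
  vessels within the profile length can shadow the crossing search.
* No centerline extraction is provided: the package starts from traced
  centerlines, not from images (phantom volumes serve validation only).
* Statistical comparison *between* modalities/labels is deliberately out
  of scope; the pipeline reports per-label summaries side by side without
  significance claims.
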