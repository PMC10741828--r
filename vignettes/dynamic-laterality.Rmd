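---
title: "Dynamic functional laterality: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional laterality: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynlat)
```

## The question and the quantity

Hemispheric specialisation is not static: a region's preference for
co-fluctuating with its own versus the opposite hemisphere drifts over
the course of a resting-state scan. `dynlat` quantifies this with the
**dynamic laterality index (DLI)**. Within a sliding window $t$, for
region $i$,

$$\mathrm{DLI}_i^{(t)} \;=\;
  \operatorname{atanh} r\!\left(x_i^{(t)},\, GS_L^{(t)}\right) \;-\;
  \operatorname{atanh} r\!\left(x_i^{(t)},\, GS_R^{(t)}\right),$$

where $r$ is the Pearson correlation inside the window, and $GS_L$,
$GS_R$ are the left and right **hemispheric global signals** — the
unweighted mean of each hemisphere's ROI series, computed within the
same window. The Fisher z-transform is applied to each correlation
before differencing, so DLI lives on an unbounded, variance-stabilised
scale. Positive DLI means stronger coupling with the left hemisphere;
relabelling hemispheres negates every value exactly (this antisymmetry
is asserted bit-for-bit in the test suite).

Two subject-level summaries are taken over any window set (all windows,
or the windows of one laterality state):

* **MLI** (mean laterality index): the mean DLI — a region's average
  lateral preference;
* **LF** (laterality fluctuation): the standard deviation of DLI —
  how restless that preference is. Sample SD (`ddof = 1`) by default,
  configurable.

The default window geometry is 50 samples at step 1 (100 s at TR = 2 s,
the shortest window that still resolves the 0.01 Hz lower band edge), so
a 142-sample series yields exactly 93 windows: $W = \lfloor (T -
\mathrm{len})/\mathrm{step} \rfloor + 1$.

### Choices the definition leaves open

* *What enters the global signal.* The package computes GS from ROI
  means, and by default a region is included in its own hemisphere's
  mean; `gs_exclude_self = TRUE` leaves it out (both paths are checked
  against a per-window reference implementation to ~1e-15). With 45
  regions per hemisphere the difference is second order.
* *Aggregate-then-summarise vs summarise-then-average.* Subnetwork MLI
  and LF are computed on the unit-mean DLI series by default; averaging
  per-ROI summaries instead is available via `aggregate = "roi_mean"`
  (the two differ for LF, which is convex in the series).
* *Degenerate windows.* A zero-variance window column, or a within-
  window correlation of exactly ±1 (infinite z), aborts with an error
  naming the region and window. Nothing is clipped silently.

## Preprocessing scope

`dynlat` starts from ROI-by-time matrices (or a labelled 4-D array).
The in-scope steps mirror standard resting-state practice: discard of
the first 10 volumes, linear detrend plus optional nuisance regression
(OLS residualisation against an intercept, ramp and user-supplied
confounds such as tissue signals or motion expansions), and a 0.01–0.1
Hz band-pass. The filter is a Butterworth design (4th-order prototype,
band transform, bilinear mapping) applied forward and backward for zero
phase with odd-symmetric edge padding; no DSP dependency is used, and
the implementation was cross-checked against a reference scientific
stack during development. Scanner-level steps (slice timing,
realignment, normalisation, smoothing) are upstream and out of scope.

## Laterality states: three-stage temporal clustering

Recurring whole-brain DLI configurations ("laterality states") are
found in three stages:

1. **Per-subject spherical k-means** (`subject_kmeans`), cosine
   distance, small over-clustering `k1 = 5`. Cosine is the right metric
   here: a window is a 90-dimensional direction whose magnitude mostly
   reflects sampling noise. `k1` is not stated in the source design; 5
   preserves subject-level diversity without letting any subject
   dominate the pool, and it is a config knob.
2. **Pooling and multi-resolution community detection.** All subjects'
   centroids are pooled (96 × 5 = 480 rows in the reference design) and
   connected by clipped cosine similarity (negative similarities → 0,
   since modularity expects non-negative weights; a shift-to-[0,1]
   alternative is available). A uniform self-loop of strength $r$ is
   added to every node and weighted Newman–Girvan modularity is
   maximised for each $r$ on the grid 0.1–1.5 (step 0.1) by a
   Louvain-style optimiser (deterministic ascending node order,
   smallest-index tie-breaks, plus seeded random-order restarts keeping
   the best modularity). Small $r$ favours coarse partitions, large $r$
   fine ones; the **most persistent community count** — the one holding
   over the longest consecutive run of resolutions, ties toward the
   smaller count — fixes the number of states $k$. Persistence is
   measured on the count, not on partition identity, because the
   quantity being selected is "how many states", not a fixed partition.
3. **Final centroids and assignment.** Spherical k-means with $k$ fixed
   (20 seeded restarts, best inertia) on the pooled centroids gives the
   state centroids; every window of every subject then goes to its
   nearest centroid in cosine distance. Occupancy is the per-state
   fraction of all windows.

The optimiser is validated against exhaustive-partition modularity
maximisation on all random weighted graphs up to 8 nodes in the test
suite. One subtlety found there: for a single-edge graph the optimal
count is 1 below $r = 1$ and 2 above it — the self-loop strength
genuinely moves the optimum even for trivial graphs, which is the
mechanism the resolution sweep exploits.

## Statistics layer

Group comparisons use the pooled-variance two-tailed Student t-test
(the source design names only "two-sample two-tailed t-test"; Welch is
a config option), with Benjamini–Hochberg FDR applied **within a
family**: the 12 hemisphere + subnetwork-by-hemisphere units, or the 90
nodes, per metric per state. This is the narrowest faithful reading of
"FDR for subnetwork or brain region attributes", and the family is
recorded in every output row. Clinical correlations (metrics of units
that survived FDR, against BPRS/SANS/YMRS-like scores, patients only)
use Spearman's rho with the t-approximation p-value
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; an exact-distribution option exists
for small samples. Sidedness is configurable and defaults to
two-sided: the published SANS result (|R| = 0.320, n = 48 → p ≈ 0.0266)
matches the two-tailed reading, while the YMRS/BPRS p-values (0.048,
0.049 at R = 0.243, 0.241) match the one-tailed one exactly — the
package takes no position on intent and exposes both. Demographics use
the same t-test for continuous variables and a 2×2 Pearson chi-square
*without* continuity correction for the gender split (26/22 vs 27/21 →
p = 0.837, reproduced to 3 dp). The handedness score is
(Right − Left)/(Right + Left); the "±" printed in the source table is
treated as a typo for "+", since the alternative is not a score at all.

## The synthetic cohort generator: what it emulates, and what it does not

Because the original cohort is an external archive, every downstream
stage is validated on synthetic cohorts with planted truth
(`simulation_spec`, `simulate_cohort`). Each region's signal is a
state-dependent mixture of two latent hemispheric drivers plus white
noise:

$$x_i(t) = a_i(s_t)\, D_L(t) + b_i(s_t)\, D_R(t) + \sigma\,\varepsilon,
\qquad a_i^2 + b_i^2 = 1,$$

parameterised by a lateral preference $\lambda_i \in [-1, 1]$
($a = \sqrt{(1+\lambda)/2}$). The drivers are Gaussian noise smoothed
with a width-5 moving average (BOLD-like autocorrelation without an HRF
model); the state sequence is a first-order Markov chain with mean
dwell 70 samples (140 s), long enough that 50-sample windows are
usually state-pure, matching the block-like occupancy the method is
meant to recover. The source paper offers no generative account of its
states; this model is a stand-in and claims nothing more.

**Planted states must respect the endogeneity of the global signal.**
GS is the mean of the very regions being lateralised, so the naive
"whole hemisphere flips preference" patterns collapse: mirroring all
couplings also mirrors the reference, and the DLI image comes back
unchanged (measured cosine ≈ 0.99 between supposedly opposite states).
The default patterns therefore use *disjoint support*: state $s$
activates every third homologous pair at $\lambda = \pm 0.8$
(ipsilateral lean) and leaves the rest neutral; neutral regions then
have near-zero expected DLI by symmetry, and the three state images are
close to orthogonal. Measured at the defaults: between-state centroid
cosines 0.06–0.2 (design premise ≤ 0.2), within-state window-to-
centroid cosine ≈ 0.95 (premise ≥ 0.9) at `noise_sd = 0.4`.

**The planted group effect must not leak.** Any change to one
subnetwork's couplings perturbs the hemisphere means and hence every
region's DLI. One-sided shifts produced false-rejection rates up to
~0.3 in non-target units at d = 1. The default effect is therefore
*mirror-antisymmetric* (+e on right-AN members, −e on left-AN members,
applied only to state-neutral couplings): the two global signals then
move identically in distribution and both the covariance and the
variance channels of the leak cancel. Measured non-target subnetwork
rejection is back at the nominal 5–10%. Hemisphere units still inherit
about a fifth of the AN effect — they contain AN — which mirrors the
original study's own finding of hemisphere-level differences alongside
AN ones.

**Calibration (all fixed before the tests were frozen).**
`group_effect = 0.076` with per-subject heterogeneity SD equal to the
effect (CV 1) yields a cohort-realised Cohen's d of 1.00 on the
right-AN MLI and FDR-level power ≈ 0.97 at 48/group. The CV-1
heterogeneity is what lets clinical scores track severity: the planted
per-subject effect explains about two thirds of the between-patient
variance of the target MLI, so a score coupling of 0.6 realises a
metric–score Spearman rho ≈ 0.49, and the default coupling 0.3 lands in
the study's reported range (R ≈ 0.24–0.32). Scores are drawn on the
instruments' scales (BPRS 44.7 ± 10.9 clipped to 18–80, SANS
21.6 ± 14.1 to 0–80, YMRS 12.0 ± 11.0 to 0–50).

What the generator does **not** emulate: hemodynamic response
convolution, physiological noise, motion, spatial smoothness within
subnetworks, site effects. A green synthetic test therefore establishes
that the estimator recovers the model's own truth at realistic SNR and
sample sizes — not that the model is the mechanism behind the original
data.

## Numerical conventions

* Seeds: every stochastic routine takes an explicit seed; cohort,
  clustering and pipeline stages derive child seeds from a master seed
  through a fixed counter scheme, so identical config + seed gives
  byte-identical artifacts (asserted in tests). Subject-level k-means
  seeds are keyed to the subject id, so subject order only permutes
  provenance.
* Spherical k-means: k-means++ initialisation, ≤ 500 iterations,
  relative-inertia tolerance 1e-6, empty clusters re-seeded from the
  farthest point, ties in assignment to the lowest state id.
* The fast laterality path uses windowed running sums with globally
  centred columns (cancellation-safe) and agrees with the direct
  per-window computation to ~1e-15; the direct path is kept as the
  reference implementation.
* Missing windows (a subject with no windows in a state) yield `NA`
  metrics with `n_windows = 0`, never silent zeros; single-window
  subsets define MLI but flag LF.

## Known limitations

* Persistence-based selection of $k$ inherits the resolution grid; a
  structure that is only stable outside 0.1–1.5 would be missed (grid
  configurable).
* The t-approximation Spearman p is adequate at n ≈ 48 but not for very
  small n; the exact option covers that case.
* `extract_roi_means()` operates on in-memory arrays; reading NIfTI
  files is delegated to the caller's I/O stack (none is available in
  this environment's R installation).
* With 93 heavily overlapping windows per subject, window-level
  observations are strongly dependent; MLI/LF inference treats subjects
  (not windows) as the unit of analysis, which is what makes the
  group-level t-tests valid.
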