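---
title: "Methods: nanocluster co-clustering statistics for SMLM point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanocluster co-clustering statistics for SMLM point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and data model

Single-molecule localization microscopy (PALM/STORM) reduces an imaging
experiment to a table of localizations: camera frame, x/y position in nm,
and a localization uncertainty (typically 20-30 nm for two-color PALM of
membrane proteins). `ncdyn` consumes such tables (ThunderSTORM-style CSV)
and provides the statistics used to describe how membrane proteins such as
small GTPases and their effectors organize into nanoclusters, how strongly
two species mix, and how cluster states evolve through time. Peak
detection and fitting, drift correction, and 3D localization are out of
scope; the package starts from the exported table.

Coordinates are handled as continuous nm values with the origin at the
lower-left corner of a rectangular observation window; there is no pixel
grid. Molecular density is always count / window area, reported in
molecules/um^2.

## Photoblinking correction

A single fluorophore blinks: it reappears over several nearby frames and
would be counted several times. `group_localizations()` merges records
that are chainable by links with spatial distance <= `max_distance` and
frame gap <= `max_off_frames + 1`. We use the *transitive* (single-linkage)
closure of these links because it makes the partition independent of
record order; the alternative (greedy first-match grouping) depends on
sort order. A merged molecule keeps the mean member position and the first
member frame. Mean position was chosen over brightest-peak position; for
the Gaussian localization errors the generators emulate, the mean is the
lower-variance estimate.

The right thresholds are a property of the fluorophore's blinking
statistics, not of this package, so `max_off_frames = 3` and
`max_distance = 50` nm are shipped as documented configuration defaults
only. Note that two localizations of one molecule observed with jitter
sigma in each frame are ~`sigma * sqrt(2)` apart per axis, so the link
distance should sit at ~3x that spread; the validation suite uses 100 nm
when recovering emitters simulated with 20-nm jitter.

Live acquisitions (12,000 frames at 50 fps in the default generator) are
sliced by `window_by_frames()` into consecutive blocks — 250 camera frames
per block yields one reconstructed point pattern every 5 s, i.e. 48
windows over a 4-minute acquisition. A trailing partial block is dropped:
the canonical 12,000 / 250 divides exactly, and a fractional-duration
window would bias per-window densities.

## Pair-correlation statistics and the extent of mixing

The univariate pair-correlation function g(r) is the density of further
molecules at distance r from a typical molecule, normalized by the overall
density, so complete spatial randomness (a homogeneous Poisson pattern)
gives g(r) = 1 at every r and short-range values above 1 quantify
self-clustering. The estimator bins ordered pairs into annuli
(`radial_bins()`, default 10-nm bins from 0 to 1000 nm — the bin width is
a package choice; results in the package are bin-averaged so any width at
or below the localization uncertainty behaves equivalently) and divides by
the pair count expected for a Poisson pattern of the same density.

Two edge-correction modes matter in practice:

* `"translation"` (default): each pair is weighted by the inverse overlap
  area of the window with its translate; unbiased for rectangular windows
  of real data.
* `"periodic"`: torus (minimum-image) distances; exact for the synthetic
  generators, which wrap their patterns periodically. All calibration
  tests pin this mode so oracle comparisons are exact.
* `"none"` is available for diagnostic use and is biased down at large r.

The bivariate function g12(r) (via `bpcf()`) is the density of species 2
at distance r from a typical molecule of species 1, normalized by the
density of species 2; independent patterns give g12 = 1. Self-pairs are
excluded in the univariate case; the bivariate sum runs over all cross
pairs, with coincident pairs (distance exactly 0) falling below the first
bin edge. Consequently `bpcf(a, a)` equals `pcf(a) * (n-1)/n`.

Whether two species co-cluster is judged against the *random labeling*
null: the observed n1 + n2 positions are fixed and the labels reshuffled
preserving counts (`rl_envelope()`, 19 simulations by default). The
per-bin minimum and maximum of the simulated g12 curves — not quantiles —
form the acceptance band; with 19 simulations, the observed curve exceeds
the band maximum with probability 1/20 under the null, a one-sided 95%
interval.

The extent of mixing normalizes g12 between the two nulls:

EOM(r) = (g12(r) - 1) / (mean_RL(r) - 1)

so independence (g12 = 1) maps to 0 and agreement with the random-labeling
expectation to +1. The upstream literature leaves the exact normalizer
unstated; we adopt the linear form above because it is the unique affine
map reproducing both printed anchors, and we use the envelope *mean*
rather than the midpoint because the mean is the Monte Carlo estimate of
the null expectation. In bins where the null itself carries no mixing
signal (|mean_RL - 1| < 0.05) EOM is reported as `NA` rather than as a
ratio of noise; values are reported unclipped, with a `clip` flag for
display. Per-cell curves are combined by `eom_average()`, a per-bin mean
over defined values that records how many cells contributed to each bin.

The scalar summary g(0-100) (`mean_g_short()`) is the unweighted mean of g
over bins with centers in (0, 100] nm; an unweighted bin mean (rather than
an area-weighted integral) was chosen because the downstream state map
treats it as a clustering score, not as an integrated intensity.

## Coordinate-based colocalization

CBC assigns each reference molecule a score in [-1, +1]: the Spearman rank
correlation between the area-corrected radial accumulation of its own
species and of the target species, computed over 50 rings from 20 nm to
1000 nm (20-nm steps match the two-color localization uncertainty; the
1-um ceiling matches the largest cluster structures seen by the PCF). The
profiles are `N(r)/N(r_max) * r_max^2/r^2`; only the `1/r^2` factor
affects ranks. Ties get average ranks. When nearest-neighbor weighting is
enabled (the default, following the standard protocol) the correlation is
damped by `exp(-E/r_max)` with E the distance to the nearest target
molecule.

Two conventions are worth stating explicitly:

* The reference point itself is included in its own-species counts. The
  upstream description is ambiguous about self-counting; including it
  makes the perfect-colocalization limit exact — a target channel whose
  coordinates duplicate the reference channel produces identical count
  profiles and hence a value of exactly +1 with weight exp(0) = 1.
* A reference point with no target neighbor within r_max, or with a
  degenerate (constant) profile, gets `NA`, not 0: zero encodes "no
  correlation", absence of data does not.

The population of CBC values is summarized by a 21-bin histogram over
[-1, 1] and its standard (non-excess) kurtosis; peripheral enrichment of
one species at the other's cluster edges pushes values toward the +/-1
tails and raises the kurtosis relative to a target-randomization null
(`cbc_randomized()`, uniform redraws of the target over the window). Note
the CBC estimator applies no edge correction (the standard formulation
does not); reference points closer than r_max to the window boundary see
truncated rings in both profiles, which attenuates rather than inflates
their scores.

## Nanodomains and enrichment

Domain detection follows the fixed-radius range-search reading of DBSCAN:
molecules within `d_th = 80` nm are linked and clusters are connected
components — single-linkage clustering cut at `d_th`, with no core-point
condition (the upstream procedure has none). Monomers and dimers are
legitimate size classes; polygonal domains are built only for clusters of
at least `min_cluster_size = 3` molecules (configurable), since a
one- or two-point "domain" area would be purely an artifact of the buffer.

Polygons are convex hulls dilated by a `buffer` (default `d_th/2`, so
domain boundaries extend half a link beyond member molecules); degenerate
clusters (collinear members) fall back to a union of discs of radius
`buffer`. The convex hull was chosen over alpha-shapes for determinism and
exact testability — dilated-hull areas have the closed form
`A_hull + perimeter * buffer + pi * buffer^2` — at the cost of
overestimating the area of strongly non-convex clusters; this is a known
simplification. The total domain area is the union clipped to the window:
analytic when domains are pairwise disjoint, and a deterministic
midpoint-grid quadrature over the affected bounding boxes otherwise.

`inout_density()` counts second-species molecules inside the union
(boundary points count as inside, closed polygons) and reports densities
in and out, their fold ratio, the fraction of molecules inside, and the
domain area fraction. `sensitivity_sweep()` reruns the whole chain at
alternative thresholds (60/80/100 nm is the standard check), keeping the
`buffer = d_th/2` rule so the comparison varies one knob.

## The density-clustering state map and cluster dynamics

For live data, each cluster is followed in a 1.5 x 1.5 um ROI through the
5-s windows; `extract_trajectory()` records per window the density of each
species, its g(0-100), and the mean short-range EOM. Empty windows keep
density 0 with `NA` clustering features, and missing features break
downstream transition pairs rather than being imputed.

Synchrony between two species is the Pearson correlation of their density
(or g) series over pairwise-complete windows.

Pooled (density, g(0-100)) observations are classified by a 3-component
Gaussian mixture with full covariances (`fit_state_model()`, backed by
mclust's EM with deterministic model-based initialization). Features are
z-scored first; their raw units differ by orders of magnitude and an
unscaled fit would be dominated by density. Components are mapped to a
fixed label convention so states are comparable across fits: the
highest-g component is state 3 (mature clusters); of the remaining two,
the lower-density one is state 1 (dispersed molecules) and the other
state 2 (dense but weakly clustered domains). The number of states is
fixed at 3 by design; model selection over the state count is a non-goal.
By default the fit pools both species' observations (their state spaces
overlap); per-species fits are a matter of subsetting the input.

`transition_matrix()` estimates the Markov transition probabilities by
pooling transition counts between consecutive windows across all cluster
sequences (the canonical data scale is 41 clusters x 48 windows) and
normalizing rows; probabilities are per 5-s step with lag fixed at one
window. Rows with no observed exits become uniform rows and are flagged.
The stationary distribution of the estimated chain is attached for
occupancy statements ("the most persistent state").

Group comparisons (densities, EOM values between conditions) use the
classic pooled-variance two-tailed Student t test by default — matching
the stated analysis convention — with Welch's correction available via
`var_equal = FALSE`; per-group SEMs are reported alongside.

## Synthetic data: what it emulates and what it does not

The generators define the package's study conditions and supply ground
truth for every recovery test:

* `gen_poisson()` — CSR at 10-100 molecules/um^2 in a 10 x 10 um window,
  the density scale of PALM membrane data.
* `gen_thomas()` — the canonical nanocluster model (Poisson parents,
  Gaussian offspring, sigma 30-60 nm), chosen because its pair
  correlation is known in closed form and serves as an analytic oracle.
  Patterns are wrapped periodically so densities stay homogeneous.
* `gen_random_label_mix()` — a mixing-fraction dial from independent
  single-species clusters (f = 0) to exact random labeling (f = 1),
  reproducing both EOM anchors by construction.
* `gen_periphery()` — species B placed uniformly on annuli around species
  A cluster centers plus a uniform background, the regime in which CBC
  tails grow heavy at cluster edges.
* `gen_domain_enrichment()` — species B placed with a programmed fold
  higher intensity inside species A's detected domain polygons; the
  realized fold is recorded as truth.
* `gen_blinking_movie()` — fixed emitters with on-bursts, dark gaps and
  Gaussian localization jitter over a 12,000-frame / 50-fps acquisition,
  with ground-truth ids for grouping validation.
* `gen_dynamic_assembly()` — a latent 3-state Markov chain per cluster
  ROI driving state-dependent density and clustering; optionally a shared
  Gaussian recruitment signal calibrated (including the Poisson counting
  noise of finite windows) so the measured density synchrony equals a
  programmed value. That calibration is exact when the chain occupies a
  single state; with state switching the state itself adds shared
  variance.

These generators do **not** emulate camera noise or the point-spread
function, fluorophore photophysics beyond simple bursts, chromatic
misalignment between channels, drift, or inhomogeneous cell backgrounds.
Passing calibration and recovery tests therefore demonstrates the
correctness of the estimators on their idealized inputs, not robustness
to every artifact of real acquisitions.

## Numerical choices and degenerate inputs

* Bins are half-open intervals (lo, hi]; a pair at exactly the threshold
  distance belongs to the lower bin, and domain links at exactly `d_th`
  connect. Coincident bivariate pairs (d = 0) fall below the first edge.
* EOM degeneracy tolerance: bins with |RL mean - 1| < 0.05 are undefined.
* Patterns with fewer than 2 points refuse a PCF; CBC needs both channels
  non-empty; the mixture fit requires >= 30 observations and refuses
  constant data; kurtosis requires >= 4 defined values and non-zero
  variance; t tests require n >= 2 per group and non-zero pooled
  variance.
* ROI cropping uses closed bounds, so cropping to the full window is the
  identity and boundary conventions agree with the closed domain
  polygons.
* All Monte Carlo stages (envelopes, randomizations, generators) take
  explicit seeds; the pipeline derives per-stage seeds deterministically
  from one root seed, so a rerun of a configuration is byte-identical.

## Validation scale

The shipped test-suite and acceptance checks run at sizes chosen so each
check's Monte Carlo error is well below the effect it tests: 50-replicate
calibrations of the Poisson and independence nulls (10 x 10 um at 50-100
molecules/um^2), 50-replicate EOM anchor checks, 500 trials for the
19-simulation envelope coverage, brute-force oracle equivalence on
patterns of up to 500 points, and recovery runs at the canonical
41-chains-by-48-windows scale. The finite-window bias of the
pair-correlation estimator for clustered patterns (from the n(n-1)
density normalization) is visible at windows holding few tens of
clusters; the analytic-oracle comparison therefore uses a 15 x 15 um
window holding ~100 clusters, where the bias is far below simulation
error.

## Known limitations

* Convex-hull domains overestimate areas of concave clusters.
* The CBC estimator is uncorrected at the window boundary.
* The transition estimator treats windows as a homogeneous Markov chain;
  it does not model observation noise in the state assignments (no hidden
  Markov smoothing, by design).
* Absolute molecular counts from SMLM are unreliable (labeling efficiency
  and blinking); all statistics here are relative measures, which is also
  how they should be interpreted on real data.
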