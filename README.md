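# ncdyn — nanocluster co-clustering dynamics from SMLM point patterns

Two-color single-molecule localization microscopy (PALM/STORM) resolves
membrane proteins as coordinate lists with ~20-30 nm precision. Questions
about signaling proteins such as small GTPases and their effectors then
become questions about point patterns: does a protein self-cluster beyond
chance, do two species mix inside the same nanoclusters, is one species
enriched inside (or at the edges of) the other's domains, and how do
cluster states evolve through time in live cells?

`ncdyn` implements that analysis chain for localization tables, end to
end and reproducibly:

* **Preprocessing** — ThunderSTORM-style CSV input, photoblinking
  correction by spatiotemporal grouping (single-linkage over space-time
  links), slicing of live acquisitions into fixed-duration windows
  (e.g. 250 camera frames at 50 fps = one point pattern every 5 s), ROI
  cropping.
* **Pair-correlation statistics** — the univariate pair-correlation
  function g(r) (CSR gives g = 1; short-range values above 1 measure
  self-clustering), the bivariate g12(r), Monte Carlo random-labeling
  envelopes (19 simulations, min/max as a one-sided 95% band), and the
  extent of mixing EOM(r) = (g12 - 1)/(mean_RL - 1), normalized so
  independence scores 0 and perfect mixing +1; plus the g(0-100) summary.
* **Coordinate-based colocalization (CBC)** — per-molecule Spearman
  correlation of area-corrected neighbor profiles over 50 rings
  (20-1000 nm), optional exp(-E/r_max) nearest-neighbor weighting,
  randomization nulls, histogram and kurtosis summaries.
* **Nanodomains** — fixed-radius (range-search DBSCAN) clustering at
  d_th = 80 nm with 60/100-nm sensitivity sweeps, size classes
  (monomers, dimers, ... ), buffered convex-hull domain polygons, and
  inside/outside density enrichment of a second species.
* **Cluster dynamics** — per-cluster (density, g(0-100)) trajectories in
  1.5 x 1.5 um ROIs, Pearson synchrony between species, a 3-state
  Gaussian-mixture classification of the density-clustering map
  (state 1 dispersed, state 2 dense/unclustered, state 3 mature
  clusters), and maximum-likelihood Markov transition probabilities
  between states across 5-s windows.
* **Synthetic data** — seed-reproducible generators with known ground
  truth (Poisson fields, Thomas nanoclusters with a closed-form g(r),
  random-labeling mixtures, peripheral and domain-enriched two-species
  patterns, blinking movies, Markov-driven assembly), used by every
  calibration and recovery test.

See the methods vignette (`vignettes/nanocluster-dynamics.Rmd`) for the
statistical conventions and design choices.

## Worked example

```r
library(ncdyn)

# simulate a two-color field: Thomas nanoclusters (sigma 30 nm), labels
# assigned by exact random labeling (perfect mixing)
mix <- gen_random_label_mix(f = 1, parent_density = 0.5,
                            offspring_mean = 20, sigma = 30,
                            window = owin_rect(0, 10000, 0, 10000),
                            seed = 42)
bins <- radial_bins(0, 500, 10)
print(pcf(mix$a, bins, edge_correction = "periodic"))
#> univariate pair-correlation curve, 50 bins (0-500 nm), periodic correction
#>   g(0-100 nm) = 81.219

env <- rl_envelope(mix$a, mix$b, bins, n_sims = 19, seed = 42,
                   edge_correction = "periodic")
print(eom(bpcf(mix$a, mix$b, bins, "periodic"), env))
#> EOM curve: 42/50 defined bins; mean EOM(r < 100 nm) = 1.005
```

The species self-clusters strongly (g(0-100) of ~81 against 1 for a
random pattern; the tighter the clusters, the larger the value), and the
short-range EOM of ~1 correctly identifies the two channels as perfectly
mixed. Bins where the random-labeling null itself is flat are reported as
undefined rather than as noise ratios (hence 42/50 defined bins).

```r
# a second species placed 10-fold denser inside the first's domains
en <- gen_domain_enrichment(fold = 10, density_b = 25, seed = 7,
                            window = owin_rect(0, 8000, 0, 8000))
print(inout_density(en$domains, en$b))
#> Enrichment (d_th = 80 nm): 201.7 in vs 22.52 out molecules/um^2 (8.96-fold)
#>   14.3% of molecules inside domains covering 1.83% of the window

# transition probabilities from 41 state sequences of 48 windows
P <- matrix(c(0.80, 0.15, 0.05,
              0.30, 0.40, 0.30,
              0.10, 0.20, 0.70), 3, byrow = TRUE)
Phat <- transition_matrix(sim_state_sequence(P, 48, 41, seed = 1))
round(unclass(Phat)[1:3, 1:3], 3)
#>        state1 state2 state3
#> state1  0.787  0.157  0.056
#> state2  0.303  0.415  0.282
#> state3  0.099  0.195  0.706
```

The recovered fold (8.96 for a programmed 10, from ~2% domain area
coverage) and the transition matrix (entries within a few hundredths of
the programmed chain) illustrate the recovery accuracy at the canonical
data scale of 41 clusters by 48 five-second windows.

A configuration-driven pipeline (`run_pipeline()`, YAML or R list) runs
preprocess -> pair correlation/EOM -> CBC -> domains -> dynamics in one
call, writing `curves.csv`, `eom.csv`, `cbc.csv`, `domains.json`,
`traj.csv`, `states.json` and a `manifest.json` recording the seed, the
resolved configuration and every default that filled an omitted field.
A thin command-line wrapper is provided at `inst/cli/ncd.R`
(`Rscript inst/cli/ncd.R run --config analysis.yaml`, plus `preprocess`,
`paircorr`, `cbc`, `domains` and `simulate` subcommands).

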