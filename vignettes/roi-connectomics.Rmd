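---
title: "ROI-level functional connectomics and morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-level functional connectomics and morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roiconn)
```

## What the package computes

`roiconn` implements the region-of-interest (ROI) level analysis stack used
in small-animal resting-state fMRI studies of chronic drug exposure: three
treatment groups (placebo, CBD, THC) of ~8 mice imaged at two sessions
(immediately after 28 days of exposure, "chronic", and after a two-week
washout). The stack has five stages:

1. **Synthetic cohorts** (`synth_config()`, `gen_cohort()`,
   `gen_atlas()`, `gen_measure_table()`): because raw MRI data of such
   studies are rarely public, every downstream stage is exercised on
   generated inputs with known ground truth.
2. **Time-series cleaning** (`preprocess_series()`): motion-spike censoring,
   linear detrending, band-pass filtering, nuisance regression, L2
   normalization.
3. **Connectivity** (`correlate()`, `fisher_z()`, `bootstrap_sig()`,
   `z_mask()`, `density_threshold()`): Pearson correlations over all node
   pairs, Fisher z transform, bootstrap significance, |z| and proportional
   edge-density thresholding.
4. **Graph metrics** (`metric_sweep()`, `node_metrics_at()`,
   `modularity_louvain()`, `consensus_partition()`, `rewire_null()`,
   `small_world_index()`): weighted global metrics over a 2–40% density
   sweep summarized by area under the curve (AUC), node metrics at 16%
   density, Louvain consensus modularity, degree-preserving null models.
5. **ROI statistics** (`roi_volumes()`, `normalize_volumes()`,
   `percent_pair()`, `roi_group_stats()`, `fdr_filter()`,
   `fdr_two_stage()`): atlas volumetry, nonparametric group tests with
   omega-squared effect sizes, and the rank-based false-discovery filter.

## The synthetic-data model

Each subject-session series is a draw from an N-node multivariate normal
whose correlation matrix is block structured: `within_module_corr` (default
0.30) inside each of four equal modules, `between_module_corr` (default
0.05) elsewhere. Treatment effects enter as per (group, session)
multipliers on the within-module level; the default plants an elevated
CBD/washout multiplier of 1.4 (within-module correlation 0.42), emulating
increased network segregation — higher modularity — after CBD washout. On
top of the correlated signal the generator adds per-node linear drift
(slopes uniform in ±0.3 signal units over the scan) and Poisson-placed
motion-spike frames (rate 3 per series) in which every node is replaced by
an outlier of 5–10 noise SDs with random sign; planted spike frames are
recorded as censoring metadata.

Defaults mirror the emulated study: 148 nodes (the bilateral graph
parcellation; 139, the atlas parcellation used for volumetry, is one
argument away since the study uses both and does not say which produced the
network figures), 200 timepoints at 1 s, 8 subjects per group, sessions
`chronic` and `washout`. Module count/sizes, correlations and multipliers
were fixed once, from the principle that the planted effect should be
moderate relative to sampling noise at T = 200: within-module correlation
0.30 gives per-pair estimation noise of roughly 0.07 on raw series, so the
0.12 planted increment is detectable at the cohort level without being
trivial at the single-subject level.

The generator does **not** emulate hemodynamic autocorrelation, spatial
smoothness, physiological (cardiac/respiratory) noise, scanner drift beyond
a straight line, within-subject correlation across sessions, or realistic
anatomy in the label images. Passing tests therefore demonstrate that the
pipeline recovers what it claims to recover from data satisfying its own
assumptions — not that those assumptions hold for any particular scanner.

Measure tables draw `baseline * (1 + shift) + N(0, sd)` per subject × ROI.
The planted volumetric shifts follow the reported dopaminergic-subsystem
effects: −12.17% under chronic THC and +10.24% after THC washout
(`measure_effect_spec()`). FA baselines use the reference placebo
means/SDs in `fa_reference_baselines()` where the ROI is named there, else
0.4 ± 0.05, keeping synthetic tables in the printed range.

## Cleaning stages and their numerical choices

* **Spike detection**: the cross-node mean absolute successive difference is
  a robust displacement proxy. Each frame is scored by the *smaller* of its
  two adjacent differences so an isolated outlier frame — not its neighbors —
  is flagged; the threshold is a robust z (median/MAD, default `z_cut = 4`).
  The emulated study names no statistic, so this rule is the package's own,
  and consecutive spike frames can evade the min-rule (a documented
  limitation).
* **Censoring policy**: censored frames are excluded from every fit
  (detrend, nuisance, correlation) rather than interpolated. Design columns
  supported only on censored frames (e.g. spike indicators) are inert and
  dropped from the fit.
* **Detrending**: per-node least-squares line fitted on usable frames,
  subtracted everywhere.
* **Band-pass**: zero-phase frequency-domain masking retaining 0.01–0.1 Hz
  (the alternative 0.009/0.12 Hz pair is available via the arguments); exact
  at DFT bin frequencies. No filter family is specified by the emulated
  pipeline, and a binary mask is the most transparent choice.
* **Nuisance regression**: OLS per node against `[intercept | design]`,
  coefficients fitted on usable frames; rank deficiency is an error naming
  the redundant columns.
* **L2 normalization**: each node's vector scaled to unit Euclidean norm.

Re-running the full chain on its own output is *not* an exact no-op:
detrending and band-passing are projections onto non-orthogonal subspaces,
so a second pass moves values by the in-band leakage of the re-fitted trend
line — on the order of a few percent of the signal scale, with downstream
correlations changing by < 0.1. The test suite asserts stability at that
composed-projection scale; each individual linear stage is exactly
idempotent and tested as such.

## Connectivity and thresholding

Correlations are Pearson over usable frames; `|r|` is clipped to
`1 - 1e-12` before `atanh`. Bootstrap significance is a percentile CI over
paired frame resamples (default B = 1000, alpha = 0.05; a pair is
significant when the CI excludes 0); constant resamples contribute r = 0.
The |z| threshold default is 2.3. Negative edges are discarded by default
before graph analysis (`negative_edges = "absolute"` keeps magnitudes): the
weighted strength/clustering formulas assume nonnegative weights and the
emulated analysis is silent on signed edges. Proportional thresholding
keeps the `floor(density * N(N-1)/2)` largest weights with deterministic
lexicographic tie-breaks, so edge sets are nested across the density ladder
and a sweep ranks edges once.

## Graph metrics

All metrics operate on weighted undirected graphs; path-based metrics use
edge lengths `1/weight`.

* Strength = row sums; degree = nonzero counts.
* Clustering: geometric-mean (Onnela-style) triangle intensity on
  max-normalized weights, divided by `k(k-1)`; the arithmetic variant is a
  documented alternative. Transitivity is the corresponding global
  triangle-to-triplet ratio.
* Characteristic path length = mean shortest-path length over connected
  ordered pairs (Dijkstra); global efficiency = mean of `1/d` with
  `1/Inf = 0`, so it tolerates disconnection.
* Assortativity = Pearson correlation of endpoint strengths over both
  orientations of every edge; uniform strengths return 0 with a warning.
* Betweenness: Brandes accumulation with a 1e-10 relative tolerance for
  geodesic ties; eigenvector centrality: power iteration to 1e-10 on the
  largest component, zeros elsewhere with a warning.
* Modularity: Louvain greedy node moves plus agglomeration (compiled for
  speed), resolution fixed at 1, deterministic given a seed (node order from
  an internal LCG; ties break to the lowest community index). The Q of any
  returned partition always equals the standalone evaluator
  `modularity_q()` recomputed from (graph, affiliation).
* Consensus ("median of 1000 iterations"): a median of partitions is not
  well defined, so the package reports the run whose (module count, Q) is
  closest to the medians across runs — count first, then Q, then lowest run
  index — keeping all runs' diagnostics; an association-matrix consensus
  (mean co-assignment, thresholded at 0.5, re-partitioned) is available via
  `method = "association"`.
* Null models: double-edge swaps (10 per edge by default) preserve the
  binary degree sequence and the weight multiset exactly; weights travel
  with swapped connections. The small-world index follows the emulated
  study's formula literally — `SWI = (CC/CC_null) / (CPL/CPL_null)` — noting
  that its lambda/gamma naming is reversed relative to the usual
  Watts-Strogatz convention.
* The density sweep runs 2–40% in 2% steps, AUC by the trapezoidal rule over
  the stored grid (no method is stated in the emulated analysis; the
  trapezoid is exact for the piecewise-linear curves being summarized).
  Within the sweep, per-density Q is the best of `q_iter` Louvain restarts
  (default 5), a light-weight stand-in for the full consensus that the
  sweep's AUC summarization does not need.

## ROI statistics

Volumes are voxel counts times the unit voxel volume in mm³; normalized
volumes divide by each subject's total labelled volume so fractions sum
to 1. The paired percent decomposition expresses two matched volumes as
complementary percentages summing to 100. Group tests wrap the standard
implementations (paired/one-sample t, Kruskal-Wallis with tie correction,
Mann-Whitney with exact enumeration for tie-free samples up to a combined
n of 12, one-/two-way ANOVA with Type-II sums of squares for unbalanced
layouts). Omega squared uses the classical one-way definition
`(SS_b - (k-1) MS_w) / (SS_t + MS_w)` and is reported unclamped.

The rank-based false-discovery filter compares the i-th smallest p-value to
`i q / (V c(V))` with defaults q = 0.2 and c(V) = 1 over V = 139 regions;
the printed-table display rounds critical values to 3 decimals. The
printed formula is compact ("P(i) <= iVqc(V)"), and `i q / (V c(V))` is the
only reading consistent with the critical values the tables print (0.010 at
rank 7, 0.042 at rank 29, 0.056 at rank 39). The filter flags each ranked
test by its own critical value; decisions are order-invariant. For node
statistics the adaptive two-stage step-up procedure is provided: stage one
runs the linear step-up at `q/(1+q)` to estimate the true-null count, stage
two reruns it at the adaptively inflated level.

## Validation experiments and their problem sizes

The test suite validates every metric against independent brute-force
oracles (triple-loop triangle enumeration, Floyd-Warshall with geodesic
counting, direct normal-equations OLS, exhaustive rank-assignment
enumeration) on 200 random graphs of up to 12 nodes, checks closed forms
(two disconnected m-cliques give Q = 0.5; complete graphs give
CPL = efficiency = 1; a constant metric over the 2–40% sweep gives
AUC = 0.38 × value), and calibrates the bootstrap significance test (1,000
simulated independent pairs at n = 200, B = 1000).

The cohort-level recovery experiment regenerates 100 cohorts (8 placebo +
8 CBD washout subjects, 148 nodes, 200 timepoints) under the default
planted multiplier and asks whether mean modularity AUC is higher for CBD
washout. Series in this experiment are censored, detrended and
L2-normalized but **not** band-passed: the generator's signal is white, so
there is no out-of-band noise to remove, and restricting 200 samples to
0.01–0.1 Hz would keep only ~38 effective degrees of freedom. The extra
estimation noise makes sparse graphs from the weaker (placebo) condition
fragment into more modules, which *raises* their modularity at low
densities and can invert the planted ordering — an instructive artifact of
proportional thresholding on noisy correlation matrices, and the reason the
band-pass stage is validated by its own frequency-response tests instead.

## Known limitations

* Voxel-level processing (registration, ICA denoising, smoothing, tensor
  fitting) is out of scope; the package starts from ROI series and ROI
  measure tables.
* The generator's stationary Gaussian model understates the heavy-tailed,
  autocorrelated noise of real BOLD data; calibration results transfer only
  to the extent the model holds.
* Modularity comparisons across graphs of very different sparsity are
  confounded by the fragmentation artifact described above; the AUC
  summary mitigates but does not remove it.
* The min-of-adjacent-differences spike rule can miss runs of consecutive
  corrupted frames.
* `consensus_partition()` with 1,000 restarts on a 148-node graph takes a
  few seconds; sweeps therefore default to a small number of restarts per
  density.
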