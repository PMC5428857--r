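---
title: "Methods: longitudinal three-level analysis of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal three-level analysis of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longnet)
```

# The analysis model

`longnet` implements a complete analysis chain for two-group, two-session
resting-state functional connectivity studies. The underlying model is
simple and explicit: each scan is summarized as an undirected weighted
graph whose nodes are atlas regions (ROIs) and whose edge weights are the
statistically reliable positive Pearson correlations between the regions'
cleaned time series. Group-by-time effects of an intervention are then
sought at three organizational levels — whole-network topology, modular
(subnetwork) connectivity, and single-node strength — because an
intervention may reorganize the brain's functional architecture at one
scale without touching the others.

## Time-series cleaning

Three operations are applied per scan, by default in the order scrubbing →
nuisance regression → band-pass:

- **Scrubbing.** Power framewise displacement summarizes inter-volume
  motion as the summed absolute backward differences of the three
  translations plus the three rotations converted to arc length on a
  50 mm sphere. Volumes with FD above the threshold (default 1 mm) are
  censored together with their immediate predecessor and successor. We
  chose censoring (deleting flagged volumes before correlation) as the
  primary mode because correlation over retained volumes is the simplest
  well-defined contract; a spike-regression mode (one indicator column per
  flagged volume, entered as nuisance regressors) is available via
  `scrub(mode = "spike")` for users who prefer to keep the temporal grid.
- **Nuisance regression.** Each ROI series is replaced by its residual
  after ordinary least squares on an intercept plus the supplied confound
  columns. The Friston 24-parameter motion expansion (parameters, their
  one-volume lag, and both sets squared) is built by `expand_motion_24()`;
  white-matter/CSF signals can be supplied as extra columns. Global-signal
  regression is exposed as a configuration flag and is off by default.
- **Band-pass.** A zero-phase (forward–backward) order-2 Butterworth
  band-pass, default 0.01–0.1 Hz — the standard resting-state band.
  Forward–backward application avoids phase distortion, which matters
  because correlations are phase-sensitive. Column means are removed
  first, so a constant series filters to zero.

Whether filtering should precede or follow nuisance regression is a point
on which practice varies; the default order (regression first) is a
documented choice and both stages are exposed individually, so any order
can be composed.

A caveat that the pipeline itself surfaces: band-pass filtering makes the
retained noise autocorrelated, so parametric edge p values computed with
`T − 2` degrees of freedom are anticonservative afterwards. This is the
conventional practice this package reproduces, but it is the reason the
backbone heuristic below checks its own output (see *Partition
derivation*).

## Network construction

For each scan, `correlation_matrix()` returns the full Pearson matrix and
two-sided p values from the t distribution with `T − 2` df. Two
thresholding rules are provided:

- **Weighted (primary):** keep edge *(i, j)* iff `r > 0` and
  `p < α / M`, with `M = N(N−1)/2` the number of distinct pairs
  (Bonferroni over pairs, not over the full matrix, since symmetry makes
  the pair the test unit); the retained weight is the correlation itself.
- **Binary (robustness variant):** Benjamini–Hochberg FDR over the `M`
  upper-triangle p values at `q = 0.01`; surviving positive edges get
  weight 1. Selected by `threshold.mode: binary` or the CLI `--binary`
  flag, and every report table records which mode produced it.

Negative correlations are excluded in both modes: their interpretation in
functional connectivity is contested and their test–retest reliability
poor. Self-connections are structurally excluded (zero diagonal).

## Global metrics

With edge weights `w_ij` and edge lengths `1/w_ij` (a stronger correlation
is a shorter functional distance):

- cost `= K / (N(N−1)/2)`; network strength `S_p = mean_i Σ_j w_ij`;
- global efficiency `E_glob = mean over ordered pairs of 1/L_ij` with
  `1/∞ = 0`;
- local efficiency `E_loc` = mean over nodes of the global efficiency of
  each node's neighbour-induced subgraph (weights inherited; neighbourhoods
  smaller than two contribute 0);
- characteristic path length `L_p` = arithmetic mean of `L_ij` over
  *reachable* ordered pairs, with the unreachable-pair count reported
  alongside — Bonferroni-thresholded networks are often disconnected and
  silently averaging infinities would be meaningless;
- clustering coefficient `C_p` = mean over nodes of
  `K_i / (D_i(D_i−1)/2)`, the binary edge-count form on the thresholded
  topology (`D_i < 2` contributes 0); a weighted Onnela variant is
  available behind `clustering_coefficient(variant = "onnela")` for
  sensitivity analysis;
- cost-efficiency `= E_glob / cost`, undefined (NA) on an empty graph;
- modularity `Q` of the network's own spectral partition.

On a complete unit-weight graph every one of cost, `E_glob`, `E_loc`,
`C_p`, `L_p` equals 1 and `S_p = N − 1`; the test suite asserts these
identities exactly for N = 3..8, and all path-based metrics against an
O(N³) Floyd–Warshall oracle on random graphs.

## Modular structure

Weighted Newman modularity is

$$Q = \sum_s \left[ \frac{W_s}{W} - \left( \frac{S_s}{2W} \right)^2 \right]$$

(`W` total weight, `W_s` intra-module weight, `S_s` summed module
strength). `spectral_partition()` maximizes Q by recursive
leading-eigenvector bisection of the generalized modularity matrix with a
Kernighan–Lin-style fine-tuning pass after each candidate split, stopping
when no split increases Q. Determinism is guaranteed by explicit tie
rules: the eigenvector's sign is fixed by making its first nonzero
component positive, fine-tuning sweeps nodes in ascending index order, and
gain ties resolve to the lowest index. Connected components are divided
independently. Exhaustive enumeration of all partitions of 8-node
two-block graphs in the test suite confirms the spectral optimum is within
0.05 of the global maximum on well-separated graphs (and never above it).

### Partition derivation

The reference partition is derived **once**, from the pooled pre-session
data: all pre-training thresholded networks (both groups) are averaged
edgewise, a backbone of locally significant edges is extracted, and the
spectral algorithm partitions the result. The same partition is then
applied to all sessions, so post-training intra-/inter-module strengths
are measured on a fixed node grouping — changes in connectivity are not
conflated with changes in module membership. Pooling both groups (rather
than one partition per group, available behind `partition.per_group`)
reflects the goal of a single representative modular solution for the
whole sample.

The backbone filter is a rank-based empirical local-significance rule: at
each node, an incident edge's local p value is its weight rank among that
node's incident weights (largest = rank 1) divided by the node's degree,
with tied weights all assigned the maximum rank of their tie group (the
conservative choice — ties never gain significance); an edge is retained
if locally significant (`p ≤ α`, default 0.05) at **one or more**
endpoints. One-endpoint retention is a documented decision; the
alternative two-endpoint rule only makes the backbone sparser.

Two structural facts about this rule shape the pipeline's behaviour. The
minimum attainable local p at a node of degree *d* is `1/d`, so in
near-regular networks with degrees below `1/α` (20 at the default) **no**
edge can be locally significant and `backbone_extract()` raises
"backbone empty; relax alpha". And for degrees just above `1/α` the
backbone keeps roughly one edge per node, which shreds the graph into
fragments that no longer reflect the modular organization. `run_study()`
therefore uses the backbone for partitioning only when it is informative —
non-empty and leaving no node without an incident backbone edge — and
otherwise partitions the full group-mean network, recording the fallback
in the log and provenance. At the scale of typical whole-brain atlases
(hundreds of nodes, large degrees) the backbone is rich and is used as-is;
at the desk scale of the synthetic studies it typically is not, and the
fallback gives exact planted-partition recovery.

Intra-module strength is the **mean** weight over a module's unordered
node pairs (zero entries included) and inter-module strength the mean over
all cross pairs; means rather than sums keep values comparable across
modules of different sizes. Singleton modules have no within-module pair
and yield NA.

## Statistics

Each metric (global measures, intra/inter-module strengths, nodal
strengths) is analysed with a 2 (group: MT/RT) × 2 (session: Pre/Post)
mixed ANOVA, implemented by its exact two-stage decomposition for two time
points: the group main effect is an F test in a between-subject model on
subject means `(Pre + Post)/2`, while the time main effect and the
group-by-time interaction are F tests on within-subject differences
`Post − Pre` (the intercept and group terms of the difference model).
Time-invariant covariates (age, education centred; gender effect-coded
±0.5) enter both stages when enabled; group is effect-coded so the time
effect is the unweighted average across groups. Partial eta-squared is
`SS_effect / (SS_effect + SS_error)`. On balanced covariate-free data the
F values agree with the classical `aov(value ~ group*session +
Error(subject))` decomposition to 1e-8, which the test suite asserts; the
implementation reports its own error degrees of freedom
(`n − 2` without covariates, `n − 5` with the three default covariates).

Follow-up simple effects are uncorrected paired t tests of Post vs Pre
within each group (α = 0.05), reported with a direction: the sign of the
mean change always (`trend`), and a significance-gated `direction`. A
constant nonzero change has no within-pair variance and is flagged rather
than tested; an identically zero change reports t = 0.

Multiple comparisons follow a per-level policy: the lenient
false-positive correction `α = 1/n_tests` at the global and intermediate
levels (where `n_tests` is the number of metrics actually tested), and a
fixed uncorrected `α = 0.005` at the nodal level, where test counts are
atlas-sized. An `n_tests = 1` policy degenerates to α = 1 and is logged as
such.

Baseline demographic comparisons use the pooled-variance two-sample t test
from summary statistics and the Pearson 2×2 chi-square without continuity
correction.

# The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` emulate the statistical structure the
analysis assumes, not fMRI physics. Each group-session cell has a block
correlation matrix: `r_intra` inside each planted module, `r_inter`
between modules, plus additive cell-specific deltas on either. Volumes are
drawn as independent multivariate-normal samples (an optional AR(1)
coefficient exists for stress-testing and defaults to 0, since the
analysis consumes only zero-lag correlations). Every cell's matrix is
eigenvalue-checked at specification time and invalid combinations are
rejected outright — never projected — so the generating truth is always
exactly what was requested. Identical seeds give bit-identical cohorts.

Default conditions are chosen to mirror a realistic study of this design
at desk scale: 20 subjects per group, 175 volumes at TR = 2 s (a 6-minute
acquisition minus 5 dummy volumes), unit noise SD, five roughly equal
modules over 64 nodes — standing in for the five canonical resting-state
systems (default mode, salience, somatomotor, fronto-parietal, visual) —
with `r_intra = 0.6` and `r_inter = 0.05`, a strongly modular but not
degenerate regime. No published effect-size scale exists for the
connectivity changes this design targets, so planted deltas are free
parameters; −0.15 on one module's internal correlation is used as the
reference detectable effect in the power checks. Motion tables default to
all zeros, with a spike option for exercising the scrubbing path.

What the generator deliberately does **not** emulate: hemodynamic
autocorrelation and low-frequency drift (so preprocessing is exercised
mechanically, not physiologically), physiological noise spectra, spatial
smoothness, atlas geometry, and between-subject heterogeneity of the
connectome. Passing tests therefore demonstrate that the pipeline's
inferential machinery is correct and calibrated under its own
assumptions — not that those assumptions hold in any given fMRI dataset.

# Numerical and procedural choices

- **Tolerances.** PSD acceptance allows eigenvalues ≥ −1e-8 (a jitter of
  1e-10 is added before Cholesky); spectral splitting requires a leading
  eigenvalue and a Q gain above 1e-10; partition Q is asserted to 1e-10;
  oracle agreements are asserted at 1e-12 where algebraically exact.
- **Degenerate inputs.** Zero-variance ROI columns get r = 0, p = 1 with a
  warning; fully scrubbed series, all-flagged cohorts and saturated
  confound models are hard errors naming the cause; zero-variance metrics
  produce a flagged (NA) ANOVA result rather than an F statistic;
  unreachable node pairs are counted, not averaged.
- **Problem sizes.** The shipped validation uses 64-node, 4×16-module
  cohorts: partition recovery over 10 seeds (ARI ≥ 0.9 required in ≥ 9),
  null calibration of the interaction test over 500 effect-free cohorts
  (rejection rate required within 5% ± 2.5%), and power over 100 cohorts
  with the −0.15 planted decrease (detection required in ≥ 80, with the MT
  simple-effect trend downward). These sizes give stable Monte-Carlo
  estimates while keeping the whole suite's runtime in minutes.
- **Determinism.** `run_study()` seeds every random stream from the
  configuration seed; numeric tables are written at fixed precision (data
  at 15 significant digits, reports at 12), so identical configurations
  reproduce hash-identical reports, which the suite verifies.

# Known limitations

- Parametric edge p values ignore the autocorrelation induced by
  filtering; at scale this inflates edge counts modestly and uniformly,
  and the Bonferroni threshold absorbs much of it, but the edge sets are
  not exact 5% family-wise selections.
- The rank/degree backbone rule is one member of the family of local
  sparsification filters; it is exposed behind a stable contract
  (`backbone_extract()`) so an alternative (e.g. a disparity-style filter)
  can be swapped in without touching the pipeline.
- The mixed ANOVA's covariate adjustment places time-invariant covariates
  in both stages of the decomposition; with heavily unbalanced groups the
  time main effect is the unweighted average of group means, which is the
  Type-III-style convention but not the only one.
- The generator's planted effects act on the population correlation; the
  measured intra-module strength of a thresholded network responds both to
  the weight decrease and to edges dropping below threshold, so measured
  effect sizes exceed the planted correlation delta.
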