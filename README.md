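# longnet

Three-level graph analysis of longitudinal resting-state functional brain
networks in R.

`longnet` is for researchers running two-group, two-session (pre/post
intervention) resting-state fMRI studies who want to ask: *did the
intervention change the functional network, and at which organizational
level?* Starting from regional (ROI) time series, the package

1. **cleans** each series — zero-phase band-pass filtering (default
   0.01–0.1 Hz), Power framewise-displacement scrubbing (censoring the
   flagged volume and its two neighbours), and nuisance regression with the
   Friston 24-parameter motion expansion plus any supplied confound
   signals;
2. **builds networks** — a Pearson correlation matrix with per-edge
   p values, thresholded either as a weighted network (positive edges with
   `p < α / M`, Bonferroni over the `M = N(N−1)/2` pairs) or a binary
   network (Benjamini–Hochberg FDR);
3. **analyses three levels**:
   - *global*: cost, network strength `S_p`, global efficiency `E_glob`,
     local efficiency `E_loc`, characteristic path length `L_p` (edge
     length `1/w_ij`), clustering coefficient `C_p`, cost-efficiency
     `E_glob / cost`, and maximized modularity `Q`;
   - *intermediate*: one modular partition derived from the pooled
     pre-session group-mean network (locally significant backbone where
     informative) by Newman's leading-eigenvector spectral algorithm with
     Kernighan–Lin refinement, then mean intra- and inter-module
     connectivity strength per subject and session;
   - *local*: nodal strength `S_i = Σ_j w_ij`;
4. **tests** every metric with a 2 (group) × 2 (session) mixed ANOVA —
   optionally adjusted for time-invariant covariates such as age, gender
   and education — reporting the interaction F/p/partial η², per-group
   paired simple effects with direction, and level-specific significance
   thresholds (`α = 1/n_tests` for global and intermediate analyses, fixed
   `α = 0.005` for nodal tests).

The modularity being maximized is the standard weighted form

```
Q = Σ_s [ W_s / W − ( S_s / 2W )² ]
```

with `W` the total edge weight, `W_s` the intra-module weight and `S_s`
the summed strength of module `s`.

Because real cohort data of this kind are rarely shareable, the package
ships a first-class **synthetic cohort generator**: multivariate-normal
ROI time series with a planted block correlation structure (modules with
within-module correlation `r_intra`, between-module `r_inter`) and
additive group-by-session connectivity effects, validated for positive
semidefiniteness at specification time. Every stage of the pipeline is
testable end to end against this known ground truth.

## Worked example

Simulate a cohort of 6 subjects per group with four 8-node modules, plant
a post-training decrease of 0.15 in module 1's within-module correlation
for the meditation-training (MT) group only, and run the full study:

```r
library(longnet)

spec <- cohort_spec(n_per_group = 6, n_nodes = 32,
                    module_sizes = c(8, 8, 8, 8),
                    r_intra = 0.6, r_inter = 0.05, n_volumes = 175,
                    delta_intra = data.frame(group = "MT", session = "Post",
                                             module = 1, delta = -0.15),
                    seed = 11)
report <- run_study(list(input = list(synthetic = spec),
                         output = list(dir = "demo_out"), seed = 11))
print(report)
#> longitudinal network study report
#>   partition: 4 modules, Q = 0.7050
#>   global: 8 tests, alpha = 0.125, 1 significant interaction(s)
#>   intermediate: 10 tests, alpha = 0.1, 3 significant interaction(s)
#>   nodal: 32 tests, alpha = 0.005, 1 significant interaction(s)
#>   outputs in: demo_out

im <- report$stats$intermediate
im[im$metric == "intra_M1", c("F_interaction", "p_interaction",
                              "significant", "MT_direction")]
#>  F_interaction p_interaction significant MT_direction
#>           10.3       0.00925        TRUE         down
```

The derived partition recovers the four planted modules exactly
(`Q = 0.705`), and the planted module-1 decrease surfaces as a significant
group-by-time interaction on intra-module connectivity strength with a
downward post-training trend in the MT group — exactly the signature the
pipeline is designed to detect. All tables (global metrics, module
strengths, nodal strengths, per-level stats reports, the partition, a
provenance block) are written as TSV under the output directory, and
re-running with the same configuration and seed reproduces them
bit-identically.

A thin command-line front end with verbs `simulate`, `run`, `metrics`,
`partition` and `stats` is installed at `inst/cli/longnet`.

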