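# netintegrate

Graph-theoretic analysis of resting-state functional integration between
the Salience Network (SN) and the Central Executive Network (CEN), for
researchers comparing two groups of subjects (e.g. experts vs amateurs at
a cognitively demanding skill) on ROI time-series data.

The package implements the full pipeline as tidyverse-style, data-frame
first functions:

- a bundled 23-node SN + CEN atlas (9 SN, 14 CEN point coordinates in MNI
  space) that fixes the node order of every matrix downstream;
- per-subject cleaning: initial-volume discard, zero-phase 0.01–0.08 Hz
  band-pass, 9-covariate nuisance regression, and 27-voxel (3×3×3 cube)
  ROI extraction from 4D volumes;
- connectivity: Pearson `r_ij` between ROI signals and the Fisher
  transform `z_ij = atanh(r_ij)`;
- binary graphs `e_ij = 1 iff r_ij ≥ T` over a grid of 25 thresholds,
  `T ∈ [0.05, 0.30]`;
- the six binary-graph characteristics, with `L_ij` the shortest-path hop
  count and `K_i` the degree:

  - global efficiency `E_global = (1/(N(N−1))) Σ_{i≠j} 1/L_ij`
  - connection cost `K_cost = Σ_i K_i / (N(N−1))` (edge density)
  - mean clustering coefficient
  - nodal degree `K_i`, nodal clustering `C_i = e_i/(K_i(K_i−1)/2)`,
    nodal efficiency `E_i = (1/(N−1)) Σ_{j≠i} 1/L_ij`;

- group inference: label-permutation tests (10,000 permutations, two-tailed,
  add-one corrected p), edge-wise pooled t-tests on Fisher-z values with
  Benjamini–Hochberg FDR over the 253 edges, the internetwork comparison
  (correlation of node-averaged SN and CEN signals, tested on z, reported
  on r), and behaviour–metric Pearson correlations;
- a synthetic cohort generator that plants block-structured group
  differences (within-network and internetwork correlations, behavioural
  coupling), so every stage is testable without scanner data.

See `vignettes/network-integration.Rmd` for the model, conventions and
design choices.

## Worked example

Simulate a cohort under the default study conditions (23 experts vs 22
amateurs, 255 volumes at TR = 2 s, internetwork correlation 0.6 vs 0.3),
clean it, and compare internetwork connectivity:

```r
library(netintegrate)

spec <- cohort_spec(seed = 20)
sim  <- simulate_cohort(spec)
cohort <- sim$cohort
cohort$ts <- lapply(cohort$ts, preprocess_subject, tr_seconds = 2)

internetwork_comparison(cohort, method = "permutation",
                        n_perm = 10000, seed = 21)
#> Internetwork (SN-CEN) functional connectivity
#>   amateur  mean r = 0.63, SD = 0.08, n = 22
#>   expert   mean r = 0.91, SD = 0.02, n = 23
#>   t = 21.00, p = 9.999e-05 (permutation, test on Fisher-z values)
```

The expert group's node-averaged SN and CEN signals are far more strongly
coupled than the amateurs' (means on the r scale), and the permutation p
is at its floor of `1/(1 + 10000)`. Edge-wise tests localise the planted
effect across the whole matrix (every block was planted stronger in
experts here):

```r
es <- edgewise_group_test(cohort)
sum(es$significant)            # 253 of 253 edges survive FDR at q <= 0.05
table(es$class[es$significant])
#>          CEN internetwork           SN
#>           91          126           36
```

Within experts, a behavioural score correlates with a global metric at the
0.2 report threshold:

```r
ex <- cohort[cohort$group == "expert", ]
eg <- sapply(ex$ts, function(ts)
  global_efficiency(binarize(correlation_matrix(ts), 0.2)))
behavior_metric_correlation(ex$span_score, eg)
#> # A tibble: 1 × 3
#>       r p_value     n
#>   <dbl>   <dbl> <int>
#> 1 0.458  0.0279    23
```

i.e. a planted coupling of 0.5 between spatial span and internetwork
connectivity surfaces as r ≈ 0.46 with the efficiency of each expert's
graph.

The whole pipeline (cleaning → metrics over the grid → permutation,
edge-wise, internetwork and behavioural inference, all tables written as
TSV plus `report.json`) runs as one call:

```r
run_pipeline(list(synthetic = list(n_expert = 23, n_amateur = 22)),
             out_dir = "run1", seed = 1)
```

or from a shell via the thin wrapper `inst/cli/netintegrate.R`
(`Rscript inst/cli/netintegrate.R run --seed 1 --out run1`).

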