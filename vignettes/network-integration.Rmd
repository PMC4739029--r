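---
title: "Methods: graph-theoretic SN–CEN integration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretic SN-CEN integration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netintegrate)
```

# The analysis

netintegrate compares resting-state functional integration between two
groups of subjects over a fixed 23-node atlas: 9 Salience Network (SN)
nodes and 14 Central Executive Network (CEN) nodes, each a point in MNI
space. For every subject the pipeline:

1. cleans the ROI time series (drops the first 5 volumes, band-passes
   0.01–0.08 Hz, optionally regresses out a 9-column nuisance set);
2. computes the Pearson correlation `r_ij` between every pair of ROI
   signals, and its Fisher transform `z_ij = atanh(r_ij)`;
3. binarizes `r` at a threshold `T`: an undirected edge `e_ij = 1` exactly
   when `r_ij >= T` (signed comparison), over a grid of 25 thresholds from
   0.05 to 0.30;
4. evaluates six binary-graph characteristics — global efficiency
   `E_global = (1/(N(N-1))) * sum_{i != j} 1/L_ij`, connection cost
   `K_cost = sum_i K_i / (N(N-1))` (edge density), mean clustering, nodal
   degree `K_i`, nodal clustering `C_i = e_i / (K_i(K_i-1)/2)`, and nodal
   efficiency `E_i = (1/(N-1)) * sum_{j != i} 1/L_ij`, with `L_ij` the
   shortest-path hop count;
5. tests group differences by a label-permutation test (pooled t recomputed
   under random relabelings), edge-wise pooled t-tests on `z_ij` with
   Benjamini–Hochberg FDR over the 253 edges, and the internetwork
   comparison: per subject, the correlation between the node-averaged SN
   signal and the node-averaged CEN signal, tested on the z scale and
   reported on the r scale;
6. correlates behavioural scores (spatial span, 2-back reaction time) with
   graph metrics within a group (Pearson r, t-distribution p with n − 2 df).

The assumptions are those of the standard resting-state FC pipeline:
stationary second-order structure within a scan, exchangeability of
subjects under the null (for the permutation test), and approximate
normality of Fisher-z correlations across subjects (for the parametric
edge-wise t-tests; the permutation path avoids this).

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band-pass | 0.01–0.08 | Hz | conventional resting-state band; the Nyquist limit at TR = 2 s is 0.25 Hz |
| discarded volumes | 5 | volumes | scanner equilibration |
| threshold grid | 0.05–0.30, 25 steps | r | no principled single threshold exists; results are examined across the grid |
| report threshold | 0.2 | r | the single threshold used for nodal tables; computed directly (it is not a grid point, since 25 equal steps from 0.05 to 0.30 step by 0.25/24) |
| permutations | 10,000 | — | resolves p down to ~1e-4 with the add-one correction |
| alpha | 0.05 | — | two-tailed, both for permutation tests and FDR |

# What the synthetic generator emulates

`cohort_spec()` / `simulate_cohort()` generate two groups (defaults 23
"experts", 22 "amateurs"; 255 volumes at TR = 2 s) of multivariate normal
series whose correlation matrix is block-structured over the atlas:
`r_sn` within the SN block, `r_cen` within CEN, `r_inter` in the cross
block. Defaults plant the group contrast the pipeline is designed to
detect: within-network 0.6 vs 0.4 and internetwork 0.6 vs 0.3
(expert vs amateur), with white measurement noise of SD 0.5 on unit-variance
signals. Time courses are i.i.d. draws by default — correlations are
invariant to this simplification — with an optional variance-preserving
AR(1) coefficient (`ar_phi`) for probing permutation robustness, an
optional 0.005 Hz sinusoidal drift (removed by the band-pass), and an
`embed_as_volume()` path that plants each ROI's series into a 3×3×3 voxel
cube so the 27-voxel extraction step can be exercised end to end.

Two distinct "internetwork connectivity" numbers exist by design. The
manifest's *realized internetwork correlation* is the mean SN×CEN pairwise
sample correlation of the generated series; with no noise it converges to
`r_inter`. The paper-style statistic computed by
`internetwork_comparison()` — the correlation of the two *node-averaged*
signals — is systematically larger under a block model, because averaging
suppresses node-specific variance (≈0.91 vs 0.63 at the defaults). Both
behave monotonically in `r_inter`, which is what the recovery tests rely
on.

Behavioural scores: spatial span ~ 9 ± 2 blocks (expert mean 11.4), 2-back
RT ~ 620/560 ± 100 ms, accuracy 0.90 ± 0.05. The source study reports only
group t-values, not moments, so these are free choices at plausible
magnitudes. The `behav_coupling` target (default 0.5) is an
*across-subject* correlation between span and realized internetwork FC, so
it is applied at cohort assembly: realized Fisher-z values are
group-centred and standardized within the cohort, and span is built as
`rho * z_std + sqrt(1 - rho^2) * resid`, with RT receiving the opposite
sign. `simulate_subject()` draws the residuals deterministically from its
seed, so both the per-subject and the cohort contracts stay reproducible.
Seeds: one master seed; per-subject seeds are one `sample.int()` draw under
it, making any subject independently regenerable.

What the generator does *not* emulate: hemodynamics, autocorrelated
physiological noise, head motion, spatial smoothness, or registration
error. Passing tests therefore show the statistical machinery is correct
and calibrated, not that the pipeline is robust to scanner artefacts.

# Numerical choices

- **Thresholding** uses signed `r` (negative correlations never form edges
  at positive `T`); equality `r_ij = T` yields an edge. An
  `abs_threshold` switch exists for sensitivity analyses.
- **Filter realization**: 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero-phase. The normative contract is the
  pass/stop behaviour (≥90% amplitude in-band, ≤10% at half the low or
  twice the high cutoff), which the tests assert by FFT; any realization
  meeting it would do.
- **Order of cleaning steps**: filtering before nuisance regression is the
  default, with a `regress_first` switch, since the literature is split;
  with no nuisance table the regression step is skipped with a logged
  notice.
- **Graph conventions**: `C_i = 0` when `K_i < 2` (the formula is 0/0
  there); `1/L_ij = 0` for disconnected pairs (limit of an infinite path);
  mean clustering averages over all N nodes including isolated ones
  (an `eligible_only` flag averages over degree ≥ 2 nodes instead).
  Distances are breadth-first hop counts; a brute-force Floyd–Warshall /
  triple-enumeration oracle in the test suite checks every metric exactly
  on hundreds of random graphs.
- **Permutation p**: two-tailed on |t| with the add-one correction
  `p = (1 + #{|t*| >= |t_obs|}) / (1 + n_perm)`, never exactly zero;
  "significant" means `p < 0.05`. When the total number of label
  assignments is at most 20,000 the test enumerates all of them instead of
  sampling (p then has no add-one term). A tolerance of
  `1e-8 * (1 + |t_obs|)` guards the `>=` comparison against floating-point
  ties.
- **Pooled (Student) t** rather than Welch for "independent samples
  t-tests", with Welch behind a flag; the era-typical default, and the
  reference group ("expert") leads the numerator so positive t means
  expert > amateur.
- **Edge tests run on Fisher-z values** (variance stabilisation); the
  internetwork group summary is reported back on the r scale.
- **Per-threshold metric tests are uncorrected across the 25 thresholds**,
  matching the convention of presenting metric-vs-threshold curves; this
  is deliberate and logged.
- **Voxel cube centres** round half away from zero, fixing platform-
  independent extraction; cube overlap or out-of-bounds conditions are
  errors naming the ROI.
- **Indexing** is R's native 1-based row position throughout;
  `network_indices()` returns positions that coincide with the atlas's
  printed 1-based ROI numbers, avoiding an off-by-one layer.

# Problem sizes used by the tests

Unit tests run on reduced cohorts (5 + 5 subjects, 60 volumes) so the
suite stays fast; the acceptance-style checks use the full study
conditions — 23 + 22 subjects at 255 volumes for 100 planted-effect and
200 null cohorts, 500 replicates × 1,000 permutations for the calibration
check, and 200 random graphs for oracle equivalence. These sizes are the
package's own choice of a convincing-but-quick evidence base; all scale up
by changing one argument.

# Known limitations

- The atlas is a point-coordinate table; no parcellation volumes.
- Only binary graphs and the six published characteristics; no weighted
  metrics, small-world index, betweenness, or network-based statistics.
- No covariate adjustment in the group tests.
- The behavioural generator's effect sizes are free parameters, not
  calibrated to any dataset.
- `run_pipeline()`'s nuisance-regression path requires the user to supply
  aligned nuisance tables; the synthetic path has no scanner nuisances by
  construction.
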