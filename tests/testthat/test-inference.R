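test_that("pooled t statistic behaves like Student's t", {
  x <- c(1, 2, 3, 4.5)
  expect_equal(two_sample_t(x, x), 0)
  set.seed(5)
  a <- rnorm(15); b <- rnorm(12, mean = 0.4)
  expect_equal(two_sample_t(a, b),
               unname(stats::t.test(a, b, var.equal = TRUE)$statistic))
  expect_equal(two_sample_t(a, b), -two_sample_t(b, a))
  expect_equal(two_sample_t(a, b, welch = TRUE),
               unname(stats::t.test(a, b)$statistic))
  expect_error(two_sample_t(rep(1, 5), rep(1, 6)), "variance")
  expect_error(two_sample_t(1, c(2, 3)), "at least 2")
})

test_that("permutation test enumerates exhaustively on tiny samples", {
  res <- permutation_test(c(1, 2), c(10, 11))
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_perm, choose(4, 2))
  expect_equal(res$p_value, 1 / 3)  # 2 of 6 assignments reach |t_obs|
  expect_true(res$p_value > 0)

  # same seed -> identical result in Monte-Carlo mode
  x <- rnorm(12); y <- rnorm(12)
  r1 <- permutation_test(x, y, n_perm = 300, seed = 4,
                         exhaustive_limit = 10)
  r2 <- permutation_test(x, y, n_perm = 300, seed = 4,
                         exhaustive_limit = 10)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_ts, r2$null_ts)
  expect_equal(r1$method, "monte_carlo")
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_warning(permutation_test(x, y, n_perm = 50, seed = 1,
                                  exhaustive_limit = 10), "coarse")
})

test_that("null permutation p-values are uniform and calibrated", {
  set.seed(2024)
  n_rep <- 400
  pvals <- vapply(seq_len(n_rep), function(i) {
    permutation_test(rnorm(12), rnorm(12), n_perm = 300,
                     seed = sample.int(1e8, 1),
                     exhaustive_limit = 10)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
})

test_that("BH correction reproduces the step-up arithmetic", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r1$reject))                        # k = 4 satisfies 0.04 <= 0.05
  r2 <- fdr_bh(c(0.5, 0.6))
  expect_equal(r2$q, c(0.6, 0.6))
  expect_false(any(r2$reject))
  r3 <- fdr_bh(0.04)
  expect_equal(r3$q, 0.04)
  expect_true(r3$reject)

  set.seed(6)
  p <- runif(40)^2
  r <- fdr_bh(p)
  expect_true(all(r$q >= r$p))                       # q >= p always
  expect_lte(sum(r$reject), sum(p < 0.05))           # never beats uncorrected
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("edge-wise tests localise a planted SN-only group difference", {
  spec <- cohort_spec(n_expert = 12L, n_amateur = 12L, n_volumes = 200L,
                      r_sn = c(amateur = 0.2, expert = 0.7),
                      r_cen = 0.2, r_inter = 0.2,
                      noise_sd = 0, seed = 99L)
  sim <- simulate_cohort(spec)
  es <- edgewise_group_test(sim$cohort)
  expect_equal(nrow(es), 253)                        # C(23, 2) unordered pairs
  expect_setequal(unique(es$class), c("SN", "CEN", "internetwork"))
  expect_equal(sum(es$class == "SN"), choose(9, 2))
  flagged <- dplyr::filter(es, significant)
  expect_gt(nrow(flagged), 0)
  expect_gte(mean(flagged$class == "SN"), 0.8)
  # direction and sign agree with a permutation test on the same edge
  e1 <- dplyr::slice_max(es, abs(t), n = 1)
  zmat <- vapply(sim$cohort$ts,
                 function(ts) correlation_matrix(ts)$z[e1$roi_a, e1$roi_b],
                 numeric(1))
  pt_edge <- permutation_test(zmat[sim$cohort$group == "expert"],
                              zmat[sim$cohort$group == "amateur"],
                              n_perm = 500, seed = 1)
  expect_equal(sign(pt_edge$observed_t), sign(e1$t))
})

test_that("edge-wise FDR stays near the nominal level under the null", {
  spec <- cohort_spec(n_expert = 12L, n_amateur = 12L, n_volumes = 120L,
                      r_sn = 0.3, r_cen = 0.3, r_inter = 0.3,
                      noise_sd = 0.5, seed = 123L)
  sim <- simulate_cohort(spec)
  es <- edgewise_group_test(sim$cohort)
  expect_lte(sum(es$significant), ceiling(0.05 * 253))
})

test_that("internetwork comparison measures SN-CEN coupling per subject", {
  set.seed(31)
  n_t <- 400
  shared <- matrix(rep(rnorm(n_t), 23), n_t, 23) +
    matrix(rnorm(n_t * 23, sd = 1e-6), n_t, 23)
  indep <- matrix(rnorm(n_t * 23), n_t, 23)
  cohort <- manual_cohort(list(shared, indep,
                               matrix(rnorm(n_t * 23), n_t, 23),
                               matrix(rnorm(n_t * 23), n_t, 23)),
                          c("expert", "expert", "amateur", "amateur"))
  ic <- internetwork_comparison(cohort)
  subj <- tidy(ic)
  expect_equal(subj$r[1], 1, tolerance = 1e-6)       # identical averages
  # independent SN and CEN signals: |r| within ~2/sqrt(T) of zero
  expect_lt(max(abs(subj$r[-1])), 2 / sqrt(n_t) * 23 / 23 + 0.1)

  # planted difference: expert mean exceeds amateur mean, on the r scale
  sim <- simulate_cohort(tiny_spec())
  ic2 <- internetwork_comparison(sim$cohort)
  gs <- glance(ic2)
  expect_gt(gs$mean_r_expert, gs$mean_r_amateur)
  expect_true(all(abs(c(gs$mean_r_expert, gs$mean_r_amateur)) <= 1))
  ic3 <- internetwork_comparison(sim$cohort, method = "permutation",
                                 n_perm = 300, seed = 2)
  expect_equal(ic3$t, ic2$t)                          # same observed statistic
})

test_that("behaviour-metric correlation matches its closed forms", {
  score <- c(5, 7, 8, 9, 11, 12)
  expect_equal(behavior_metric_correlation(score, 2 * score + 1)$r, 1)
  set.seed(14)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(behavior_metric_correlation(a, b)$r,
               behavior_metric_correlation(b, a)$r)
  expect_equal(behavior_metric_correlation(a, b)$p_value,
               stats::cor.test(a, b)$p.value)
  expect_error(behavior_metric_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("per-metric permutation tests cover every grid point", {
  sim <- simulate_cohort(tiny_spec())
  grid <- threshold_grid(0.1, 0.3, 3)
  metrics <- purrr::map2_dfr(sim$cohort$ts, seq_len(nrow(sim$cohort)),
                             function(ts, i) {
    dplyr::mutate(metrics_over_thresholds(correlation_matrix(ts), grid),
                  subject_id = sim$cohort$subject_id[i],
                  group = sim$cohort$group[i], .before = 1)
  })
  res <- metric_permutation_tests(dplyr::filter(metrics, node == "global"),
                                  n_perm = 200, seed = 7)
  expect_equal(nrow(res), 3 * 3)                     # 3 thresholds x 3 metrics
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
  res2 <- metric_permutation_tests(dplyr::filter(metrics, node == "global"),
                                   n_perm = 200, seed = 7)
  expect_identical(res$p_value, res2$p_value)        # seeded determinism
})
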