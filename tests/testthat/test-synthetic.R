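test_that("block covariance places targets and stays positive definite", {
  spec0 <- tiny_spec(r_sn = 0, r_cen = 0, r_inter = 0)
  expect_equal(block_covariance(spec0, "expert"),
               diag(23), ignore_attr = TRUE)

  # compound symmetry: eigenvalues 1 - r and 1 + (N - 1) r
  spec_cs <- tiny_spec(r_sn = 0.5, r_cen = 0.5, r_inter = 0.5)
  sig <- block_covariance(spec_cs, "expert")
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 0.5, tolerance = 1e-10)
  expect_equal(max(ev), 1 + 22 * 0.5, tolerance = 1e-10)

  spec_g <- tiny_spec(r_inter = c(amateur = 0.3, expert = 0.6))
  atlas <- sn_cen_atlas()
  sn <- network_indices(atlas, "SN"); cen <- network_indices(atlas, "CEN")
  expect_true(all(block_covariance(spec_g, "expert")[sn, cen] == 0.6))
  expect_true(all(block_covariance(spec_g, "amateur")[sn, cen] == 0.3))
})

test_that("non-positive-definite targets trigger the eigenvalue-floor repair", {
  spec_bad <- tiny_spec(r_sn = 0, r_cen = 0, r_inter = 0.9)
  expect_warning(sig <- block_covariance(spec_bad, "expert"),
                 "positive definite")
  expect_true(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) > 0)
  expect_equal(diag(sig), rep(1, 23), ignore_attr = TRUE)
})

test_that("subject simulation is deterministic and recovers the planted covariance", {
  spec <- tiny_spec()
  a <- simulate_subject(spec, "expert", 7L)
  b <- simulate_subject(spec, "expert", 7L)
  expect_identical(a$ts, b$ts)
  expect_identical(a$behav_resid, b$behav_resid)
  c <- simulate_subject(spec, "expert", 8L)
  expect_false(identical(a$ts, c$ts))

  # law of large numbers: noiseless long series -> sample cor ~ planted matrix
  spec_lln <- cohort_spec(n_volumes = 20000L, noise_sd = 0,
                          drift_amplitude = 0, seed = 5L)
  rec <- simulate_subject(spec_lln, "expert", 11L)
  expect_lt(max(abs(cor(rec$ts) - block_covariance(spec_lln, "expert"))), 0.02)
})

test_that("mean realized internetwork FC tracks the planted cross-block target", {
  spec <- cohort_spec(noise_sd = 0, seed = 2L)  # r_inter expert 0.6
  realized <- vapply(seq_len(50), function(i) {
    simulate_subject(spec, "expert", 1000L + i)$realized_inter_r
  }, numeric(1))
  expect_lt(abs(mean(realized) - 0.6), 0.05)
})

test_that("default cohort has the study sizes and a faithful manifest round-trip", {
  spec <- cohort_spec(n_volumes = 40L, seed = 3L)
  sim <- simulate_cohort(spec)
  expect_equal(nrow(sim$cohort), 45)           # 23 experts + 22 amateurs
  expect_equal(sum(sim$cohort$group == "expert"), 23)
  expect_equal(sum(sim$cohort$group == "amateur"), 22)
  expect_equal(sim$manifest$subject_id, sim$cohort$subject_id)

  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$manifest), as.data.frame(sim$manifest))
  expect_equal(back$cohort$ts[[1]], sim$cohort$ts[[1]],
               ignore_attr = TRUE)
  expect_equal(back$spec$r_inter, sim$spec$r_inter)
})

test_that("behavioural coupling is recovered across subjects", {
  spec <- cohort_spec(n_expert = 200L, n_amateur = 0L, n_volumes = 120L,
                      behav_coupling = 0.5, seed = 17L)
  sim <- simulate_cohort(spec)
  r <- cor(sim$cohort$span_score, sim$cohort$realized_inter_r)
  expect_lt(abs(r - 0.5), 0.15)
  # reaction time couples with the opposite sign
  r_rt <- cor(sim$cohort$nback_rt, sim$cohort$realized_inter_r)
  expect_lt(r_rt, 0)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(cohort_spec(n_volumes = 10), "exceed 10")
  expect_error(cohort_spec(r_sn = 0.99), "0.95")
  expect_error(cohort_spec(behav_coupling = 1.5), "behav_coupling")
  expect_error(cohort_spec(n_expert = 0, n_amateur = 0), "at least one")
})
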