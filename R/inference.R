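# Group inference: pooled two-sample t, label-permutation tests with an
# empirical null, Benjamini-Hochberg FDR over edges, edge-wise group tests
# on Fisher-z connectivity, the SN-CEN internetwork comparison, and
# behaviour-metric correlations.

#' Pooled-variance two-sample t statistic
#'
#' Student's t with the pooled variance estimate; the numerator is
#' `mean(x) - mean(y)`. (Welch's variant is available via `welch = TRUE`.)
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param welch Use Welch's unequal-variance form instead of pooling.
#' @return The t statistic (a single number).
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 values")
  v1 <- var(x); v2 <- var(y)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (!is.finite(se) || se == 0) abort("degenerate (zero) variance in t statistic")
  (mean(x) - mean(y)) / se
}

# Pooled t for a subset assignment, from precomputed totals. v: pooled data,
# s1/q1: subset sum and sum of squares for the group of size n1.
subset_pooled_t <- function(s1, q1, n1, n2, total_sum, total_sumsq) {
  s2 <- total_sum - s1
  q2 <- total_sumsq - q1
  ss1 <- q1 - s1^2 / n1
  ss2 <- q2 - s2^2 / n2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  (s1 / n1 - s2 / n2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Label-permutation test for a two-group difference
#'
#' Computes the observed pooled t, then rebuilds it under random
#' reassignments of the group labels (preserving group sizes) to form an
#' empirical null of `n_perm` t values. The two-tailed p-value uses the
#' add-one correction `p = (1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm)`, so it
#' is never exactly zero. When the number of distinct label assignments
#' `choose(n1 + n2, n1)` is at most `exhaustive_limit`, all assignments are
#' enumerated instead and `p = #\{|t*| >= |t_obs|\} / total`.
#'
#' @param x,y Numeric vectors (combined length at least 4).
#' @param n_perm Number of random permutations (default 10,000).
#' @param seed Optional seed; the test is deterministic given it.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param exhaustive_limit Enumerate exhaustively when the total number of
#'   assignments is at most this (default 20,000).
#' @return A list of class `"perm_test"`: `observed_t`, `null_ts`,
#'   `p_value`, `significant` (`p < alpha`), `n_perm`, `method`
#'   (`"exhaustive"` or `"monte_carlo"`), `alpha`.
#' @export
permutation_test <- function(x, y, n_perm = 10000L, seed = NULL,
                             alpha = 0.05, exhaustive_limit = 20000) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n < 4) abort("need a combined sample size of at least 4")
  if (n_perm < 100) warn("n_perm < 100 gives a very coarse empirical null")
  t_obs <- two_sample_t(x, y)
  v <- c(x, y)
  total_sum <- sum(v); total_sumsq <- sum(v^2)
  tol <- 1e-8 * (1 + abs(t_obs))

  n_assign <- choose(n, n1)
  if (n_assign <= exhaustive_limit) {
    idx <- combn(n, n1)
    null_ts <- apply(idx, 2, function(i) {
      subset_pooled_t(sum(v[i]), sum(v[i]^2), n1, n2, total_sum, total_sumsq)
    })
    p <- mean(abs(null_ts) >= abs(t_obs) - tol)
    method <- "exhaustive"
    n_used <- length(null_ts)
  } else {
    draw <- function() {
      vapply(seq_len(n_perm), function(k) {
        i <- sample.int(n, n1)
        subset_pooled_t(sum(v[i]), sum(v[i]^2), n1, n2, total_sum, total_sumsq)
      }, numeric(1))
    }
    null_ts <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
    p <- (1 + sum(abs(null_ts) >= abs(t_obs) - tol)) / (1 + n_perm)
    method <- "monte_carlo"
    n_used <- n_perm
  }
  structure(
    list(observed_t = t_obs, null_ts = null_ts, p_value = p,
         significant = p < alpha, n_perm = n_used, method = method,
         alpha = alpha),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Label-permutation test (%s, %d permutations)\n",
              x$method, x$n_perm))
  cat(sprintf("  observed t = %.3f, two-tailed p = %.4g (%ssignificant at %.2g)\n",
              x$observed_t, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a vector of p-values; rejection of the largest
#' prefix `p_(k) <= k * alpha / m` is equivalent to `q <= alpha` on the
#' adjusted values. Output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A tibble with columns `p`, `q` (BH-adjusted) and `reject`.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, reject = q <= alpha)
}

# Vectorised pooled t-tests: columns of m are variables, g is a logical
# vector marking group 1. Returns list(t, p, df).
columnwise_pooled_t <- function(m, g) {
  n1 <- sum(g); n2 <- sum(!g)
  m1 <- colMeans(m[g, , drop = FALSE])
  m2 <- colMeans(m[!g, , drop = FALSE])
  v1 <- apply(m[g, , drop = FALSE], 2, var)
  v2 <- apply(m[!g, , drop = FALSE], 2, var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

# Pull z (or r) matrices out of a cohort tibble, computing connectivity on
# the fly from the ts list-column when needed.
cohort_z_matrices <- function(cohort) {
  if ("conn" %in% names(cohort)) {
    purrr::map(cohort$conn, function(c) {
      if (inherits(c, "connectivity")) c$z else as.matrix(c)
    })
  } else if ("ts" %in% names(cohort)) {
    purrr::map(cohort$ts, function(ts) correlation_matrix(ts)$z)
  } else {
    abort("cohort needs a 'conn' or 'ts' list-column")
  }
}

check_two_groups <- function(group, ref_group) {
  lv <- unique(group)
  if (length(lv) != 2) abort("cohort must contain exactly two groups")
  if (!ref_group %in% lv) ref_group <- sort(lv)[1]
  ref_group
}

#' Edge-wise group comparison with FDR correction
#'
#' For every unordered ROI pair, a pooled two-sample t-test compares the
#' Fisher-z connectivity values between groups; p-values are corrected over
#' all `N (N - 1) / 2` edges with Benjamini-Hochberg FDR. Each edge is
#' classified as intranetwork SN, intranetwork CEN, or internetwork.
#'
#' @param cohort A tibble with a `group` column and either a `conn`
#'   list-column of [correlation_matrix()] results or a `ts` list-column of
#'   time x N matrices.
#' @param atlas Atlas tibble.
#' @param alpha FDR level (default 0.05).
#' @param ref_group Group placed first in the t numerator (default
#'   `"expert"`; positive t means this group is higher).
#' @return A tibble with one row per edge: `roi_a`, `roi_b`, `class`
#'   (`"SN"`, `"CEN"`, `"internetwork"`), `mean_z_<ref>`, `mean_z_<other>`,
#'   `t`, `p`, `q`, `significant`, `direction`.
#' @export
edgewise_group_test <- function(cohort, atlas = sn_cen_atlas(), alpha = 0.05,
                                ref_group = "expert") {
  zs <- cohort_z_matrices(cohort)
  ref_group <- check_two_groups(cohort$group, ref_group)
  g <- cohort$group == ref_group
  if (sum(g) < 2 || sum(!g) < 2) abort("need at least 2 subjects per group")
  other <- setdiff(unique(cohort$group), ref_group)

  n <- nrow(atlas)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  edge_z <- t(vapply(zs, function(z) z[upper.tri(z)], numeric(nrow(ut))))

  tests <- columnwise_pooled_t(edge_z, g)
  adj <- fdr_bh(tests$p, alpha)
  net_a <- atlas$network[ut[, 1]]
  net_b <- atlas$network[ut[, 2]]
  out <- tibble(
    roi_a = atlas$abbrev[ut[, 1]],
    roi_b = atlas$abbrev[ut[, 2]],
    class = dplyr::case_when(
      net_a == "SN" & net_b == "SN" ~ "SN",
      net_a == "CEN" & net_b == "CEN" ~ "CEN",
      .default = "internetwork"
    ),
    t = tests$t, p = tests$p, q = adj$q, significant = adj$reject,
    direction = ifelse(tests$t >= 0,
                       paste0(ref_group, ">", other),
                       paste0(other, ">", ref_group))
  )
  out[[paste0("mean_z_", ref_group)]] <- colMeans(edge_z[g, , drop = FALSE])
  out[[paste0("mean_z_", other)]] <- colMeans(edge_z[!g, , drop = FALSE])
  dplyr::relocate(out, dplyr::starts_with("mean_z_"), .after = "class")
}

#' Internetwork (SN vs CEN) functional-connectivity comparison
#'
#' Per subject, the Pearson correlation between the node-averaged SN signal
#' and the node-averaged CEN signal; the group difference is tested on
#' Fisher-z values (pooled t by default, or a label-permutation test), while
#' group means and SDs are reported back on the r scale.
#'
#' @param cohort A tibble with `group` and a `ts` list-column.
#' @param atlas Atlas tibble.
#' @param method `"parametric"` (Student p from the pooled t) or
#'   `"permutation"`.
#' @param ref_group Group placed first in the t numerator (default
#'   `"expert"`).
#' @param n_perm,seed Permutation settings when `method = "permutation"`.
#' @return A list of class `"internetwork_comparison"`: `subjects` (tibble
#'   with per-subject `r` and `z`), `group_stats` (per-group mean/sd of r and
#'   n), `t`, `p_value`, `method`, `ref_group`.
#' @export
internetwork_comparison <- function(cohort, atlas = sn_cen_atlas(),
                                    method = c("parametric", "permutation"),
                                    ref_group = "expert",
                                    n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (!"ts" %in% names(cohort)) abort("cohort needs a 'ts' list-column")
  ref_group <- check_two_groups(cohort$group, ref_group)

  r <- purrr::map_dbl(cohort$ts, function(ts) {
    cor(average_network_signal(ts, atlas, "SN"),
        average_network_signal(ts, atlas, "CEN"))
  })
  z <- atanh(pmin(pmax(r, -0.999999), 0.999999))
  subjects <- tibble(subject_id = cohort$subject_id %||%
                       as.character(seq_along(r)),
                     group = cohort$group, r = r, z = z)

  x <- z[cohort$group == ref_group]
  y <- z[cohort$group != ref_group]
  if (method == "parametric") {
    t_stat <- two_sample_t(x, y)
    p <- 2 * pt(-abs(t_stat), length(x) + length(y) - 2)
  } else {
    pt_res <- permutation_test(x, y, n_perm = n_perm, seed = seed)
    t_stat <- pt_res$observed_t
    p <- pt_res$p_value
  }
  group_stats <- subjects |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = sd(.data$r),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(subjects = subjects, group_stats = group_stats, t = t_stat,
         p_value = p, method = method, ref_group = ref_group),
    class = "internetwork_comparison"
  )
}

#' @export
print.internetwork_comparison <- function(x, ...) {
  cat("Internetwork (SN-CEN) functional connectivity\n")
  gs <- x$group_stats
  for (i in seq_len(nrow(gs))) {
    cat(sprintf("  %-8s mean r = %.2f, SD = %.2f, n = %d\n",
                gs$group[i], gs$mean_r[i], gs$sd_r[i], gs$n[i]))
  }
  cat(sprintf("  t = %.2f, p = %.4g (%s, test on Fisher-z values)\n",
              x$t, x$p_value, x$method))
  invisible(x)
}

#' Correlation between a behavioural score and a network metric
#'
#' Pearson correlation with a two-tailed p-value from the t distribution
#' with n - 2 degrees of freedom; intended to be computed within one group
#' at a time.
#'
#' @param scores,values Paired numeric vectors (at least 3 pairs, neither
#'   constant).
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
behavior_metric_correlation <- function(scores, values) {
  if (length(scores) != length(values)) abort("inputs must be the same length")
  if (length(scores) < 3) abort("need at least 3 paired observations")
  if (sd(scores) == 0 || sd(values) == 0) abort("constant input")
  ct <- cor.test(scores, values, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(scores))
}

#' Permutation tests over a tidy table of per-subject metrics
#'
#' Runs [permutation_test()] separately for every `(threshold, metric,
#' node)` combination of a per-subject metric table (as produced by stacking
#' [metrics_over_thresholds()] across subjects). Tests at different
#' thresholds are reported uncorrected, matching the per-threshold
#' presentation convention.
#'
#' @param metrics A tibble with columns `subject_id`, `group`, `threshold`,
#'   `metric`, `node`, `value`.
#' @param n_perm Permutations per test.
#' @param seed Master seed; per-test seeds are derived deterministically.
#' @param alpha Two-tailed level.
#' @param ref_group Group whose mean leads the t numerator.
#' @return A tibble with one row per combination: `threshold`, `metric`,
#'   `node`, `t`, `p_value`, `significant`.
#' @export
metric_permutation_tests <- function(metrics, n_perm = 10000L, seed = 1L,
                                     alpha = 0.05, ref_group = "expert") {
  ref_group <- check_two_groups(metrics$group, ref_group)
  nested <- metrics |>
    dplyr::group_by(.data$threshold, .data$metric, .data$node) |>
    tidyr::nest() |>
    dplyr::ungroup()
  seeds <- with_local_seed(seed,
                           sample.int(.Machine$integer.max - 1L, nrow(nested)))
  res <- purrr::map2(nested$data, seeds, function(d, s) {
    x <- d$value[d$group == ref_group]
    y <- d$value[d$group != ref_group]
    if (sd(c(x, y)) == 0) {
      return(tibble(t = NA_real_, p_value = NA_real_, significant = FALSE))
    }
    pr <- permutation_test(x, y, n_perm = n_perm, seed = s, alpha = alpha)
    tibble(t = pr$observed_t, p_value = pr$p_value,
           significant = pr$significant)
  })
  dplyr::bind_cols(dplyr::select(nested, -"data"), dplyr::bind_rows(res))
}
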