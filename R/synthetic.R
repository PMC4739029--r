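# Synthetic two-group cohort generator. Subjects are i.i.d. multivariate
# normal time series with a block correlation structure over the atlas
# (within-SN, within-CEN, SN-CEN cross blocks), optional AR(1) colouring,
# slow drift and white measurement noise, plus behavioural scores coupled to
# each subject's realized internetwork connectivity.

#' Specification of a synthetic two-group cohort
#'
#' Holds every parameter of the generator. Group-dependent parameters
#' (`r_sn`, `r_cen`, `r_inter`, `span_mean`, `rt_mean`) take either a single
#' value shared by both groups or a named pair `c(amateur = , expert = )`.
#'
#' Defaults describe the study conditions the package is exercised under:
#' 23 experts vs 22 amateurs, 255 volumes at TR = 2 s, within-network
#' correlations 0.6 (expert) vs 0.4 (amateur), internetwork correlation 0.6
#' vs 0.3, white-noise SD 0.5, and a 0.5 coupling between spatial-span score
#' and realized internetwork connectivity (2-back reaction time is coupled
#' with the opposite sign).
#'
#' @param n_expert,n_amateur Group sizes.
#' @param n_volumes Time points per subject (must exceed 10).
#' @param tr_seconds Sampling interval in seconds.
#' @param r_sn,r_cen Within-network target correlations, per group.
#' @param r_inter SN-CEN cross-network target correlation, per group.
#' @param noise_sd SD of additive white measurement noise (signal SD is 1).
#' @param drift_amplitude Amplitude of an added 0.005 Hz sinusoidal drift.
#' @param ar_phi AR(1) coefficient of the latent series (0 = white).
#' @param behav_coupling Target correlation, across subjects, between
#'   spatial-span score and realized internetwork connectivity, in `[-1, 1]`.
#' @param span_mean,span_sd Spatial-span score moments (blocks).
#' @param rt_mean,rt_sd 2-back reaction-time moments (ms).
#' @param acc_mean,acc_sd 2-back accuracy moments (proportion, clamped to
#'   `[0, 1]`).
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_expert = 23L, n_amateur = 22L,
                        n_volumes = 255L, tr_seconds = 2,
                        r_sn = c(amateur = 0.4, expert = 0.6),
                        r_cen = c(amateur = 0.4, expert = 0.6),
                        r_inter = c(amateur = 0.3, expert = 0.6),
                        noise_sd = 0.5, drift_amplitude = 0, ar_phi = 0,
                        behav_coupling = 0.5,
                        span_mean = c(amateur = 9, expert = 11.4), span_sd = 2,
                        rt_mean = c(amateur = 620, expert = 560), rt_sd = 100,
                        acc_mean = 0.9, acc_sd = 0.05,
                        seed = 1L) {
  spec <- list(
    n_expert = as.integer(n_expert), n_amateur = as.integer(n_amateur),
    n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
    r_sn = unlist(r_sn), r_cen = unlist(r_cen), r_inter = unlist(r_inter),
    noise_sd = noise_sd, drift_amplitude = drift_amplitude, ar_phi = ar_phi,
    behav_coupling = behav_coupling,
    span_mean = unlist(span_mean), span_sd = span_sd,
    rt_mean = unlist(rt_mean), rt_sd = rt_sd,
    acc_mean = acc_mean, acc_sd = acc_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_expert < 0 || spec$n_amateur < 0 || spec$n_expert + spec$n_amateur < 1) {
    abort("group sizes must be non-negative with at least one subject in total")
  }
  if (spec$n_volumes <= 10) abort("n_volumes must exceed 10")
  if (spec$tr_seconds <= 0) abort("tr_seconds must be positive")
  for (nm in c("r_sn", "r_cen", "r_inter")) {
    v <- spec[[nm]]
    if (any(v < 0) || any(v > 0.95)) {
      abort(paste0(nm, " must lie in [0, 0.95]"))
    }
  }
  if (spec$noise_sd < 0) abort("noise_sd must be non-negative")
  if (spec$drift_amplitude < 0) abort("drift_amplitude must be non-negative")
  if (abs(spec$ar_phi) >= 1) abort("ar_phi must lie in (-1, 1)")
  if (abs(spec$behav_coupling) > 1) abort("behav_coupling must lie in [-1, 1]")
  invisible(spec)
}

# Resolve a possibly group-dependent parameter for one group.
group_value <- function(x, group) {
  if (length(x) == 1L) return(unname(x))
  if (is.null(names(x)) || !group %in% names(x)) {
    abort("group-dependent parameters need names 'amateur' and 'expert'")
  }
  unname(x[[group]])
}

# Run code under a temporary RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Block correlation matrix planted for one group
#'
#' Unit-diagonal matrix over the atlas nodes with `r_sn` inside the SN block,
#' `r_cen` inside the CEN block and `r_inter` in the SN x CEN cross block.
#' If the requested targets make the matrix numerically non-positive-definite
#' an eigenvalue floor is applied (with a warning) and the result rescaled to
#' unit diagonal; if that repair fails the offending parameters are reported.
#'
#' @param spec A [cohort_spec()].
#' @param group `"expert"` or `"amateur"`.
#' @param atlas Atlas tibble; defaults to the bundled one.
#' @return An N x N correlation matrix with ROI abbreviations as dimnames.
#' @export
block_covariance <- function(spec, group = c("expert", "amateur"),
                             atlas = sn_cen_atlas()) {
  group <- match.arg(group)
  validate_cohort_spec(spec)
  sn <- network_indices(atlas, "SN")
  cen <- network_indices(atlas, "CEN")
  n <- nrow(atlas)
  r_sn <- group_value(spec$r_sn, group)
  r_cen <- group_value(spec$r_cen, group)
  r_inter <- group_value(spec$r_inter, group)

  sigma <- matrix(0, n, n, dimnames = list(atlas$abbrev, atlas$abbrev))
  sigma[sn, sn] <- r_sn
  sigma[cen, cen] <- r_cen
  sigma[sn, cen] <- r_inter
  sigma[cen, sn] <- r_inter
  diag(sigma) <- 1

  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) {
    warn("planted correlation matrix is not positive definite; applying eigenvalue floor")
    vals <- pmax(ev$values, 1e-6)
    sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(sigma))
    sigma <- sigma / tcrossprod(d)
    dimnames(sigma) <- list(atlas$abbrev, atlas$abbrev)
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
      abort(sprintf(
        "cannot build a positive-definite block matrix from r_sn=%.3g, r_cen=%.3g, r_inter=%.3g",
        r_sn, r_cen, r_inter
      ))
    }
  }
  sigma
}

#' Simulate one subject's ROI time series
#'
#' Draws `n_volumes` multivariate normal samples with the group's planted
#' block correlation, optionally AR(1)-coloured (variance-preserving), adds a
#' 0.005 Hz sinusoidal drift of amplitude `drift_amplitude` (random phase per
#' ROI) and white noise of SD `noise_sd`. Behavioural residuals (standard
#' normal) are drawn here and turned into scores by [simulate_cohort()],
#' where the across-subject coupling with realized connectivity is applied.
#' Deterministic given `(spec, group, subject_seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"expert"` or `"amateur"`.
#' @param subject_seed Integer seed for this subject.
#' @param atlas Atlas tibble.
#' @return A list of class `"subject_record"` with elements `group`, `ts`
#'   (time x N matrix, ROI abbreviations as colnames), `realized_inter_r`
#'   (mean SN x CEN pairwise sample correlation of `ts`), `behav_resid`
#'   (standard-normal residuals for span/RT/accuracy) and `meta`.
#' @export
simulate_subject <- function(spec, group = c("expert", "amateur"),
                             subject_seed, atlas = sn_cen_atlas()) {
  group <- match.arg(group)
  sigma <- block_covariance(spec, group, atlas)
  n_t <- spec$n_volumes
  n_roi <- nrow(atlas)
  ru <- chol(sigma)

  with_local_seed(subject_seed, {
    z <- matrix(rnorm(n_t * n_roi), n_t, n_roi)
    if (spec$ar_phi != 0) {
      z <- apply(z, 2, function(col) {
        stats::filter(col * sqrt(1 - spec$ar_phi^2), spec$ar_phi,
                      method = "recursive")
      })
      z <- matrix(as.numeric(z), n_t, n_roi)
    }
    ts <- z %*% ru
    if (spec$drift_amplitude > 0) {
      tt <- (seq_len(n_t) - 1) * spec$tr_seconds
      phase <- runif(n_roi, 0, 2 * pi)
      drift <- spec$drift_amplitude *
        sin(outer(tt, rep(2 * pi * 0.005, n_roi)) + rep(phase, each = n_t))
      ts <- ts + drift
    }
    if (spec$noise_sd > 0) {
      ts <- ts + spec$noise_sd * matrix(rnorm(n_t * n_roi), n_t, n_roi)
    }
    colnames(ts) <- atlas$abbrev
    behav_resid <- c(span = rnorm(1), rt = rnorm(1), acc = rnorm(1))

    sn <- network_indices(atlas, "SN")
    cen <- network_indices(atlas, "CEN")
    cmat <- cor(ts)
    realized <- mean(cmat[sn, cen])

    structure(
      list(
        group = group, ts = ts,
        realized_inter_r = realized,
        behav_resid = behav_resid,
        meta = list(tr_seconds = spec$tr_seconds, n_discarded = 0L,
                    subject_seed = as.integer(subject_seed))
      ),
      class = "subject_record"
    )
  })
}

#' Simulate a full two-group cohort
#'
#' Per-subject seeds are derived from `spec$seed` by a single draw of
#' distinct integers, so the cohort is reproducible and any subject can be
#' regenerated independently via [simulate_subject()]. After all subjects are
#' generated, behavioural scores are assembled so that, across subjects, the
#' spatial-span score correlates with realized internetwork connectivity at
#' `behav_coupling` (group-centred standardization; reaction time gets the
#' opposite sign), on top of the configured group mean differences.
#'
#' @param spec A [cohort_spec()].
#' @param atlas Atlas tibble.
#' @return A list of class `"cohort_sim"` with elements `cohort` (tibble:
#'   `subject_id`, `group`, `ts` list-column, `realized_inter_r`,
#'   `realized_inter_z`, `span_score`, `nback_rt`, `nback_acc`), `manifest`
#'   (the same tibble without the `ts` column) and `spec`.
#' @export
simulate_cohort <- function(spec, atlas = sn_cen_atlas()) {
  validate_cohort_spec(spec)
  groups <- c(rep("expert", spec$n_expert), rep("amateur", spec$n_amateur))
  n <- length(groups)
  ids <- c(sprintf("expert_%02d", seq_len(spec$n_expert)),
           sprintf("amateur_%02d", seq_len(spec$n_amateur)))
  subject_seeds <- with_local_seed(spec$seed,
                                   sample.int(.Machine$integer.max - 1L, n))

  records <- purrr::map2(groups, subject_seeds,
                         function(g, s) simulate_subject(spec, g, s, atlas))

  z <- atanh(pmin(pmax(purrr::map_dbl(records, "realized_inter_r"),
                       -0.999999), 0.999999))
  zc <- z - stats::ave(z, groups)
  zstd <- if (sd(zc) > 1e-12) zc / sd(zc) else rep(0, n)

  rho <- spec$behav_coupling
  resid <- t(vapply(records, function(r) r$behav_resid, numeric(3)))
  mix <- sqrt(1 - rho^2)
  span <- vapply(groups, function(g) group_value(spec$span_mean, g), 0) +
    spec$span_sd * (rho * zstd + mix * resid[, 1])
  rt <- vapply(groups, function(g) group_value(spec$rt_mean, g), 0) +
    spec$rt_sd * (-rho * zstd + mix * resid[, 2])
  acc <- pmin(pmax(spec$acc_mean + spec$acc_sd * resid[, 3], 0), 1)

  cohort <- tibble(
    subject_id = ids,
    group = groups,
    ts = purrr::map(records, "ts"),
    realized_inter_r = purrr::map_dbl(records, "realized_inter_r"),
    realized_inter_z = z,
    span_score = span,
    nback_rt = rt,
    nback_acc = acc
  )
  structure(
    list(cohort = cohort, manifest = dplyr::select(cohort, -"ts"), spec = spec),
    class = "cohort_sim"
  )
}

#' Write a simulated cohort to a directory
#'
#' One TSV per subject (time x ROI, header = atlas abbreviations), a
#' `manifest.tsv` and the generating spec as `spec.yaml`.
#'
#' @param sim A `"cohort_sim"` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::walk2(sim$cohort$subject_id, sim$cohort$ts, function(id, ts) {
    readr::write_tsv(as_tibble(as.data.frame(ts)),
                     file.path(dir, paste0(id, ".tsv")), progress = FALSE)
  })
  readr::write_tsv(sim$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  spec_out <- lapply(unclass(sim$spec), function(x) {
    if (length(x) > 1) as.list(x) else x  # keep group names in YAML maps
  })
  yaml::write_yaml(spec_out, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Also accepts externally prepared directories: any `manifest.tsv` with
#' columns `subject_id` and `group` plus one `<subject_id>.tsv` time x ROI
#' table per row is enough.
#'
#' @param dir Directory path.
#' @return A list of class `"cohort_sim"` (element `spec` is `NULL` when no
#'   `spec.yaml` is present).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) abort("no manifest.tsv found in cohort directory")
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  if (!all(c("subject_id", "group") %in% names(manifest))) {
    abort("manifest.tsv needs at least subject_id and group columns")
  }
  ts_list <- purrr::map(manifest$subject_id, function(id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(f)) abort(paste0("missing time-series file for subject ", id))
    as.matrix(readr::read_tsv(f, show_col_types = FALSE, progress = FALSE))
  })
  cohort <- as_tibble(manifest)
  cohort$ts <- ts_list
  cohort <- dplyr::relocate(cohort, "ts", .after = "group")
  spec_path <- file.path(dir, "spec.yaml")
  spec <- NULL
  if (file.exists(spec_path)) {
    spec <- yaml::read_yaml(spec_path)
    spec <- do.call(cohort_spec, spec[setdiff(names(spec), character())])
  }
  structure(list(cohort = cohort, manifest = manifest, spec = spec),
            class = "cohort_sim")
}
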