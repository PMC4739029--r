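# End-to-end orchestration: atlas -> cohort (synthetic or from disk) ->
# preprocessing -> connectivity -> metrics over the threshold grid ->
# group inference -> TSV tables + report.json. Stage logging goes to stderr;
# result files only, so stdout stays clean.

pipeline_defaults <- function() {
  list(
    mode = "synthetic",            # synthetic | timeseries_dir | volumes_dir
    input_dir = NULL,
    atlas_path = NULL,             # NULL = bundled atlas
    synthetic = list(),            # overrides for cohort_spec()
    tr_seconds = 2,
    discard = 5L,
    bandpass = TRUE,
    low_hz = 0.01,
    high_hz = 0.08,
    preprocess_order = "filter_first",
    grid_lo = 0.05,
    grid_hi = 0.3,
    grid_steps = 25L,
    report_threshold = 0.2,
    n_perm = 10000L,
    alpha = 0.05,
    seed = 1L,
    out_dir = "netintegrate_run"
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML/JSON file path, a list, or `NULL` (all defaults). Unknown
#' keys and out-of-range values are all reported together in one error.
#'
#' @param config A path, a list of settings, or `NULL`.
#' @return A validated config list of class `"run_config"` with defaults
#'   filled in.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) abort("config must be a list, a file path, or NULL")

  defaults <- pipeline_defaults()
  problems <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    problems <- c(problems,
                  paste0("unknown keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  cfg$discard <- as.integer(cfg$discard)
  cfg$grid_steps <- as.integer(cfg$grid_steps)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg$seed <- as.integer(cfg$seed)

  if (!cfg$mode %in% c("synthetic", "timeseries_dir", "volumes_dir")) {
    problems <- c(problems, "mode must be synthetic, timeseries_dir or volumes_dir")
  }
  if (cfg$mode != "synthetic" && is.null(cfg$input_dir)) {
    problems <- c(problems, "input_dir is required unless mode is synthetic")
  }
  if (cfg$tr_seconds <= 0) problems <- c(problems, "tr_seconds must be positive")
  nyquist <- 1 / (2 * cfg$tr_seconds)
  if (cfg$bandpass && (cfg$low_hz <= 0 || cfg$low_hz >= cfg$high_hz)) {
    problems <- c(problems, "need 0 < low_hz < high_hz")
  }
  if (cfg$bandpass && cfg$high_hz >= nyquist) {
    problems <- c(problems, sprintf(
      "high_hz (%.3g) must be below the Nyquist frequency %.3g Hz",
      cfg$high_hz, nyquist))
  }
  if (cfg$discard < 0) problems <- c(problems, "discard must be non-negative")
  if (!(cfg$grid_lo < cfg$grid_hi)) problems <- c(problems, "need grid_lo < grid_hi")
  if (cfg$grid_steps < 2) problems <- c(problems, "grid_steps must be at least 2")
  if (cfg$report_threshold <= -1 || cfg$report_threshold >= 1) {
    problems <- c(problems, "report_threshold must lie in (-1, 1)")
  }
  if (is.na(cfg$n_perm) || cfg$n_perm < 1) {
    problems <- c(problems, "n_perm must be a positive integer")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) problems <- c(problems, "alpha must lie in (0, 1)")
  if (!cfg$preprocess_order %in% c("filter_first", "regress_first")) {
    problems <- c(problems, "preprocess_order must be filter_first or regress_first")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[netintegrate] ", fmt), ...))

load_pipeline_cohort <- function(cfg, atlas) {
  if (cfg$mode == "synthetic") {
    spec <- do.call(cohort_spec, utils::modifyList(cfg$synthetic,
                                                   list(seed = cfg$seed)))
    sim <- simulate_cohort(spec, atlas)
    return(sim)
  }
  if (cfg$mode == "timeseries_dir") {
    return(read_cohort(cfg$input_dir))
  }
  # volumes_dir: manifest.tsv plus one <subject_id>.nii[.gz] per subject
  manifest_path <- file.path(cfg$input_dir, "manifest.tsv")
  if (!file.exists(manifest_path)) abort("no manifest.tsv found in input_dir")
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  ts_list <- purrr::map(manifest$subject_id, function(id) {
    f <- file.path(cfg$input_dir, paste0(id, ".nii"))
    if (!file.exists(f)) f <- file.path(cfg$input_dir, paste0(id, ".nii.gz"))
    if (!file.exists(f)) abort(paste0("missing volume for subject ", id))
    v <- read_volume_nifti(f)
    extract_roi_timeseries(v$volume, v$affine, atlas)
  })
  cohort <- as_tibble(manifest)
  cohort$ts <- ts_list
  structure(list(cohort = cohort, manifest = manifest, spec = NULL),
            class = "cohort_sim")
}

#' Run the full analysis pipeline
#'
#' Executes atlas loading, cohort generation (or loading), preprocessing,
#' connectivity, graph metrics over the threshold grid, and group inference
#' (per-threshold permutation tests on global metrics, nodal tests at the
#' report threshold, edge-wise FDR-corrected tests, the internetwork
#' comparison and behaviour-metric correlations), writing every result table
#' as TSV plus a machine-readable `report.json` under the output directory.
#' Rerunning with the same config and seed reproduces every statistic.
#'
#' @param config A config list, YAML/JSON path, or `NULL` (defaults); see
#'   [validate_config()].
#' @param out_dir Optional override of the output directory.
#' @param seed Optional override of the master seed.
#' @return The run report (a list), invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    stage_log("%s done in %.2fs", stage, timings[[stage]])
    res
  }

  atlas <- clock("atlas", {
    if (is.null(cfg$atlas_path)) sn_cen_atlas() else read_atlas(cfg$atlas_path)
  })

  sim <- clock("cohort", load_pipeline_cohort(cfg, atlas))
  cohort <- sim$cohort
  stage_log("cohort: %d subjects (%s)", nrow(cohort),
            paste(sprintf("%s=%d", names(table(cohort$group)),
                          table(cohort$group)), collapse = ", "))

  cohort <- clock("preprocess", {
    cleaned <- purrr::map(cohort$ts, function(ts) {
      suppressMessages(preprocess_subject(
        ts, tr_seconds = cfg$tr_seconds, discard = cfg$discard,
        low_hz = cfg$low_hz, high_hz = cfg$high_hz, nuisance = NULL,
        order = cfg$preprocess_order, bandpass = cfg$bandpass))
    })
    stage_log("preprocess: discard %d volumes, band-pass %s (no nuisance table supplied; regression skipped)",
              cfg$discard,
              if (cfg$bandpass) sprintf("%.3g-%.3g Hz", cfg$low_hz, cfg$high_hz) else "off")
    dplyr::mutate(cohort, ts = cleaned)
  })

  cohort <- clock("connectivity", {
    dplyr::mutate(cohort, conn = purrr::map2(.data$ts, .data$subject_id,
                                             correlation_matrix))
  })

  grid <- threshold_grid(cfg$grid_lo, cfg$grid_hi, cfg$grid_steps)
  metrics <- clock("metrics", {
    purrr::map2_dfr(cohort$conn, seq_len(nrow(cohort)), function(cn, i) {
      dplyr::mutate(metrics_over_thresholds(cn, grid),
                    subject_id = cohort$subject_id[i],
                    group = cohort$group[i], .before = 1)
    })
  })
  report_metrics <- purrr::map2_dfr(cohort$conn, seq_len(nrow(cohort)),
                                    function(cn, i) {
    dplyr::mutate(graph_metrics(binarize(cn, cfg$report_threshold)),
                  subject_id = cohort$subject_id[i],
                  group = cohort$group[i], .before = 1)
  })

  seeds <- with_local_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 3))
  global_tests <- clock("global_metric_tests", {
    metric_permutation_tests(
      dplyr::filter(metrics, .data$node == "global"),
      n_perm = cfg$n_perm, seed = seeds[1], alpha = cfg$alpha)
  })
  nodal_tests <- clock("nodal_metric_tests", {
    metric_permutation_tests(
      dplyr::mutate(dplyr::filter(report_metrics, .data$node != "global"),
                    threshold = cfg$report_threshold),
      n_perm = cfg$n_perm, seed = seeds[2], alpha = cfg$alpha)
  })
  edge_stats <- clock("edgewise_tests", {
    edgewise_group_test(cohort, atlas, alpha = cfg$alpha)
  })
  internetwork <- clock("internetwork", {
    internetwork_comparison(cohort, atlas, method = "permutation",
                            n_perm = cfg$n_perm, seed = seeds[3])
  })

  behaviour <- clock("behaviour_correlations", {
    behaviour_correlation_table(cohort, report_metrics, cfg$report_threshold)
  })

  clock("write_outputs", {
    w <- function(x, f) readr::write_tsv(x, file.path(cfg$out_dir, f),
                                         progress = FALSE)
    w(atlas, "atlas.tsv")
    w(sim$manifest, "manifest.tsv")
    w(metrics, "metrics.tsv")
    w(report_metrics, "report_threshold_metrics.tsv")
    w(global_tests, "global_metric_tests.tsv")
    w(nodal_tests, "nodal_metric_tests.tsv")
    w(edge_stats, "edge_stats.tsv")
    w(tidy(internetwork), "internetwork_subjects.tsv")
    w(glance(internetwork), "internetwork_summary.tsv")
    if (nrow(behaviour) > 0) w(behaviour, "behavior_correlations.tsv")
    yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  })

  report <- list(
    package_version = as.character(utils::packageVersion("netintegrate")),
    config = unclass(cfg),
    n_subjects = nrow(cohort),
    n_thresholds = length(grid),
    n_edges = nrow(edge_stats),
    global_metric_tests = global_tests,
    nodal_metric_tests = nodal_tests,
    edge_stats = edge_stats,
    internetwork = glance(internetwork),
    behavior_correlations = behaviour,
    timings = timings
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  stage_log("report written to %s", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}

# Behaviour-metric correlations computed within each group: spatial span and
# 2-back RT against the three global metrics at the report threshold, plus
# the nodal efficiency of DLPFC_L when that node exists in the atlas.
behaviour_correlation_table <- function(cohort, report_metrics,
                                        report_threshold) {
  if (!all(c("span_score", "nback_rt") %in% names(cohort))) {
    return(tibble())
  }
  targets <- dplyr::filter(report_metrics,
                           .data$node == "global" |
                             (.data$metric == "efficiency" &
                                .data$node == "DLPFC_L"))
  wide <- tidyr::pivot_wider(targets,
                             id_cols = c("subject_id", "group"),
                             names_from = c("metric", "node"),
                             values_from = "value")
  wide <- dplyr::left_join(wide,
                           dplyr::select(cohort, "subject_id", "span_score",
                                         "nback_rt"),
                           by = "subject_id")
  metric_cols <- setdiff(names(wide),
                         c("subject_id", "group", "span_score", "nback_rt"))
  purrr::map_dfr(unique(wide$group), function(g) {
    d <- dplyr::filter(wide, .data$group == g)
    purrr::map_dfr(metric_cols, function(mc) {
      purrr::map_dfr(c("span_score", "nback_rt"), function(bh) {
        res <- tryCatch(behavior_metric_correlation(d[[bh]], d[[mc]]),
                        error = function(e) tibble(r = NA_real_,
                                                   p_value = NA_real_,
                                                   n = nrow(d)))
        dplyr::mutate(res, group = g, behaviour = bh, metric = mc,
                      threshold = report_threshold, .before = 1)
      })
    })
  })
}
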