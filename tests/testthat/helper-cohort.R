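# Shared small-cohort settings so unit tests stay fast; acceptance tests use
# the full default study conditions.

tiny_spec <- function(...) {
  cohort_spec(n_expert = 5L, n_amateur = 5L, n_volumes = 60L, seed = 101L, ...)
}

# A cohort tibble built directly from raw time-series matrices.
manual_cohort <- function(ts_list, groups) {
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(ts_list)),
    group = groups,
    ts = ts_list
  )
}
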