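# broom-style tidiers for the package's fitted objects.

#' Tidy a permutation test
#'
#' @param x A `"perm_test"` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic` (observed t) and `p.value`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$observed_t, p.value = x$p_value)
}

#' One-row summary of a permutation test
#'
#' @param x A `"perm_test"` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p.value`, `significant`,
#'   `n_perm`, `method`, `alpha`.
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$observed_t, p.value = x$p_value,
         significant = x$significant, n_perm = x$n_perm,
         method = x$method, alpha = x$alpha)
}

#' Per-subject values of an internetwork comparison
#'
#' @param x An `"internetwork_comparison"` object.
#' @param ... Unused.
#' @return A tibble with one row per subject: `subject_id`, `group`, `r`
#'   (SN-CEN correlation) and `z` (its Fisher transform).
#' @method tidy internetwork_comparison
#' @export
tidy.internetwork_comparison <- function(x, ...) {
  x$subjects
}

#' One-row summary of an internetwork comparison
#'
#' @param x An `"internetwork_comparison"` object.
#' @param ... Unused.
#' @return A one-row tibble with per-group means/SDs on the r scale, group
#'   sizes, the t statistic (on Fisher-z values) and its p-value.
#' @method glance internetwork_comparison
#' @export
glance.internetwork_comparison <- function(x, ...) {
  gs <- x$group_stats
  wide <- tidyr::pivot_wider(gs, names_from = "group",
                             values_from = c("mean_r", "sd_r", "n"))
  dplyr::mutate(wide, statistic = x$t, p.value = x$p_value,
                method = x$method)
}
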