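#' The bundled 23-node SN + CEN atlas
#'
#' Returns the region-of-interest (ROI) table used throughout the package: 23
#' point coordinates in MNI space, the first 9 belonging to the Salience
#' Network (SN: bilateral anterior/posterior insula, dACC, MFG, SMG) and the
#' remaining 14 to the Central Executive Network (CEN: parietal, frontal eye
#' field, precentral, SMA, DLPFC and ventral occipital nodes). The row order
#' of this table fixes the row/column order of every connectivity matrix and
#' binary graph downstream.
#'
#' The table is shipped as a plain TSV inside the package so users can supply
#' their own atlas with the same schema via [read_atlas()]. Area labels are
#' transcribed as printed in the source table (continuation rows inherit the
#' label of the first row of their pair).
#'
#' @return A tibble with columns `index` (1-based ROI number, display only),
#'   `network` (`"SN"` or `"CEN"`), `abbrev` (unique short label, e.g.
#'   `"aIns_L"`), `x`, `y`, `z` (MNI millimetres) and `area_name`.
#' @export
#' @examples
#' atlas <- sn_cen_atlas()
#' nrow(atlas)                   # 23
#' table(atlas$network)          # 9 SN, 14 CEN
sn_cen_atlas <- function() {
  path <- system.file("extdata", "sn_cen_atlas.tsv", package = "netintegrate",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    abort("bundled atlas file is missing from the installed package")
  }
  read_atlas(path)
}

#' Read an ROI atlas table from a TSV file
#'
#' The schema matches the bundled atlas: tab-separated with a header row and
#' columns `index`, `network`, `abbrev`, `x`, `y`, `z`, `area_name`.
#'
#' @param path Path to a TSV file.
#' @return A validated atlas tibble (see [sn_cen_atlas()]).
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(
    path,
    col_types = readr::cols(
      index = readr::col_integer(),
      network = readr::col_character(),
      abbrev = readr::col_character(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double(),
      area_name = readr::col_character()
    ),
    progress = FALSE
  )
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  required <- c("index", "network", "abbrev", "x", "y", "z", "area_name")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    abort(paste0("atlas is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(atlas) < 1) abort("atlas has no rows")
  if (anyDuplicated(atlas$index)) abort("atlas ROI indices must be unique")
  if (anyDuplicated(atlas$abbrev)) abort("atlas ROI abbreviations must be unique")
  if (!all(atlas$network %in% c("SN", "CEN"))) {
    abort("atlas network labels must be 'SN' or 'CEN'")
  }
  coords <- as.matrix(atlas[, c("x", "y", "z")])
  if (any(!is.finite(coords)) || any(abs(coords) > 90)) {
    abort("atlas MNI coordinates must be finite and within [-90, 90] mm")
  }
  invisible(atlas)
}

#' Row positions of a network's ROIs within an atlas
#'
#' @param atlas An atlas tibble, e.g. [sn_cen_atlas()].
#' @param network One of `"SN"`, `"CEN"`, `"ALL"`.
#' @return An integer vector of 1-based row positions, in atlas order. For the
#'   bundled atlas these coincide with the printed ROI numbers (1-9 SN,
#'   10-23 CEN).
#' @export
#' @examples
#' network_indices(sn_cen_atlas(), "SN")
network_indices <- function(atlas, network = c("SN", "CEN", "ALL")) {
  network <- match.arg(network)
  validate_atlas(atlas)
  if (network == "ALL") return(seq_len(nrow(atlas)))
  which(atlas$network == network)
}
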