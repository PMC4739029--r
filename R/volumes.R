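# Toy 4D volume support: embedding ROI time series into a voxel grid and
# extracting them back by 27-voxel (3x3x3) cube averaging around each ROI's
# MNI coordinate. Exercises the volume path without scanner data.

# Round half away from zero, elementwise; used for nearest-voxel centres so
# extraction is deterministic across platforms (round() would round half to
# even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Voxel-centre indices (0-based, NIfTI convention) of each atlas ROI under an
# affine mapping voxel indices to world mm.
roi_voxel_centres <- function(affine, atlas) {
  inv <- tryCatch(solve(affine), error = function(e) {
    abort("affine is not invertible")
  })
  world <- rbind(t(as.matrix(atlas[, c("x", "y", "z")])), 1)
  vox <- inv %*% world
  t(round_half_away(vox[1:3, , drop = FALSE]))
}

#' Embed ROI time series into a toy 4D volume
#'
#' Builds a voxel grid covering the atlas, writes each ROI's time course
#' into all 27 voxels of a 3x3x3 cube centred on the voxel nearest its MNI
#' coordinate, and fills the background with white noise. The returned
#' affine maps 0-based voxel indices to MNI millimetres, so
#' [extract_roi_timeseries()] recovers the input exactly.
#'
#' @param ts A time x N matrix, columns in atlas order.
#' @param atlas Atlas tibble.
#' @param voxel_size_mm Isotropic voxel size; must be small enough that no
#'   two ROI cubes overlap (1 mm works for the bundled atlas).
#' @param margin_mm Padding around the atlas bounding box.
#' @param background_sd SD of the white-noise background.
#' @param seed Optional seed for the background noise.
#' @return A list with `volume` (4D array, x,y,z,time) and `affine` (4 x 4).
#' @export
embed_as_volume <- function(ts, atlas = sn_cen_atlas(), voxel_size_mm = 1,
                            margin_mm = 4, background_sd = 1, seed = NULL) {
  ts <- as.matrix(ts)
  validate_atlas(atlas)
  if (ncol(ts) != nrow(atlas)) {
    abort("ts must have one column per atlas ROI")
  }
  if (voxel_size_mm <= 0) abort("voxel_size_mm must be positive")
  coords <- as.matrix(atlas[, c("x", "y", "z")])
  origin <- floor(apply(coords, 2, min)) - margin_mm
  extent <- ceiling(apply(coords, 2, max)) + margin_mm
  dims <- as.integer(ceiling((extent - origin) / voxel_size_mm)) + 1L

  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- origin

  centres <- roi_voxel_centres(affine, atlas)
  if (any(centres < 1) || any(centres > rep(dims - 2L, each = nrow(centres)))) {
    bad <- which(apply(centres, 1, function(v) any(v < 1) || any(v > dims - 2L)))
    abort(paste0("ROI cube out of bounds for: ",
                 paste(atlas$abbrev[bad], collapse = ", ")))
  }
  dmat <- as.matrix(stats::dist(centres, method = "maximum"))
  overlap <- which(dmat <= 2 & upper.tri(dmat), arr.ind = TRUE)
  if (nrow(overlap) > 0) {
    pair <- overlap[1, ]
    abort(sprintf(
      "ROI cubes overlap at voxel size %g mm (e.g. %s and %s); use smaller voxels",
      voxel_size_mm, atlas$abbrev[pair[1]], atlas$abbrev[pair[2]]))
  }

  n_t <- nrow(ts)
  gen <- function() array(rnorm(prod(dims) * n_t, sd = background_sd),
                          dim = c(dims, n_t))
  vol <- if (is.null(seed)) gen() else with_local_seed(seed, gen())
  for (j in seq_len(nrow(atlas))) {
    ix <- centres[j, 1] + (-1:1) + 1L  # to 1-based array indices
    iy <- centres[j, 2] + (-1:1) + 1L
    iz <- centres[j, 3] + (-1:1) + 1L
    for (t in seq_len(n_t)) vol[ix, iy, iz, t] <- ts[t, j]
  }
  list(volume = vol, affine = affine)
}

#' Extract ROI time series from a 4D volume by 27-voxel cube averaging
#'
#' For each atlas ROI the voxel nearest its MNI coordinate (under the
#' affine; ties rounded half away from zero) anchors a 3x3x3 cube whose 27
#' voxels are averaged at every time point.
#'
#' @param volume A 4D array (x, y, z, time).
#' @param affine 4 x 4 matrix mapping 0-based voxel indices to world mm.
#' @param atlas Atlas tibble.
#' @return A time x N matrix with atlas abbreviations as colnames.
#' @export
extract_roi_timeseries <- function(volume, affine, atlas = sn_cen_atlas()) {
  validate_atlas(atlas)
  dims <- dim(volume)
  if (length(dims) != 4) abort("volume must be a 4D array (x, y, z, time)")
  centres <- roi_voxel_centres(affine, atlas)
  bad <- which(apply(centres, 1, function(v) any(v < 1) || any(v > dims[1:3] - 2L)))
  if (length(bad) > 0) {
    abort(paste0("ROI cube out of bounds for: ",
                 paste(atlas$abbrev[bad], collapse = ", ")))
  }
  n_t <- dims[4]
  out <- matrix(NA_real_, n_t, nrow(atlas),
                dimnames = list(NULL, atlas$abbrev))
  for (j in seq_len(nrow(atlas))) {
    ix <- centres[j, 1] + (-1:1) + 1L
    iy <- centres[j, 2] + (-1:1) + 1L
    iz <- centres[j, 3] + (-1:1) + 1L
    cube <- volume[ix, iy, iz, , drop = FALSE]
    out[, j] <- apply(cube, 4, mean)
  }
  out
}

#' Write a toy volume as NIfTI-1
#'
#' @param embedded A list with `volume` and `affine`, as returned by
#'   [embed_as_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(embedded, path) {
  img <- RNifti::asNifti(embedded$volume)
  img <- RNifti::`sform<-`(img, structure(embedded$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its affine
#'
#' @param path Path to a NIfTI file.
#' @return A list with `volume` (4D array) and `affine` (4 x 4 matrix).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = as.array(img), affine = unclass(RNifti::xform(img)))
}
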