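#' Image volume container
#'
#' A 3D scalar field with per-axis voxel spacing in millimetres, an optional
#' cardiac phase tag (percent of the RR interval, one of 0, 10, ..., 90) and
#' an intensity state that tracks where the volume sits in the preprocessing
#' chain (`"raw_hu"`, `"clipped"` or `"normalized"`).
#'
#' @param voxels numeric 3D array.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm; all > 0.
#' @param phase optional cardiac phase percent in `seq(0, 90, 10)`.
#' @param patient_id optional opaque identifier.
#' @param intensity_state one of `"raw_hu"`, `"clipped"`, `"normalized"`.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), phase = NULL,
                         patient_id = NULL, intensity_state = "raw_hu") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  intensity_state <- match.arg(intensity_state,
                               c("raw_hu", "clipped", "normalized"))
  if (!is.null(phase)) {
    phase <- as.numeric(phase)
    if (length(phase) != 1L || !(phase %in% seq(0, 90, 10)))
      stop("`phase` must be one of 0, 10, ..., 90")
  }
  structure(list(voxels = voxels, spacing = spacing, phase = phase,
                 patient_id = patient_id, intensity_state = intensity_state),
            class = "image_volume")
}

#' Binary mask container
#'
#' A 3D logical field sharing the voxel grid and spacing of a paired
#' [image_volume()].
#'
#' @param voxels logical (or coercible 0/1) 3D array.
#' @param spacing numeric length-3 spacing in mm.
#' @param phase,patient_id optional tags, as for [image_volume()].
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), phase = NULL,
                        patient_id = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!is.logical(voxels)) {
    v <- as.numeric(voxels)
    if (any(!v %in% c(0, 1))) stop("mask voxels must be binary")
    voxels <- array(v > 0.5, dim = dim(voxels))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing, phase = phase,
                 patient_id = patient_id),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, state %s%s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$intensity_state,
              if (is.null(x$phase)) "" else sprintf(", phase %d%%", as.integer(x$phase))))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("volume and mask do not share the same grid")
  invisible(TRUE)
}

#' Region-of-interest specification
#'
#' Half-open, 0-based per-axis index intervals: a voxel (i, j, k) (0-based)
#' belongs to the ROI iff `lo[d] <= idx[d] < hi[d]` on every axis.
#'
#' @param lo,hi integer length-3 bounds, `lo < hi` per axis.
#' @param role `"signal"` or `"background"`.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(lo, hi, role = c("signal", "background")) {
  role <- match.arg(role)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L) stop("bounds must have length 3")
  if (any(lo < 0L) || any(hi <= lo)) stop("ROI bounds must satisfy 0 <= lo < hi")
  structure(list(lo = lo, hi = hi, role = role), class = "roi_spec")
}

roi_extract <- function(vol, roi) {
  d <- dim(vol$voxels)
  if (any(roi$hi > d)) stop("ROI bounds exceed the voxel grid")
  vol$voxels[(roi$lo[1] + 1L):roi$hi[1],
             (roi$lo[2] + 1L):roi$hi[2],
             (roi$lo[3] + 1L):roi$hi[3]]
}
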