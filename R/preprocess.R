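#' Preprocessing configuration
#'
#' Intensity and geometry preprocessing parameters. Clipping restricts
#' Hounsfield units to `[clip_low, clip_high]` (default \[-350, 800\] HU,
#' lung tissue to bone including the contrast-enhanced blood pool);
#' min-max normalisation then maps that fixed range affinely onto \[0, 1\],
#' so intensity meaning is consistent across patients. `target_spacing`
#' is the isotropic resampling target and `crop_margin` the number of
#' voxels kept around the mask bounding box when cropping.
#'
#' @param clip_low,clip_high HU clipping bounds, `clip_low < clip_high`.
#' @param target_spacing numeric length-3 target spacing in mm, all > 0.
#' @param crop_margin non-negative integer margin in voxels.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(clip_low = -350, clip_high = 800,
                              target_spacing = c(1, 1, 1), crop_margin = 0L) {
  if (clip_low >= clip_high) stop("clip_low must be below clip_high")
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three positive numbers")
  crop_margin <- as.integer(crop_margin)
  if (crop_margin < 0L) stop("crop_margin must be >= 0")
  structure(list(clip_low = clip_low, clip_high = clip_high,
                 target_spacing = target_spacing, crop_margin = crop_margin),
            class = "preprocess_config")
}

#' Image signal-to-noise ratio
#'
#' SNR = S / sigma with S the mean intensity inside the signal ROI (placed
#' in the contrast-enhanced left atrium) and sigma the standard deviation
#' inside a background ROI containing no signal. The *population*
#' (divide-by-n) standard deviation is used.
#'
#' @param vol an [image_volume()] in the `"raw_hu"` state.
#' @param signal_roi,noise_roi [roi_spec()] objects within the grid.
#' @return scalar SNR.
#' @export
compute_snr <- function(vol, signal_roi, noise_roi) {
  if (!inherits(vol, "image_volume")) stop("`vol` must be an image_volume")
  if (vol$intensity_state != "raw_hu")
    stop("SNR is defined on raw HU intensities")
  s <- roi_extract(vol, signal_roi)
  nz <- roi_extract(vol, noise_roi)
  sigma <- sqrt(mean((nz - mean(nz))^2))
  if (sigma == 0) stop("noise ROI has zero standard deviation")
  mean(s) / sigma
}

#' Clip Hounsfield units and min-max normalise
#'
#' Values below `clip_low` are set to `clip_low`, values above `clip_high`
#' to `clip_high`, then the fixed clipped range is mapped affinely so that
#' `clip_low` becomes 0 and `clip_high` becomes 1.
#'
#' @param vol an [image_volume()] in the `"raw_hu"` state.
#' @param cfg a [preprocess_config()].
#' @return the normalised `image_volume` (`intensity_state = "normalized"`).
#' @export
clip_and_normalize <- function(vol, cfg = preprocess_config()) {
  if (!inherits(vol, "image_volume")) stop("`vol` must be an image_volume")
  if (vol$intensity_state != "raw_hu")
    stop("input must be in the raw_hu state")
  v <- pmin(pmax(vol$voxels, cfg$clip_low), cfg$clip_high)
  vol$voxels <- array((v - cfg$clip_low) / (cfg$clip_high - cfg$clip_low),
                      dim = dim(vol$voxels))
  vol$intensity_state <- "normalized"
  vol
}

# Sample a 3D array at fractional 0-based voxel coordinates.
# order 1 = trilinear, order 0 = nearest neighbour; out-of-field -> fill.
sample_at <- function(arr, xi, yi, zi, order = 1L, fill = 0) {
  d <- dim(arr)
  if (order == 0L) {
    i <- round(xi); j <- round(yi); k <- round(zi)
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
      k >= 0 & k <= d[3] - 1
    out <- rep(fill, length(xi))
    idx <- cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)
    out[ok] <- arr[idx]
    return(out)
  }
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  out <- rep(as.numeric(fill), length(xi))
  ok <- xi >= 0 & xi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
    zi >= 0 & zi <= d[3] - 1
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  out[ok] <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x1, y1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy * fz +
    at(x1, y1, z1) * fx * fy * fz
  out
}

#' Resample to a target (isotropic) spacing
#'
#' Resamples an image (trilinear interpolation) or a mask (nearest
#' neighbour, so the output stays strictly binary) onto `target_spacing`,
#' default 1 x 1 x 1 mm. Voxel centres are aligned so the physical extent
#' is preserved to within one voxel per axis.
#'
#' @param x an [image_volume()] or [binary_mask()].
#' @param cfg a [preprocess_config()] supplying `target_spacing`.
#' @return the resampled object, same class as `x`.
#' @export
resample_iso <- function(x, cfg = preprocess_config()) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("`x` must be an image_volume or binary_mask")
  d <- dim(x$voxels)
  if (any(d < 2L)) stop("cannot resample a single-voxel axis")
  tsp <- cfg$target_spacing
  if (isTRUE(all.equal(x$spacing, tsp, tolerance = 1e-8))) return(x)
  nd <- pmax(2L, as.integer(round(d * x$spacing / tsp)))
  # output voxel-centre -> input voxel coordinate (0-based, centre-aligned)
  coord <- function(axis) ((seq_len(nd[axis]) - 1) + 0.5) *
    tsp[axis] / x$spacing[axis] - 0.5
  g <- expand.grid(x = coord(1), y = coord(2), z = coord(3))
  src <- if (is_mask) (x$voxels) * 1 else x$voxels
  v <- sample_at(src, g$x, g$y, g$z, order = if (is_mask) 0L else 1L,
                 fill = if (is_mask) 0 else min(x$voxels))
  x$voxels <- if (is_mask) array(v > 0.5, dim = nd) else array(v, dim = nd)
  x$spacing <- tsp
  x$affine <- NULL                             # geometry changed
  x
}

mask_bbox <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

#' Crop an image and mask to the mask bounding box
#'
#' Both inputs are cropped to the mask's foreground bounding box expanded
#' by `crop_margin` voxels per side and clamped to the grid.
#'
#' @param vol an [image_volume()].
#' @param mask a non-empty [binary_mask()] on the same grid.
#' @param cfg a [preprocess_config()] supplying `crop_margin`.
#' @return list with elements `vol` and `mask`, cropped.
#' @export
crop_to_mask <- function(vol, mask, cfg = preprocess_config()) {
  stopifnot_same_grid(vol, mask)
  bb <- mask_bbox(mask)
  d <- dim(vol$voxels)
  lo <- pmax(1L, bb$lo - cfg$crop_margin)
  hi <- pmin(d, bb$hi + cfg$crop_margin)
  slice <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vol$voxels <- slice(vol$voxels); vol$affine <- NULL
  mask$voxels <- slice(mask$voxels); mask$affine <- NULL
  list(vol = vol, mask = mask)
}
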