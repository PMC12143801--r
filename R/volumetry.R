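#' Mask volume in millilitres
#'
#' Foreground voxel count times the voxel volume `dx*dy*dz` (mm^3),
#' divided by 1000.
#'
#' @param mask a [binary_mask()].
#' @return volume in mL (0 for an empty mask).
#' @export
mask_volume <- function(mask) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Left-atrial volume curve over the cardiac cycle
#'
#' Computes the ten per-phase volumes and fits a periodic cubic spline
#' through them (the cycle wraps from 90% back to 0%). `lav_max` and
#' `lav_min` are taken from the ten sampled volumes, not the spline.
#'
#' @param masks list of exactly 10 [binary_mask()] objects ordered by (or
#'   tagged with) phases 0, 10, ..., 90.
#' @return object of class `volume_curve`: list with `phases`, `lav` (mL),
#'   `lav_max`, `lav_min`, and `spline`, a function of phase percent
#'   (periodic with period 100).
#' @export
volume_curve <- function(masks) {
  if (length(masks) != 10L) stop("exactly 10 phase masks are required")
  phases <- seq(0, 90, 10)
  tagged <- vapply(masks, function(m) !is.null(m$phase), logical(1))
  if (all(tagged)) {
    ph <- vapply(masks, function(m) as.numeric(m$phase), numeric(1))
    if (!setequal(ph, phases)) stop("masks must cover phases 0, 10, ..., 90")
    masks <- masks[order(ph)]
  }
  lav <- vapply(masks, mask_volume, numeric(1))
  # periodic interpolation needs the closing knot at 100% == 0%
  sp_fun <- stats::splinefun(c(phases, 100), c(lav, lav[1]),
                             method = "periodic")
  spline <- function(phase) sp_fun(phase %% 100)
  structure(list(phases = phases, lav = lav,
                 lav_max = max(lav), lav_min = min(lav), spline = spline),
            class = "volume_curve")
}

#' Left-atrial expansion index (LAEI)
#'
#' `LAEI = (LAVmax - LAVmin) / LAVmin * 100` (percent), the capacity of
#' the atrium to expand during diastole (reservoir function).
#'
#' @param curve a [volume_curve()] (or any list with `lav_max`, `lav_min`).
#' @return LAEI in percent.
#' @export
expansion_index <- function(curve) {
  if (curve$lav_min <= 0) stop("LAVmin must be positive")
  (curve$lav_max - curve$lav_min) / curve$lav_min * 100
}

#' Left-atrial emptying fraction (LAEF)
#'
#' `LAEF = (LAVmax - LAVmin) / LAVmax * 100` (percent), the proportion of
#' blood emptied from the atrium over the cycle. Algebraically
#' `LAEF = 100 * LAEI / (100 + LAEI)`.
#'
#' @param curve a [volume_curve()].
#' @return LAEF in percent.
#' @export
emptying_fraction <- function(curve) {
  if (curve$lav_max <= 0) stop("LAVmax must be positive")
  (curve$lav_max - curve$lav_min) / curve$lav_max * 100
}

# 4-connected components of a logical matrix; returns an integer label
# matrix (0 = background).
label_components_2d <- function(m) {
  d <- dim(m)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  idx <- which(m)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      i <- (q - 1L) %% d[1] + 1L
      j <- (q - 1L) %/% d[1] + 1L
      for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- i + o[1]; nj <- j + o[2]
        ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2]
        nq <- (nj[ok] - 1L) * d[1] + ni[ok]
        nq <- nq[m[nq] & lab[nq] == 0L]
        lab[nq] <- cur
        queue <- c(queue, nq)
      }
      queue <- unique(queue)
    }
  }
  lab
}

# Border pixels of a logical matrix: foreground with a background (or
# out-of-grid) 4-neighbour. Returns an n x 2 index matrix.
border_pixels_2d <- function(m) {
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  inner <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  which(m & !inner, arr.ind = TRUE)
}

#' Antero-posterior (AP) diameter
#'
#' At the phase of maximal atrial volume, selects the axial (x-y) slice
#' with the largest segmented area, keeps the largest 4-connected
#' component, extracts its border pixels and returns the maximum pairwise
#' Euclidean distance between border pixels in millimetres (using the
#' in-plane spacing).
#'
#' @param masks list of 10 phase-ordered [binary_mask()] objects (as for
#'   [volume_curve()]), or a single `binary_mask` at the maximal phase.
#' @return AP diameter in mm (0 for a single-pixel component).
#' @export
ap_diameter <- function(masks) {
  if (inherits(masks, "binary_mask")) {
    mask <- masks
  } else {
    vols <- vapply(masks, mask_volume, numeric(1))
    mask <- masks[[which.max(vols)]]
  }
  if (sum(mask$voxels) == 0L) stop("mask at the maximal phase is empty")
  areas <- apply(mask$voxels, 3, sum)
  sl <- mask$voxels[, , which.max(areas)]
  lab <- label_components_2d(sl)
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)
  bp <- border_pixels_2d(comp)
  if (nrow(bp) < 2L) return(0)
  pts <- cbind(bp[, 1] * mask$spacing[1], bp[, 2] * mask$spacing[2])
  max(stats::dist(pts))
}

#' Volumetric rhythm features for one patient
#'
#' Convenience wrapper computing the (LAEI, LAEF, AP) triple from ten
#' phase masks.
#'
#' @param masks list of 10 phase-ordered [binary_mask()] objects.
#' @return list with `laei` (%), `laef` (%), `ap` (mm) and the
#'   [volume_curve()] as `curve`.
#' @export
volumetric_features <- function(masks) {
  curve <- volume_curve(masks)
  list(laei = expansion_index(curve), laef = emptying_fraction(curve),
       ap = ap_diameter(masks), curve = curve)
}
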