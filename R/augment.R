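#' Affine augmentation configuration
#'
#' Online affine augmentation draws, per augmented copy, three in-plane
#' rotation angles (x-y, x-z, y-z planes) uniformly from
#' `[-rot_range, rot_range]` radians, three shear coefficients from
#' `[-shear_range, shear_range]`, and one relative volume change from
#' `[-scale_range, scale_range]` (the linear scale factor is its cube
#' root, so a 0.15 draw changes *volume* by 15%). `factor` copies are
#' produced per input pair and the stream is keyed by
#' `(seed, epoch, sample)` so every run is reproducible.
#'
#' @param rot_range rotation half-range in radians (default 0.2).
#' @param shear_range shear half-range, unitless (default 0.05).
#' @param scale_range relative volume-change half-range (default 0.15).
#' @param factor augmented copies per volume (default 4).
#' @param seed integer RNG seed.
#' @return an object of class `affine_augment_config`.
#' @export
affine_augment_config <- function(rot_range = 0.2, shear_range = 0.05,
                                  scale_range = 0.15, factor = 4L,
                                  seed = 1L) {
  if (rot_range < 0 || shear_range < 0 || scale_range < 0)
    stop("ranges must be >= 0")
  factor <- as.integer(factor)
  if (factor < 0L) stop("factor must be >= 0")
  structure(list(rot_range = rot_range, shear_range = shear_range,
                 scale_range = scale_range, factor = factor,
                 seed = as.integer(seed)),
            class = "affine_augment_config")
}

#' Homogeneous shear matrix
#'
#' Returns the 4x4 shear matrix whose diagonal is kept at one while the
#' off-diagonal terms couple the axes:
#' rows `(1, sx, sx*sy, 0)`, `(sy, 1, sy*sz, 0)`, `(sz, sz*sx, 1, 0)`,
#' `(0, 0, 0, 1)`.
#'
#' @param sx,sy,sz shear coefficients along x, y, z.
#' @return a 4x4 numeric matrix.
#' @export
shear_matrix <- function(sx, sy, sz) {
  matrix(c(1,  sx, sx * sy, 0,
           sy, 1,  sy * sz, 0,
           sz, sz * sx, 1,  0,
           0,  0,  0,       1),
         nrow = 4, byrow = TRUE)
}

rotation_matrix <- function(theta, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  m <- diag(4)
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  m[ax[1], ax[1]] <- cos(theta); m[ax[2], ax[2]] <- cos(theta)
  m[ax[1], ax[2]] <- -sin(theta); m[ax[2], ax[1]] <- sin(theta)
  m
}

scale_matrix <- function(s) diag(c(s, s, s, 1))

#' Apply a homogeneous affine transform to a 3D array
#'
#' The transform acts about the volume centre: an output voxel at centred
#' coordinate `p` samples the input at `solve(M) %*% p`. Out-of-field
#' voxels take `fill`.
#'
#' @param arr numeric 3D array.
#' @param M 4x4 homogeneous matrix mapping input to output coordinates.
#' @param order 1 (trilinear) or 0 (nearest neighbour).
#' @param fill out-of-field fill value.
#' @return transformed array, same dimensions.
#' @export
apply_affine <- function(arr, M, order = 1L, fill = 0) {
  d <- dim(arr)
  ctr <- (d - 1) / 2
  Minv <- solve(M)
  g <- expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                   z = seq_len(d[3]) - 1)
  p <- rbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3], 1)
  q <- Minv %*% p
  v <- sample_at(arr, q[1, ] + ctr[1], q[2, ] + ctr[2], q[3, ] + ctr[3],
                 order = order, fill = fill)
  array(v, dim = d)
}

draw_affine <- function(cfg) {
  ang <- stats::runif(3, -cfg$rot_range, cfg$rot_range)
  sh <- stats::runif(3, -cfg$shear_range, cfg$shear_range)
  dv <- stats::runif(1, -cfg$scale_range, cfg$scale_range)
  s <- (1 + dv)^(1 / 3)
  # rotation first, then shear, then scale (applied to points in that order)
  scale_matrix(s) %*% shear_matrix(sh[1], sh[2], sh[3]) %*%
    rotation_matrix(ang[1], "xy") %*% rotation_matrix(ang[2], "xz") %*%
    rotation_matrix(ang[3], "yz")
}

# Derive a 32-bit-safe stream seed from (seed, epoch, sample).
stream_seed <- function(seed, epoch, sample) {
  (as.integer(seed) * 2654435L + as.integer(epoch) * 40503L +
     as.integer(sample) * 97L) %% 2147483647L
}

#' Online affine augmentation of an image/mask pair
#'
#' Draws `cfg$factor` random composite affine transforms
#' (rotation, then shear, then scale, about the volume centre) and applies
#' each *identically* to the image (trilinear) and the mask (nearest
#' neighbour). The random stream is keyed by `(cfg$seed, epoch, sample)`,
#' so the "online" augmentation of a training run is a deterministic
#' function of the configuration.
#'
#' @param vol an [image_volume()].
#' @param mask a [binary_mask()] on the same grid.
#' @param cfg an [affine_augment_config()].
#' @param epoch,sample stream keys (default 1, 1).
#' @return a list of `cfg$factor` lists, each with elements `vol` and `mask`.
#' @export
augment_pair <- function(vol, mask, cfg = affine_augment_config(),
                         epoch = 1L, sample = 1L) {
  stopifnot_same_grid(vol, mask)
  if (cfg$factor == 0L) return(list())
  out <- vector("list", cfg$factor)
  for (i in seq_len(cfg$factor)) {
    # draw under an isolated, keyed RNG state so training RNG is untouched
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(stream_seed(cfg$seed, epoch, (sample - 1L) * cfg$factor + i))
    M <- draw_affine(cfg)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    v <- vol; m <- mask
    v$voxels <- apply_affine(vol$voxels, M, order = 1L, fill = 0)
    m$voxels <- array(apply_affine(mask$voxels * 1, M, order = 0L,
                                   fill = 0) > 0.5,
                      dim = dim(mask$voxels))
    out[[i]] <- list(vol = v, mask = m)
  }
  out
}
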