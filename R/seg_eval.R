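#' Volume-overlap segmentation metrics
#'
#' Integer-count metrics on the whole volume: Dice
#' `DS = 2|P∩GT| / (|P| + |GT|)`, precision `Pr = |P∩GT| / |P|` and recall
#' `Re = |P∩GT| / |GT|` (the latter two in percent). DS is the harmonic
#' mean of precision and recall.
#'
#' @param pred,gt [binary_mask()] objects on the same grid; not both empty.
#' @return list with `ds`, `pr`, `re` and the counts `n_pred`, `n_gt`,
#'   `n_overlap`.
#' @export
seg_metrics <- function(pred, gt) {
  stopifnot_same_grid(pred, gt)
  np <- sum(pred$voxels)
  ng <- sum(gt$voxels)
  if (np + ng == 0L) stop("both masks are empty; metrics undefined")
  ov <- sum(pred$voxels & gt$voxels)
  list(ds = 2 * ov / (np + ng),
       pr = if (np > 0) 100 * ov / np else NA_real_,
       re = if (ng > 0) 100 * ov / ng else NA_real_,
       n_pred = np, n_gt = ng, n_overlap = ov)
}

# Foreground voxels with at least one background 6-neighbour (or on the
# grid boundary). Returns an n x 3 matrix of 1-based indices.
surface_voxels <- function(mask) {
  m <- mask$voxels
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  which(core & !nb, arr.ind = TRUE)
}

# Minimum distance from each row of `a` to the rows of `b` (mm), chunked
# to bound memory.
min_dists <- function(a, b, chunk = 2048L) {
  n <- nrow(a)
  out <- numeric(n)
  bt <- t(b)
  b2 <- colSums(bt^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ac <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ac^2), b2, "+") - 2 * ac %*% bt
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Signed node-to-node surface distances
#'
#' For every surface node of the predicted mask (centres of foreground
#' voxels with a background 6-neighbour), the distance in millimetres to
#' the nearest ground-truth surface node. The sign is positive where the
#' predicted node lies outside the ground-truth mask (overestimation) and
#' negative where it lies inside (underestimation).
#'
#' @param pred,gt non-empty [binary_mask()] objects with equal spacing.
#' @return object of class `surface_distance_map`: list with `nodes`
#'   (n x 3 mm coordinates) and `signed_error` (mm per node).
#' @export
surface_distance <- function(pred, gt) {
  if (sum(pred$voxels) == 0L || sum(gt$voxels) == 0L)
    stop("surface distances require non-empty masks")
  if (!isTRUE(all.equal(pred$spacing, gt$spacing, tolerance = 1e-8)))
    stop("masks must share voxel spacing")
  sp <- pred$spacing
  pv <- surface_voxels(pred)
  gv <- surface_voxels(gt)
  pmm <- sweep(pv - 1, 2, sp, `*`)
  gmm <- sweep(gv - 1, 2, sp, `*`)
  d <- min_dists(pmm, gmm)
  inside <- gt$voxels[pv]
  structure(list(nodes = pmm, signed_error = ifelse(inside, -d, d)),
            class = "surface_distance_map")
}

#' Histogram of signed surface errors
#'
#' Bins the node-to-node errors of a [surface_distance()] map; counts sum
#' to the node count.
#'
#' @param map a `surface_distance_map`.
#' @param bin_width bin width in mm, > 0.
#' @return list with `breaks` (bin edges, mm) and `counts`.
#' @export
error_histogram <- function(map, bin_width = 0.5) {
  if (!inherits(map, "surface_distance_map")) stop("not a surface_distance_map")
  if (bin_width <= 0) stop("bin width must be positive")
  e <- map$signed_error
  if (length(e) == 0L) stop("empty distance map")
  lo <- floor(min(e) / bin_width) * bin_width
  hi <- ceiling(max(e) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  bin <- findInterval(e, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  list(breaks = breaks, counts = counts)
}
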