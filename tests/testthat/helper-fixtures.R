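# Shared fixtures, all generated in code.

# Digitised sphere mask of radius r_mm centred in the grid.
sphere_mask <- function(r_mm, spacing = c(1, 1, 1), dimv = NULL,
                        ctr_off = c(0, 0, 0)) {
  if (is.null(dimv)) dimv <- as.integer(ceiling(2 * (r_mm + 4) / spacing))
  ctr <- (dimv - 1) / 2 * spacing + ctr_off
  xs <- (seq_len(dimv[1]) - 1) * spacing[1]
  ys <- (seq_len(dimv[2]) - 1) * spacing[2]
  zs <- (seq_len(dimv[3]) - 1) * spacing[3]
  m <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
             (zs - ctr[3])^2, "+") <= r_mm^2
  binary_mask(m, spacing = spacing)
}

# Small 32^3 phantom configuration used for training-scale tests.
phantom32_config <- function(seed, vmin = 2.2, vmax = 3.4) {
  phantom_config(shape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                 atrium = c(7, 8, 9), appendage = c(3, 3, 4),
                 volume_program = sr_volume_program(vmin, vmax),
                 seed = seed)
}

# Normalised volume + mask pair from one phase of a 32^3 phantom.
phantom32_pair <- function(seed, phase_idx) {
  s <- make_phase_series(phantom32_config(seed))[[phase_idx]]
  list(vol = clip_and_normalize(s$vol), mask = s$mask)
}

# Nested-list accessors for parameter trees (used by gradient checks).
get_at <- function(p, path) {
  for (k in path) p <- p[[k]]
  p
}
set_at <- function(p, path, v) {
  if (length(path) == 1L) {
    p[[path[[1]]]] <- v
    return(p)
  }
  p[[path[[1]]]] <- set_at(p[[path[[1]]]], path[-1], v)
  p
}

# Well-separated synthetic rhythm features: AF-like cluster (low LAEI/LAEF,
# high AP) vs SR-like cluster, >= 3 pooled SD apart on every axis.
separated_rhythm_config <- function(seed = 1L) {
  rhythm_sim_config(n_af = 22L, n_sr = 11L,
                    af_mean = c(laei = 12, laef = 10.7, ap = 92),
                    sr_mean = c(laei = 70, laef = 41.2, ap = 74),
                    af_cov = diag(c(4, 3, 3)^2),
                    sr_cov = diag(c(12, 5, 3)^2),
                    seed = seed)
}
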