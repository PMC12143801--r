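test_that("mask_volume converts voxel counts to millilitres", {
  a <- array(FALSE, dim = c(20, 20, 5))
  a[seq_len(1000)] <- TRUE
  expect_equal(mask_volume(binary_mask(a, spacing = c(1, 1, 1))), 1.0)
  expect_equal(mask_volume(binary_mask(a, spacing = c(0.45, 0.45, 1))),
               0.2025)
  expect_equal(mask_volume(binary_mask(array(FALSE, dim = c(4, 4, 4)))), 0)
  sph <- sphere_mask(12)
  vref <- 4 / 3 * pi * 12^3 / 1000
  expect_lt(abs(mask_volume(sph) - vref) / vref, 0.05)
})

test_that("volume_curve interpolates the ten volumes periodically", {
  flat <- replicate(10, sphere_mask(5, dimv = c(16, 16, 16)),
                    simplify = FALSE)
  vc <- volume_curve(flat)
  expect_equal(vc$lav_max, vc$lav_min)
  expect_equal(vc$spline(c(5, 37, 91)), rep(vc$lav[1], 3), tolerance = 1e-9)

  # knots reproduced exactly; cycle wraps (value at 100 == value at 0)
  prog <- sr_volume_program(4, 8)
  cfgp <- phantom_config(shape = c(48L, 48L, 40L), spacing = c(1, 1, 1),
                         atrium = c(9, 10, 11), appendage = c(4, 4, 4),
                         volume_program = prog, seed = 2)
  masks <- lapply(make_phase_series(cfgp), `[[`, "mask")
  vc2 <- volume_curve(masks)
  expect_equal(vc2$spline(seq(0, 90, 10)), vc2$lav, tolerance = 1e-9)
  expect_equal(vc2$spline(100), vc2$lav[1], tolerance = 1e-9)
  # recovered curve matches the programmed volumes within 5% at the knots
  expect_true(all(abs(vc2$lav - prog) / prog < 0.05))

  expect_error(volume_curve(flat[1:9]), "10")
})

test_that("expansion index and emptying fraction follow their formulas", {
  curve <- list(lav_max = 180, lav_min = 90)
  expect_equal(expansion_index(curve), 100)
  expect_equal(emptying_fraction(curve), 50)
  flat <- list(lav_max = 120, lav_min = 120)
  expect_equal(expansion_index(flat), 0)
  expect_equal(emptying_fraction(flat), 0)
  expect_error(expansion_index(list(lav_max = 1, lav_min = 0)), "LAVmin")
  expect_error(emptying_fraction(list(lav_max = 0, lav_min = 0)), "LAVmax")
  set.seed(4)
  for (i in 1:50) {
    v <- sort(runif(2, 1, 300))
    cu <- list(lav_max = v[2], lav_min = v[1])
    laei <- expansion_index(cu)
    laef <- emptying_fraction(cu)
    expect_equal(laei, (v[2] - v[1]) / v[1] * 100, tolerance = 1e-12)
    # algebraic identity LAEF = 100 * LAEI / (100 + LAEI)
    expect_equal(laef, 100 * laei / (100 + laei), tolerance = 1e-9)
    if (v[2] > v[1]) expect_lt(laef, laei)
  }
})

test_that("ap_diameter measures the set diameter of the border pixels", {
  # digitised disc of radius 10 voxels at 1 mm -> 20 +/- 1 mm
  disc <- array(FALSE, dim = c(32, 32, 5))
  for (i in 1:32) for (j in 1:32)
    if ((i - 16)^2 + (j - 16)^2 <= 100) disc[i, j, 3] <- TRUE
  dm <- binary_mask(disc)
  ap <- ap_diameter(dm)
  expect_lt(abs(ap - 20), 1)
  # brute-force all-pairs oracle over every foreground pixel
  oracle <- max(stats::dist(which(disc[, , 3], arr.ind = TRUE)))
  expect_equal(ap, oracle, tolerance = 1e-9)

  # ellipse semi-axes 20/10 mm -> 40 +/- 1 mm, invariant to 90-deg rotation
  ell <- array(FALSE, dim = c(56, 56, 3))
  for (i in 1:56) for (j in 1:56)
    if (((i - 28) / 20)^2 + ((j - 28) / 10)^2 <= 1) ell[i, j, 2] <- TRUE
  em <- binary_mask(ell)
  expect_lt(abs(ap_diameter(em) - 40), 1)
  rot <- binary_mask(aperm(ell, c(2, 1, 3)))
  expect_equal(ap_diameter(rot), ap_diameter(em), tolerance = 1e-9)

  # translation invariance and monotonicity under dilation
  shifted <- array(FALSE, dim = c(32, 32, 5))
  shifted[, , 4] <- disc[c(27:32, 1:26), , 3]
  expect_equal(ap_diameter(binary_mask(shifted)), ap, tolerance = 1e-9)
  grown <- array(FALSE, dim = c(32, 32, 5))
  for (i in 1:32) for (j in 1:32)
    if ((i - 16)^2 + (j - 16)^2 <= 144) grown[i, j, 3] <- TRUE
  expect_gte(ap_diameter(binary_mask(grown)), ap)

  # stray voxels are suppressed by the largest-component rule
  noisy <- disc
  noisy[1, 1, 3] <- TRUE
  expect_equal(ap_diameter(binary_mask(noisy)), ap, tolerance = 1e-9)

  # single-voxel slice -> 0 mm
  single <- array(FALSE, dim = c(8, 8, 3))
  single[4, 4, 2] <- TRUE
  expect_equal(ap_diameter(binary_mask(single)), 0)
  expect_error(ap_diameter(binary_mask(array(FALSE, dim = c(8, 8, 3)))),
               "empty")
})

test_that("ap_diameter picks the maximal-volume phase", {
  masks <- lapply(seq(0, 90, 10), function(ph) {
    r <- if (ph == 40) 10 else 6
    m <- sphere_mask(r, dimv = c(32, 32, 32))
    m$phase <- ph
    m
  })
  expect_lt(abs(ap_diameter(masks) - 20), 1.5)
})
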