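test_that("NIfTI round-trip preserves values, spacing and voxel sums", {
  tmp <- withr::local_tempdir()
  arr <- array(rep(7, 4 * 4 * 4), dim = c(4, 4, 4))
  v <- image_volume(arr, spacing = c(0.45, 0.45, 1))
  p <- file.path(tmp, "const.nii.gz")
  write_nifti(v, p)
  v2 <- read_nifti(p)
  expect_identical(v2$voxels, arr)
  # pixdim is float32 in the NIfTI-1 header
  expect_equal(v2$spacing, c(0.45, 0.45, 1), tolerance = 1e-6)
  expect_identical(v2$intensity_state, "raw_hu")

  # phantom volume round-trip: float32 payload, but integral HU values
  # survive exactly, so the voxel sum is preserved exactly
  ph <- make_phase_series(phantom32_config(3))[[1]]
  vol <- ph$vol
  vol$voxels <- round(vol$voxels)
  p2 <- file.path(tmp, "phantom.nii.gz")
  write_nifti(vol, p2)
  expect_identical(sum(read_nifti(p2)$voxels), sum(vol$voxels))

  # masks round-trip exactly as uint8
  p3 <- file.path(tmp, "mask.nii")
  write_nifti(ph$mask, p3)
  expect_identical(read_nifti(p3, mask = TRUE)$voxels, ph$mask$voxels)
})

test_that("read_nifti rejects missing files and non-3D payloads", {
  expect_error(read_nifti(file.path(tempdir(), "nope.nii")), "not found")
  # craft a 2D payload by patching dim[0] and dim[3] in a valid header
  tmp <- withr::local_tempfile(fileext = ".nii")
  write_nifti(image_volume(array(0, dim = c(4, 4, 1))), tmp)
  raw <- readBin(tmp, "raw", file.size(tmp))
  con <- rawConnection(raw(0), "w")
  writeBin(c(2L, 4L, 4L), con, size = 2, endian = "little")
  patch <- rawConnectionValue(con)
  close(con)
  raw[41:46] <- patch                     # dim[0:2] at byte offset 40
  raw[47:48] <- as.raw(c(0, 0))           # dim[3] = 0
  writeBin(raw, tmp)
  expect_error(read_nifti(tmp), "not 3D|invalid")
})

test_that("compute_snr follows the mean/population-SD quotient", {
  arr <- array(0, dim = c(10, 10, 4))
  arr[1:4, 1:4, ] <- 10                            # signal block
  noise_vals <- rep(c(-2, 2), length.out = 4 * 4 * 4)
  arr[7:10, 7:10, ] <- noise_vals                  # sd exactly 2
  vol <- image_volume(arr)
  sig <- roi_spec(c(0, 0, 0), c(4, 4, 4), "signal")
  noi <- roi_spec(c(6, 6, 0), c(10, 10, 4), "background")
  expect_equal(compute_snr(vol, sig, noi), 5.0)

  # constant background -> division-by-zero guard
  flat <- image_volume(array(3, dim = c(10, 10, 4)))
  expect_error(compute_snr(flat, sig, noi), "zero standard deviation")

  # random ROIs match an independent mean/population-sd computation
  set.seed(11)
  rnd <- image_volume(array(rnorm(8^3, 50, 12), dim = c(8, 8, 8)))
  s <- roi_spec(c(0, 0, 0), c(4, 8, 8), "signal")
  nz <- roi_spec(c(4, 0, 0), c(8, 8, 8), "background")
  a <- rnd$voxels[1:4, , ]
  b <- rnd$voxels[5:8, , ]
  oracle <- mean(a) / sqrt(sum((b - mean(b))^2) / length(b))
  expect_equal(compute_snr(rnd, s, nz), oracle, tolerance = 1e-12)
})

test_that("clip_and_normalize maps the fixed HU range onto [0, 1]", {
  arr <- array(c(-1000, 800, 225, rep(0, 24 - 3)), dim = c(3, 4, 2))
  out <- clip_and_normalize(image_volume(arr))
  expect_equal(out$voxels[1], 0)
  expect_equal(out$voxels[2], 1)
  expect_equal(out$voxels[3], 0.5)
  expect_identical(out$intensity_state, "normalized")
  expect_error(clip_and_normalize(out), "raw_hu")

  # property: range and monotonicity against a brute-force mapping
  set.seed(5)
  x <- array(rnorm(6^3, 200, 700), dim = c(6, 6, 6))
  y <- clip_and_normalize(image_volume(x))$voxels
  expect_true(min(y) >= 0 && max(y) <= 1)
  ref <- (pmin(pmax(as.numeric(x), -350), 800) + 350) / 1150
  expect_equal(as.numeric(y), ref, tolerance = 1e-12)
  o <- order(x)
  expect_true(all(diff(y[o]) >= -1e-12))
})

test_that("resample_iso preserves geometry and keeps masks binary", {
  iso <- image_volume(array(rnorm(10^3), dim = c(10, 10, 10)),
                      spacing = c(1, 1, 1))
  expect_identical(resample_iso(iso), iso)

  half <- binary_mask(array(TRUE, dim = c(20, 20, 20)),
                      spacing = c(0.5, 0.5, 0.5))
  out <- resample_iso(half)
  expect_identical(dim(out$voxels), c(10L, 10L, 10L))
  expect_equal(out$spacing, c(1, 1, 1))
  expect_type(out$voxels, "logical")

  # sphere volume conserved within 5% against the analytic oracle
  sph <- sphere_mask(8, spacing = c(0.5, 0.5, 0.5))
  res <- resample_iso(sph)
  expect_lt(abs(mask_volume(res) - mask_volume(sph)) / mask_volume(sph), 0.05)
  expect_lt(abs(mask_volume(res) * 1000 - 4 / 3 * pi * 8^3) /
              (4 / 3 * pi * 8^3), 0.05)

  one <- image_volume(array(0, dim = c(1, 5, 5)))
  expect_error(resample_iso(one, preprocess_config(target_spacing = 2)),
               "single-voxel")
})

test_that("crop_to_mask crops to the bounding box plus margin", {
  vol <- image_volume(array(rnorm(8^3), dim = c(8, 8, 8)))
  full <- binary_mask(array(TRUE, dim = c(8, 8, 8)))
  cr <- crop_to_mask(vol, full)
  expect_identical(cr$vol$voxels, vol$voxels)

  single <- array(FALSE, dim = c(9, 9, 9))
  single[5, 5, 5] <- TRUE
  cr2 <- crop_to_mask(vol = image_volume(array(0, dim = c(9, 9, 9))),
                      mask = binary_mask(single),
                      cfg = preprocess_config(crop_margin = 2L))
  expect_identical(dim(cr2$vol$voxels), c(5L, 5L, 5L))

  set.seed(8)
  blobs <- array(runif(10^3) > 0.8, dim = c(10, 10, 10))
  mb <- binary_mask(blobs)
  cr3 <- crop_to_mask(image_volume(array(0, dim = c(10, 10, 10))), mb)
  expect_identical(sum(cr3$mask$voxels), sum(blobs))

  empty <- binary_mask(array(FALSE, dim = c(8, 8, 8)))
  expect_error(crop_to_mask(vol, empty), "empty")
})

test_that("SNR is shift-invariant in the noise ROI and linear in signal", {
  set.seed(2)
  arr <- array(rnorm(8^3, 100, 10), dim = c(8, 8, 8))
  vol <- image_volume(arr)
  s <- roi_spec(c(0, 0, 0), c(4, 8, 8), "signal")
  nz <- roi_spec(c(4, 0, 0), c(8, 8, 8), "background")
  base <- compute_snr(vol, s, nz)
  shifted <- vol
  shifted$voxels[5:8, , ] <- shifted$voxels[5:8, , ] + 57
  expect_equal(compute_snr(shifted, s, nz), base, tolerance = 1e-10)
  scaled <- vol
  scaled$voxels[1:4, , ] <- scaled$voxels[1:4, , ] * 3
  expect_equal(compute_snr(scaled, s, nz), 3 * base, tolerance = 1e-10)
})
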