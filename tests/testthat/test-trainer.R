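# Independent elementwise-sum oracle for the two-class soft Dice loss.
dice_loss_oracle <- function(p, r, eps) {
  num_fg <- 0; den_fg <- 0; num_bg <- 0; den_bg <- 0
  for (n in seq_along(p)) {
    num_fg <- num_fg + p[n] * r[n]
    den_fg <- den_fg + p[n] + r[n]
    num_bg <- num_bg + (1 - p[n]) * (1 - r[n])
    den_bg <- den_bg + 2 - p[n] - r[n]
  }
  1 - (num_fg + eps) / (den_fg + eps) - (num_bg + eps) / (den_bg + eps)
}

test_that("dice_loss matches its forced values and the sum oracle", {
  r <- array(0, dim = c(3, 3, 3))
  r[1:2, 1:2, 1:2] <- 1                       # 8 foreground of 27
  expect_lt(abs(dice_loss(r, r, eps = 1e-5)), 1e-4)
  expect_lt(abs(dice_loss(1 - r, r, eps = 1e-5) - 1), 1e-4)
  set.seed(14)
  for (i in 1:30) {
    p <- array(runif(27), dim = c(3, 3, 3))
    rr <- array(as.numeric(runif(27) > 0.5), dim = c(3, 3, 3))
    expect_equal(dice_loss(p, rr),
                 dice_loss_oracle(as.numeric(p), as.numeric(rr), 1e-5),
                 tolerance = 1e-12)
    # foreground/background symmetry
    expect_equal(dice_loss(p, rr), dice_loss(1 - p, 1 - rr),
                 tolerance = 1e-12)
    # range (-0.5 - delta, 1 + delta]
    expect_gt(dice_loss(p, rr), -0.5 - 1e-3)
    expect_lte(dice_loss(p, rr), 1 + 1e-3)
  }
  # degenerate both-empty case scores about -0.5 under the printed form
  z <- array(0, dim = c(3, 3, 3))
  expect_equal(dice_loss(z, z), -0.5, tolerance = 1e-3)
  # conventional variant is 0 at perfect overlap
  expect_lt(abs(dice_loss(r, r, strict = FALSE)), 2e-4)
  expect_error(dice_loss(array(0, c(2, 2, 2)), r), "mismatch")
})

test_that("dice_loss gradient matches finite differences", {
  set.seed(3)
  p <- array(runif(27, 0.05, 0.95), dim = c(3, 3, 3))
  r <- array(as.numeric(runif(27) > 0.5), dim = c(3, 3, 3))
  g <- lacycle:::dice_loss_grad(p, r)
  h <- 1e-6
  for (i in c(1L, 9L, 27L)) {
    pp <- p; pp[i] <- p[i] + h
    pm <- p; pm[i] <- p[i] - h
    num <- (dice_loss(pp, r) - dice_loss(pm, r)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("build_phase_folds reproduces the published fold table", {
  folds <- build_phase_folds()
  expect_identical(folds[[1]]$train, c(10, 20, 30, 60, 70, 80))
  expect_identical(folds[[1]]$val, c(40, 90))
  expect_identical(folds[[1]]$test, c(0, 50))
  expect_identical(folds[[2]], list(train = c(20, 30, 40, 70, 80, 90),
                                    val = c(0, 50), test = c(10, 60)))
  expect_identical(folds[[3]]$test, c(20, 70))
  expect_identical(folds[[3]]$val, c(10, 60))
  expect_identical(folds[[4]], list(train = c(0, 10, 40, 50, 60, 90),
                                    val = c(20, 70), test = c(30, 80)))
  expect_identical(folds[[5]], list(train = c(0, 10, 20, 50, 60, 70),
                                    val = c(30, 80), test = c(40, 90)))
  for (f in folds) {
    expect_setequal(c(f$train, f$val, f$test), seq(0, 90, 10))
    expect_length(f$train, 6L)
    expect_length(f$val, 2L)
    expect_length(f$test, 2L)
    expect_identical(diff(f$test), 50)
  }
  # invariant to input ordering
  expect_identical(build_phase_folds(sample(seq(0, 90, 10))), folds)
  expect_error(build_phase_folds(seq(0, 80, 10)), "0, 10")
})

test_that("split_patients yields reproducible 36/12/12 patient splits", {
  ids <- sprintf("pt%02d", 1:60)
  for (fold in c(1L, 4L)) {
    sp <- split_patients(ids, fold, seed = 9)
    expect_length(sp$train, 36L)
    expect_length(sp$val, 12L)
    expect_length(sp$test, 12L)
    expect_setequal(c(sp$train, sp$val, sp$test), ids)
    expect_identical(lengths(sp$test_phase_assignment),
                     stats::setNames(c(6L, 6L),
                                     names(sp$test_phase_assignment)))
    expect_setequal(names(sp$test_phase_assignment),
                    as.character(build_phase_folds()[[fold]]$test))
    expect_identical(sp, split_patients(ids, fold, seed = 9))
  }
  expect_false(identical(split_patients(ids, 1L, seed = 1),
                         split_patients(ids, 1L, seed = 2)))
  expect_error(split_patients(ids[1:59], 1L), "60")
})

test_that("early stopping fires after `patience` stagnant epochs", {
  # with lr = 0 no parameter ever changes, so the validation loss is
  # constant: the first epoch is 'best' and training must stop at
  # patience + 1 epochs
  net <- build_resunet(resunet_config(depth = 1L, base_features = 2L),
                       seed = 8)
  pair <- list(vol = image_volume(array(runif(8^3), dim = c(8, 8, 8)),
                                  intensity_state = "normalized"),
               mask = sphere_mask(2.5, dimv = c(8, 8, 8)))
  cfg <- train_config(lr = 0, epochs_max = 50L, patience = 3L,
                      augmentation_factor = 0L)
  res <- train_fold(net, list(pair), list(pair), cfg)
  expect_identical(res$best_epoch, 1L)
  expect_identical(res$stop_epoch, 4L)
  expect_identical(nrow(res$log), 4L)
  expect_true(all(res$log$epoch == seq_len(4)))
  expect_error(train_fold(net, list(), list(pair), cfg), "empty")
})

test_that("the segmenter fits a tiny separable phantom", {
  net <- build_resunet(resunet_config(depth = 2L, base_features = 4L),
                       seed = 21)
  mask <- sphere_mask(4.5, dimv = c(16, 16, 16))
  vol <- image_volume(mask$voxels * 0.7 + 0.15,
                      intensity_state = "normalized")
  cfg <- train_config(lr = 3e-3, epochs_max = 60L, patience = 59L,
                      augmentation_factor = 0L, seed = 5,
                      target_train_loss = 0.05)
  res <- train_fold(net, list(list(vol = vol, mask = mask)), list(),
                    cfg = cfg)
  expect_lt(utils::tail(res$log$t_loss, 1), 0.35)
  expect_lt(utils::tail(res$log$t_loss, 1), res$log$t_loss[1])
  # 1 - Dice of the binarised prediction tracks the loss near convergence
  pm <- predict_mask(res$net, vol)
  ds <- seg_metrics(pm, mask)$ds
  expect_lt(abs((1 - ds) - utils::tail(res$log$t_loss, 1)), 0.35)
})

test_that("training is bitwise reproducible for a fixed seed", {
  run <- function() {
    net <- build_resunet(resunet_config(depth = 1L, base_features = 2L),
                         seed = 13)
    pair <- list(vol = image_volume(array(runif(8^3), dim = c(8, 8, 8)),
                                    intensity_state = "normalized"),
                 mask = sphere_mask(2.5, dimv = c(8, 8, 8)))
    cfg <- train_config(epochs_max = 21L, patience = 20L,
                        augmentation_factor = 2L, seed = 13)
    set.seed(99)
    train_fold(net, list(pair), list(pair), cfg,
               augment_cfg = affine_augment_config(seed = 13))
  }
  a <- run()
  b <- run()
  expect_identical(a$log, b$log)
  expect_identical(a$net$params, b$net$params)
})
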