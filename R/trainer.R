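#' Training configuration
#'
#' Optimiser and schedule settings: Adam with learning rate 1e-4 and decay
#' rates (0.9, 0.999), up to 500 epochs with early stopping after 20
#' epochs without validation-loss improvement, Dice-loss stabiliser
#' `epsilon_dice = 1e-5`, augmentation factor 4, batch size 1.
#'
#' @param lr learning rate.
#' @param beta1,beta2 Adam decay rates.
#' @param epochs_max maximum epochs.
#' @param patience early-stopping patience in epochs; must be below
#'   `epochs_max`.
#' @param epsilon_dice Dice-loss stabiliser, > 0.
#' @param augmentation_factor online augmented copies per volume (0
#'   disables augmentation).
#' @param seed integer seed governing initialisation and augmentation.
#' @param strict_eq6 use the two-class Dice loss exactly as printed (no
#'   factor 2 on the per-class ratios); see [dice_loss()].
#' @param target_train_loss optional early exit once the epoch-mean
#'   training loss falls below this value (useful to stay inside a compute
#'   budget on phantom data; `NULL` disables it).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epochs_max = 500L, patience = 20L,
                         epsilon_dice = 1e-5, augmentation_factor = 4L,
                         seed = 1L, strict_eq6 = TRUE,
                         target_train_loss = NULL) {
  if (epsilon_dice <= 0) stop("epsilon_dice must be > 0")
  if (patience >= epochs_max) stop("patience must be below epochs_max")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs_max = as.integer(epochs_max),
                 patience = as.integer(patience),
                 epsilon_dice = epsilon_dice,
                 augmentation_factor = as.integer(augmentation_factor),
                 seed = as.integer(seed), strict_eq6 = strict_eq6,
                 target_train_loss = target_train_loss),
            class = "train_config")
}

#' Two-class soft Dice loss
#'
#' For predicted probabilities `p` and a binary reference `r`,
#' `DL = 1 - (sum(p*r) + eps) / (sum(p + r) + eps)
#'        - (sum((1-p)*(1-r)) + eps) / (sum(2 - p - r) + eps)`.
#' Each class ratio approaches 1/2 at perfect overlap, so the loss spans
#' roughly (-1/2, 1\]; `eps` guards the empty-volume ratios (note that with
#' this form the degenerate both-empty input scores about -1/2, because
#' the background ratio tends to 1 while the foreground ratio tends to 1).
#' With `strict = FALSE` the conventional variant with a factor 2 on each
#' ratio is used instead (0 at perfect overlap, range about \[0, 2\]).
#'
#' @param p numeric array of probabilities in \[0, 1\].
#' @param r binary array of the same shape.
#' @param eps stabiliser, > 0 (default 1e-5).
#' @param strict use the printed two-term form (default `TRUE`).
#' @return scalar loss.
#' @export
dice_loss <- function(p, r, eps = 1e-5, strict = TRUE) {
  if (!identical(dim(p), dim(r)) && length(p) != length(r))
    stop("shape mismatch between prediction and reference")
  if (eps <= 0) stop("eps must be > 0")
  p <- as.numeric(p); r <- as.numeric(r)
  fg <- (sum(p * r) + eps) / (sum(p + r) + eps)
  bg <- (sum((1 - p) * (1 - r)) + eps) / (sum(2 - p - r) + eps)
  if (strict) 1 - fg - bg else 1 - 2 * fg - 2 * bg + 1
}

# Gradient of dice_loss with respect to p (same array shape as p).
dice_loss_grad <- function(p, r, eps = 1e-5, strict = TRUE) {
  A <- sum(p * r) + eps
  B <- sum(p + r) + eps
  C <- sum((1 - p) * (1 - r)) + eps
  D <- sum(2 - p - r) + eps
  g <- -(r * B - A) / B^2 - (-(1 - r) * D + C) / D^2
  if (!strict) g <- 2 * g
  array(g, dim = dim(p))
}

#' Phase assignments for the five cross-validation folds
#'
#' Fold k (1-based) tests on phases `{(k-1)*10, (k-1)*10 + 50}` (two phases
#' half a cycle apart), validates on the test phases of the previous fold
#' (wrapping, so fold 1 validates on 40% and 90%), and trains on the
#' remaining six phases.
#'
#' @param phases the ten phase percents; must be `seq(0, 90, 10)`.
#' @param n_folds number of folds; must be 5.
#' @return list of 5 lists with sorted numeric `train`, `val`, `test`.
#' @export
build_phase_folds <- function(phases = seq(0, 90, 10), n_folds = 5L) {
  if (!setequal(phases, seq(0, 90, 10)) || length(phases) != 10L)
    stop("phases must be exactly 0, 10, ..., 90")
  if (n_folds != 5L) stop("the phase scheme is defined for 5 folds")
  all <- seq(0, 90, 10)
  lapply(seq_len(5L), function(k) {
    test <- c((k - 1) * 10, (k - 1) * 10 + 50)
    kprev <- if (k == 1L) 5L else k - 1L
    val <- c((kprev - 1) * 10, (kprev - 1) * 10 + 50)
    list(train = sort(setdiff(all, c(test, val))), val = sort(val),
         test = sort(test))
  })
}

#' Patient-level 36/12/12 split for one fold
#'
#' Randomly (but reproducibly, per fold and seed) partitions the 60-patient
#' cohort into 36 training, 12 validation and 12 test patients, and assigns
#' the test patients evenly -- six each -- to the fold's two test phases.
#'
#' @param patient_ids ordered ids; length must equal `cohort` (default 60).
#' @param fold fold index 1..5.
#' @param seed integer seed.
#' @param cohort expected cohort size (default 60).
#' @return list with `train`, `val`, `test` id vectors and
#'   `test_phase_assignment`, a named list mapping each test phase to six
#'   patient ids.
#' @export
split_patients <- function(patient_ids, fold, seed = 1L, cohort = 60L) {
  if (length(patient_ids) != cohort)
    stop("expected ", cohort, " patient ids, got ", length(patient_ids))
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  fold <- as.integer(fold)
  if (fold < 1L || fold > 5L) stop("fold must be in 1..5")
  n <- length(patient_ids)
  n_train <- round(n * 36 / 60)
  n_val <- round(n * 12 / 60)
  set.seed(stream_seed(seed, fold, 0L))
  perm <- sample.int(n)
  train <- patient_ids[perm[seq_len(n_train)]]
  val <- patient_ids[perm[(n_train + 1L):(n_train + n_val)]]
  test <- patient_ids[perm[(n_train + n_val + 1L):n]]
  phases <- build_phase_folds()[[fold]]$test
  half <- ceiling(length(test) / 2)
  assign <- list(test[seq_len(half)], test[(half + 1L):length(test)])
  names(assign) <- as.character(phases)
  list(train = train, val = val, test = test,
       test_phase_assignment = assign)
}

#' Train the segmenter on one fold
#'
#' Adam optimisation of the two-class Dice loss, batch size one, with
#' optional online affine augmentation. The validation loss is monitored
#' each epoch; training stops after `cfg$patience` consecutive epochs
#' without improvement (or at `cfg$epochs_max`), and the weights from the
#' epoch with the lowest validation loss are returned. The per-epoch log
#' records the mean training loss `t_loss` and the mean validation Dice of
#' the binarised prediction `v_score`.
#'
#' @param net a [build_resunet()] network.
#' @param train_data,val_data lists of `list(vol =, mask =)` pairs with
#'   normalised volumes.
#' @param cfg a [train_config()].
#' @param augment_cfg optional [affine_augment_config()]; when supplied and
#'   `cfg$augmentation_factor > 0`, each training pair additionally
#'   contributes that many augmented copies per epoch.
#' @param verbose print per-epoch progress.
#' @return list with `net` (best weights), `log` (data.frame epoch/t_loss/
#'   v_loss/v_score), `best_epoch`, `stop_epoch`.
#' @export
train_fold <- function(net, train_data, val_data, cfg = train_config(),
                       augment_cfg = NULL, verbose = FALSE) {
  if (length(train_data) == 0L) stop("empty training set")
  opt <- adam_init(net$params, lr = cfg$lr, beta1 = cfg$beta1,
                   beta2 = cfg$beta2)
  best_loss <- Inf
  best_params <- net$params
  best_epoch <- 0L
  bad <- 0L
  log <- data.frame(epoch = integer(), t_loss = numeric(),
                    v_loss = numeric(), v_score = numeric())
  eval_val <- function() {
    if (length(val_data) == 0L) return(c(NA_real_, NA_real_))
    vl <- 0; vs <- 0
    for (s in val_data) {
      prob <- resunet_forward(net, s$vol)$prob
      ref <- as.numeric(s$mask$voxels)
      vl <- vl + dice_loss(prob, ref, cfg$epsilon_dice, cfg$strict_eq6)
      pred <- prob > net$cfg$threshold
      vs <- vs + 2 * sum(pred & s$mask$voxels) /
        max(sum(pred) + sum(s$mask$voxels), 1)
    }
    c(vl / length(val_data), vs / length(val_data))
  }
  stop_epoch <- cfg$epochs_max
  for (epoch in seq_len(cfg$epochs_max)) {
    tl <- 0; nb <- 0L
    for (si in seq_along(train_data)) {
      s <- train_data[[si]]
      batch <- list(list(vol = s$vol, mask = s$mask))
      if (!is.null(augment_cfg) && cfg$augmentation_factor > 0L) {
        acfg <- augment_cfg
        acfg$factor <- cfg$augmentation_factor
        batch <- c(batch, augment_pair(s$vol, s$mask, acfg,
                                       epoch = epoch, sample = si))
      }
      for (b in batch) {
        fw <- resunet_forward(net, b$vol, want_cache = TRUE)
        ref <- array(as.numeric(b$mask$voxels), dim = dim(fw$prob))
        tl <- tl + dice_loss(fw$prob, ref, cfg$epsilon_dice, cfg$strict_eq6)
        nb <- nb + 1L
        g <- dice_loss_grad(fw$prob, ref, cfg$epsilon_dice, cfg$strict_eq6)
        grads <- resunet_backward(net, fw$cache, g)
        st <- adam_step(opt, net$params, grads)
        net$params <- st$params
        opt <- st$opt
      }
    }
    tl <- tl / nb
    v <- eval_val()
    log <- rbind(log, data.frame(epoch = epoch, t_loss = tl,
                                 v_loss = v[1], v_score = v[2]))
    if (verbose)
      message(sprintf("epoch %3d  t_loss %.4f  v_loss %.4f  v_score %.4f",
                      epoch, tl, v[1], v[2]))
    monitor <- if (is.na(v[1])) tl else v[1]
    if (monitor < best_loss - 1e-12) {
      best_loss <- monitor
      best_params <- net$params
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) { stop_epoch <- epoch; break }
    }
    if (!is.null(cfg$target_train_loss) && tl < cfg$target_train_loss) {
      stop_epoch <- epoch
      break
    }
    stop_epoch <- epoch
  }
  net$params <- best_params
  list(net = net, log = log, best_epoch = best_epoch, stop_epoch = stop_epoch)
}
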