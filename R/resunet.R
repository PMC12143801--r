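#' Residual 3D U-Net configuration
#'
#' Depth-3 encoder-decoder whose stages are residual blocks of two
#' sub-units. Feature maps double along the encoder from `base_features`
#' to `max_features` (32 to 256 under the defaults) and halve along the
#' decoder; skip connections concatenate encoder features into the
#' decoder; the head is a 1x1x1 convolution with a sigmoid.
#'
#' @param depth encoder/decoder depth (default 3).
#' @param base_features first-stage feature maps (default 32).
#' @param max_features bottleneck feature maps; must equal
#'   `base_features * 2^depth` (default 256).
#' @param subunits_per_block residual sub-units per block (default 2).
#' @param threshold default binarisation threshold (default 0.5).
#' @return an object of class `resunet_config`.
#' @export
resunet_config <- function(depth = 3L, base_features = 32L,
                           max_features = base_features * 2^depth,
                           subunits_per_block = 2L, threshold = 0.5) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_features * 2^depth != max_features)
    stop("max_features must equal base_features * 2^depth")
  if (subunits_per_block < 1L) stop("subunits_per_block must be >= 1")
  structure(list(depth = depth, base_features = as.integer(base_features),
                 max_features = as.integer(max_features),
                 subunits_per_block = as.integer(subunits_per_block),
                 kernel = 3L, downsample_stride = 2L,
                 in_channels = 1L, out_channels = 1L,
                 threshold = threshold),
            class = "resunet_config")
}

#' Per-stage feature-map widths
#'
#' Enumerates encoder, bottleneck and decoder widths; (32, 64, 128, 256,
#' 128, 64, 32) under the default configuration.
#'
#' @param cfg a [resunet_config()].
#' @return integer vector of stage widths.
#' @export
feature_widths <- function(cfg = resunet_config()) {
  enc <- cfg$base_features * 2^(seq_len(cfg$depth) - 1L)
  as.integer(c(enc, cfg$max_features, rev(enc)))
}

init_subunit <- function(cin, cout, stride) {
  p <- list(conv1 = kaiming_conv(3L, cin, cout),
            a1 = rep(0.25, cout),
            conv2 = kaiming_conv(3L, cout, cout))
  if (cin != cout || stride != 1L)
    p$proj <- kaiming_conv(1L, cin, cout)
  p
}

init_block <- function(cin, cout, stride, nsub) {
  b <- list(sub1 = init_subunit(cin, cout, stride))
  for (i in seq_len(nsub - 1L))
    b[[paste0("sub", i + 1L)]] <- init_subunit(cout, cout, 1L)
  b
}

#' Build a residual 3D U-Net
#'
#' Constructs the network and initialises all convolution weights with
#' Kaiming-normal draws (PReLU slopes start at 0.25, biases at zero) under
#' `seed`, so identical seeds give identical parameters.
#'
#' @param cfg a [resunet_config()].
#' @param seed integer RNG seed for initialisation.
#' @return an object of class `resunet` holding `cfg` and nested `params`.
#' @export
build_resunet <- function(cfg = resunet_config(), seed = 1L) {
  net <- structure(list(cfg = cfg, params = NULL, seed = as.integer(seed)),
                   class = "resunet")
  init_weights(net, seed)
}

#' (Re-)initialise network weights
#'
#' @param net a [build_resunet()] network.
#' @param seed integer seed; identical seeds yield parameter-wise identical
#'   networks.
#' @return the network with fresh parameters.
#' @export
init_weights <- function(net, seed = 1L) {
  cfg <- net$cfg
  set.seed(as.integer(seed))
  w <- feature_widths(cfg)
  depth <- cfg$depth
  nsub <- cfg$subunits_per_block
  enc <- vector("list", depth)
  cin <- cfg$in_channels
  for (i in seq_len(depth)) {
    enc[[i]] <- init_block(cin, w[i], if (i == 1L) 1L else 2L, nsub)
    cin <- w[i]
  }
  bott <- init_block(w[depth], cfg$max_features, 2L, nsub)
  dec <- vector("list", depth)
  cprev <- cfg$max_features
  for (i in rev(seq_len(depth))) {
    cout <- w[i]
    dec[[i]] <- list(up = kaiming_upconv(cprev, cout),
                     upa = rep(0.25, cout),
                     block = init_block(2L * cout, cout, 1L, nsub))
    cprev <- cout
  }
  head <- kaiming_conv(1L, w[1], cfg$out_channels)
  net$params <- list(enc = enc, bott = bott, dec = dec, head = head)
  net$seed <- as.integer(seed)
  net
}

subunit_fwd <- function(p, x, stride = 1L) {
  c1 <- conv_fwd(x, p$conv1, stride = stride, pad = 1L)
  n1 <- instnorm_fwd(c1$y)
  a1 <- prelu_fwd(n1$y, p$a1)
  c2 <- conv_fwd(a1$y, p$conv2, stride = 1L, pad = 1L)
  n2 <- instnorm_fwd(c2$y)
  if (!is.null(p$proj)) {
    sc <- conv_fwd(x, p$proj, stride = stride, pad = 0L)
    y <- sc$y + n2$y
    sc_cache <- sc$cache
  } else {
    y <- x + n2$y
    sc_cache <- NULL
  }
  list(y = y, cache = list(c1 = c1$cache, n1 = n1$cache, a1 = a1$cache,
                           c2 = c2$cache, n2 = n2$cache, sc = sc_cache))
}

subunit_bwd <- function(p, cache, dy) {
  dn2 <- instnorm_bwd(dy, cache$n2)
  cb2 <- conv_bwd(dn2, p$conv2, cache$c2)
  pb <- prelu_bwd(cb2$dx, p$a1, cache$a1)
  dn1 <- instnorm_bwd(pb$dx, cache$n1)
  cb1 <- conv_bwd(dn1, p$conv1, cache$c1)
  dx <- cb1$dx
  grads <- list(conv1 = cb1$grads, a1 = pb$grads, conv2 = cb2$grads)
  if (!is.null(p$proj)) {
    pj <- conv_bwd(dy, p$proj, cache$sc)
    dx <- dx + pj$dx
    grads$proj <- pj$grads
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = grads)
}

block_fwd <- function(p, x, stride = 1L) {
  caches <- vector("list", length(p))
  cur <- x
  for (i in seq_along(p)) {
    s <- subunit_fwd(p[[i]], cur, stride = if (i == 1L) stride else 1L)
    caches[[i]] <- s$cache
    cur <- s$y
  }
  list(y = cur, cache = caches)
}

block_bwd <- function(p, cache, dy) {
  grads <- vector("list", length(p))
  names(grads) <- names(p)
  for (i in rev(seq_along(p))) {
    s <- subunit_bwd(p[[i]], cache[[i]], dy)
    grads[[i]] <- s$grads
    dy <- s$dx
  }
  list(dx = dy, grads = grads)
}

as_input_array <- function(x) {
  if (inherits(x, "image_volume")) x <- x$voxels
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Forward pass of the residual 3D U-Net
#'
#' @param net a [build_resunet()] network.
#' @param x numeric 3D array (or [image_volume()]); every spatial dimension
#'   must be divisible by `2^depth`.
#' @param want_cache keep layer caches for backpropagation.
#' @return list with `prob` (3D array of sigmoid outputs in (0, 1)) and,
#'   when requested, `cache`.
#' @export
resunet_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$cfg
  x <- as_input_array(x)
  sd3 <- dim(x)[1:3]
  if (any(sd3 %% (2^cfg$depth) != 0))
    stop("input spatial dimensions must be divisible by 2^depth = ",
         2^cfg$depth)
  p <- net$params
  depth <- cfg$depth
  skips <- vector("list", depth)
  enc_caches <- vector("list", depth)
  cur <- x
  for (i in seq_len(depth)) {
    b <- block_fwd(p$enc[[i]], cur, stride = if (i == 1L) 1L else 2L)
    skips[[i]] <- b$y
    enc_caches[[i]] <- b$cache
    cur <- b$y
  }
  bb <- block_fwd(p$bott, cur, stride = 2L)
  cur <- bb$y
  dec_caches <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    u <- upconv_fwd(cur, p$dec[[i]]$up)
    un <- instnorm_fwd(u$y)
    ua <- prelu_fwd(un$y, p$dec[[i]]$upa)
    dcat <- c(dim(ua$y)[1:3], dim(ua$y)[4] + dim(skips[[i]])[4])
    cat4 <- array(c(ua$y, skips[[i]]), dim = dcat)
    db <- block_fwd(p$dec[[i]]$block, cat4, stride = 1L)
    dec_caches[[i]] <- list(up = u$cache, un = un$cache, ua = ua$cache,
                            ncat = dim(ua$y)[4], block = db$cache)
    cur <- db$y
  }
  hc <- conv_fwd(cur, p$head, stride = 1L, pad = 0L)
  sg <- sigmoid_fwd(hc$y)
  prob <- array(sg$y, dim = sd3)
  if (!want_cache) return(list(prob = prob))
  list(prob = prob,
       cache = list(enc = enc_caches, bott = bb$cache, dec = dec_caches,
                    head = hc$cache, sig = sg$cache, sd3 = sd3))
}

# Backward pass; dprob has the spatial shape of the input. Returns nested
# gradients matching net$params.
resunet_backward <- function(net, cache, dprob) {
  p <- net$params
  depth <- net$cfg$depth
  dy <- sigmoid_bwd(array(dprob, dim = c(cache$sd3, 1L)), cache$sig)
  hb <- conv_bwd(dy, p$head, cache$head)
  grads <- list(enc = vector("list", depth), bott = NULL,
                dec = vector("list", depth), head = hb$grads)
  dskips <- vector("list", depth)
  dcur <- hb$dx
  for (i in seq_len(depth)) {
    dc <- cache$dec[[i]]
    db <- block_bwd(p$dec[[i]]$block, dc$block, dcur)
    ncat <- dc$ncat
    dall <- db$dx
    nc <- dim(dall)[4]
    dua <- dall[, , , seq_len(ncat), drop = FALSE]
    dskips[[i]] <- dall[, , , (ncat + 1L):nc, drop = FALSE]
    pb <- prelu_bwd(dua, p$dec[[i]]$upa, dc$ua)
    dun <- instnorm_bwd(pb$dx, dc$un)
    ub <- upconv_bwd(dun, p$dec[[i]]$up, dc$up)
    grads$dec[[i]] <- list(up = ub$grads, upa = pb$grads, block = db$grads)
    dcur <- ub$dx
  }
  bb <- block_bwd(p$bott, cache$bott, dcur)
  grads$bott <- bb$grads
  dcur <- bb$dx
  for (i in rev(seq_len(depth))) {
    dcur <- dcur + dskips[[i]]
    eb <- block_bwd(p$enc[[i]], cache$enc[[i]], dcur)
    grads$enc[[i]] <- eb$grads
    dcur <- eb$dx
  }
  grads
}

#' Predict a binary mask
#'
#' Runs the forward pass and thresholds the sigmoid output.
#'
#' @param net a [build_resunet()] network.
#' @param vol a *normalised* [image_volume()] (or a 3D array in \[0, 1\]).
#' @param threshold binarisation threshold (default from the config).
#' @return a [binary_mask()] inheriting the volume's geometry.
#' @export
predict_mask <- function(net, vol, threshold = NULL) {
  if (is.null(threshold)) threshold <- net$cfg$threshold
  spacing <- c(1, 1, 1); phase <- NULL; pid <- NULL
  if (inherits(vol, "image_volume")) {
    if (vol$intensity_state != "normalized")
      stop("predict_mask expects a normalised volume")
    spacing <- vol$spacing; phase <- vol$phase; pid <- vol$patient_id
  }
  prob <- resunet_forward(net, vol)$prob
  binary_mask(prob > threshold, spacing = spacing, phase = phase,
              patient_id = pid)
}

#' Number of trainable parameters
#'
#' @param net a [build_resunet()] network.
#' @return integer parameter count (a pure function of the configuration).
#' @export
count_params <- function(net) as.integer(nested_count(net$params))

#' @export
print.resunet <- function(x, ...) {
  cat(sprintf("<resunet> depth %d, widths %s, %d parameters\n",
              x$cfg$depth, paste(feature_widths(x$cfg), collapse = "-"),
              count_params(x)))
  invisible(x)
}
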