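# A small CPU deep-learning engine: 3D convolution via im2col (Rcpp gather,
# BLAS matmul), affine-free instance normalisation, per-channel PReLU,
# kernel-2/stride-2 transposed convolution, sigmoid, and Adam. Backward
# passes are hand-derived and checked against finite differences in the
# test suite. Feature maps are numeric arrays of dim (X, Y, Z, C).

conv_out_dim <- function(d, k, stride, pad) (d + 2L * pad - k) %/% stride + 1L

conv_fwd <- function(x, p, stride = 1L, pad = 1L) {
  dx <- dim(x)
  k <- dim(p$W)[1]
  cout <- dim(p$W)[5]
  Wm <- p$W
  dim(Wm) <- c(length(p$W) %/% cout, cout)
  res <- conv_fwd_cpp(x, as.integer(dx), Wm, p$b, k, as.integer(stride),
                      as.integer(pad))
  y <- res$y
  dim(y) <- c(conv_out_dim(dx[1:3], k, stride, pad), cout)
  list(y = y,
       cache = list(cols = res$cols, dx = dx, k = k, stride = stride,
                    pad = pad))
}

conv_bwd <- function(dy, p, cache) {
  cout <- dim(p$W)[5]
  Wm <- p$W
  dim(Wm) <- c(length(p$W) %/% cout, cout)
  res <- conv_bwd_cpp(dy, cache$cols, Wm, as.integer(cache$dx), cache$k,
                      as.integer(cache$stride), as.integer(cache$pad))
  dx <- res$dx
  dim(dx) <- cache$dx
  dW <- res$dW
  dim(dW) <- dim(p$W)
  list(dx = dx, grads = list(W = dW, b = res$db))
}

IN_EPS <- 1e-5

instnorm_fwd <- function(x) {
  d <- dim(x)
  n <- prod(d[1:3])
  res <- instnorm_fwd_cpp(x, as.integer(n), as.integer(d[4]), IN_EPS)
  y <- res$y
  dim(y) <- d
  list(y = y, cache = list(y = y, isd = res$isd, d = d, n = n))
}

instnorm_bwd <- function(dy, cache) {
  dx <- instnorm_bwd_cpp(dy, cache$y, cache$isd, as.integer(cache$n),
                         as.integer(cache$d[4]))
  dim(dx) <- cache$d
  dx
}

prelu_fwd <- function(x, a) {
  d <- dim(x)
  n <- prod(d[1:3])
  y <- prelu_fwd_cpp(x, a, as.integer(n))
  dim(y) <- d
  list(y = y, cache = list(x = x, d = d, n = n))
}

prelu_bwd <- function(dy, a, cache) {
  res <- prelu_bwd_cpp(dy, cache$x, a, as.integer(cache$n))
  dx <- res$dx
  dim(dx) <- cache$d
  list(dx = dx, grads = res$da)
}

# Transposed convolution, kernel 2, stride 2 (exact 2x upsampling).
# W has dim (2, 2, 2, Cout, Cin).
upconv_fwd <- function(x, p) {
  d <- dim(x)
  cin <- d[4]
  cout <- dim(p$W)[4]
  n <- prod(d[1:3])
  xm <- matrix(x, nrow = n)                         # n x cin
  Wm <- matrix(p$W, ncol = cin)                     # (8*cout) x cin
  ym <- tcrossprod(xm, Wm)                          # n x (8*cout)
  od <- c(2L * d[1:3], cout)
  idx <- upconv_index(d[1:3], cout)
  out <- numeric(prod(od))
  out[idx] <- ym
  out <- out + rep(p$b, each = prod(od[1:3]))
  list(y = array(out, dim = od),
       cache = list(xm = xm, d = d, idx = idx, cout = cout))
}

upconv_bwd <- function(dy, p, cache) {
  d <- cache$d
  cin <- d[4]
  n <- prod(d[1:3])
  dym <- matrix(dy[cache$idx], nrow = n)            # n x (8*cout)
  Wm <- matrix(p$W, ncol = cin)
  dW <- crossprod(dym, cache$xm)                    # (8*cout) x cin
  dxm <- dym %*% Wm                                 # n x cin
  odspat <- prod(2L * d[1:3])
  db <- colSums(matrix(dy, nrow = odspat))
  list(dx = array(dxm, dim = d),
       grads = list(W = array(dW, dim = dim(p$W)), b = db))
}

# Linear (column-major) indices of output voxels written by each column of
# the upconv product, ordered (n, (dx, dy, dz, co)).
upconv_index <- function(sd, cout) {
  X <- sd[1]; Y <- sd[2]; Z <- sd[3]
  X2 <- 2L * X; Y2 <- 2L * Y; Z2 <- 2L * Z
  xo <- rep(seq_len(X) - 1L, times = Y * Z)
  yo <- rep(rep(seq_len(Y) - 1L, each = X), times = Z)
  zo <- rep(seq_len(Z) - 1L, each = X * Y)
  base <- 2L * xo + X2 * (2L * yo) + X2 * Y2 * (2L * zo)   # 0-based
  off <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  out <- integer(0)
  spat <- as.double(X2) * Y2 * Z2
  idx <- vector("list", 8L * cout)
  pos <- 1L
  for (co in seq_len(cout) - 1L) {
    for (r in seq_len(8L)) {
      o <- off$dx[r] + X2 * off$dy[r] + X2 * Y2 * off$dz[r] + spat * co
      idx[[pos]] <- base + o + 1
      pos <- pos + 1L
    }
  }
  unlist(idx, use.names = FALSE)
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}

sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

# ---- parameter initialisation -------------------------------------------

kaiming_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  list(W = array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
                 dim = c(k, k, k, cin, cout)),
       b = numeric(cout))
}

kaiming_upconv <- function(cin, cout) {
  fan_in <- cin                                     # one input tap per output
  list(W = array(stats::rnorm(8 * cout * cin, sd = sqrt(2 / fan_in)),
                 dim = c(2, 2, 2, cout, cin)),
       b = numeric(cout))
}

# ---- nested parameter trees ---------------------------------------------

is_param_leaf <- function(x) !is.list(x)

nested_map <- function(f, x) {
  if (is_param_leaf(x)) return(f(x))
  lapply(x, function(e) nested_map(f, e))
}

nested_map2 <- function(f, x, y) {
  if (is_param_leaf(x)) return(f(x, y))
  mapply(function(a, b) nested_map2(f, a, b), x, y, SIMPLIFY = FALSE)
}

nested_map3 <- function(f, x, y, z) {
  if (is_param_leaf(x)) return(f(x, y, z))
  mapply(function(a, b, c) nested_map3(f, a, b, c), x, y, z, SIMPLIFY = FALSE)
}

nested_zero <- function(x) nested_map(function(v) v * 0, x)

nested_count <- function(x) {
  if (is_param_leaf(x)) return(length(x))
  sum(vapply(x, nested_count, numeric(1)))
}

#' Adam optimiser state
#'
#' Standard Adam with bias correction; `lr` defaults to 1e-4 and the decay
#' rates to (0.9, 0.999).
#'
#' @param params nested parameter list (as held by a network).
#' @param lr learning rate.
#' @param beta1,beta2 moving-average decay rates.
#' @param eps numerical stabiliser.
#' @return an `adam_state` object.
#' @export
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  structure(list(m = nested_zero(params), v = nested_zero(params),
                 t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' One Adam update
#'
#' @param opt an [adam_init()] state.
#' @param params nested parameter list.
#' @param grads matching nested gradient list.
#' @return list with updated `params` and `opt`.
#' @export
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- nested_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                       opt$m, grads)
  opt$v <- nested_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g * g,
                       opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  params <- nested_map3(function(p, m, v)
    p - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps),
    params, opt$m, opt$v)
  list(params = params, opt = opt)
}
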