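# Unsupervised baseline classifiers: clustering on raw volumetric features
# (DBSCAN, GMM, mean shift) or on the latent space of a small autoencoder
# (AE + DBSCAN / GMM). Clusters are mapped to rhythm labels by the
# majority-class rule: the largest cluster becomes AF, everything else
# (including DBSCAN noise) SR.

#' Fit a dense autoencoder
#'
#' A single-hidden-layer autoencoder `d -> latent_dim -> d` trained with
#' Adam on the mean squared reconstruction error of the z-scored
#' features. With `activation = "linear"` and `latent_dim = d` the model
#' has identity capacity.
#'
#' @param X numeric matrix (samples x features).
#' @param latent_dim latent dimension (default 2).
#' @param activation `"tanh"` or `"linear"` on the latent layer.
#' @param epochs training epochs (full-batch).
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @return object of class `autoencoder` with weights, the standardiser
#'   and the final reconstruction MSE.
#' @export
autoencoder_fit <- function(X, latent_dim = 2L, activation = c("tanh", "linear"),
                            epochs = 2000L, lr = 1e-2, seed = 1L) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  st <- standardize_fit(X)
  Z <- standardize_apply(X, st)
  d <- ncol(Z); n <- nrow(Z)
  set.seed(as.integer(seed))
  params <- list(W1 = matrix(stats::rnorm(latent_dim * d, sd = sqrt(1 / d)),
                             latent_dim, d),
                 b1 = numeric(latent_dim),
                 W2 = matrix(stats::rnorm(d * latent_dim,
                                          sd = sqrt(1 / latent_dim)),
                             d, latent_dim),
                 b2 = numeric(d))
  opt <- adam_init(params, lr = lr)
  mse <- NA_real_
  for (e in seq_len(epochs)) {
    H <- Z %*% t(params$W1) + rep(params$b1, each = n)
    A <- if (activation == "tanh") tanh(H) else H
    Y <- A %*% t(params$W2) + rep(params$b2, each = n)
    E <- Y - Z
    mse <- mean(E^2)
    dY <- 2 * E / length(E)
    gW2 <- t(dY) %*% A
    gb2 <- colSums(dY)
    dA <- dY %*% params$W2
    dH <- if (activation == "tanh") dA * (1 - A^2) else dA
    gW1 <- t(dH) %*% Z
    gb1 <- colSums(dH)
    st_ <- adam_step(opt, params, list(W1 = gW1, b1 = gb1, W2 = gW2,
                                       b2 = gb2))
    params <- st_$params
    opt <- st_$opt
  }
  structure(list(params = params, activation = activation, standard = st,
                 latent_dim = latent_dim, mse = mse),
            class = "autoencoder")
}

#' Encode features into the autoencoder latent space
#'
#' @param ae an [autoencoder_fit()] model.
#' @param X numeric matrix.
#' @return matrix of latent codes (samples x latent_dim).
#' @export
autoencoder_encode <- function(ae, X) {
  Z <- standardize_apply(as.matrix(X), ae$standard)
  H <- Z %*% t(ae$params$W1) + rep(ae$params$b1, each = nrow(Z))
  if (ae$activation == "tanh") tanh(H) else H
}

mvn_logdens <- function(X, mu, S) {
  d <- length(mu)
  ch <- chol(S)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Gaussian mixture model clustering (EM)
#'
#' Full-covariance k-component GMM fitted by EM, initialised from a seeded
#' k-means; covariances are ridge-regularised for stability.
#'
#' @param X numeric matrix.
#' @param k number of components (default 2).
#' @param max_iter EM iteration cap.
#' @param seed integer seed (k-means initialisation).
#' @return list with `cluster` (hard assignments), `weights`, `means`,
#'   `covs`, `loglik`.
#' @export
gmm_cluster <- function(X, k = 2L, max_iter = 200L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < k) stop("fewer samples than components")
  set.seed(as.integer(seed))
  km <- stats::kmeans(X, centers = k, nstart = 5)
  w <- tabulate(km$cluster, k) / n
  mu <- lapply(seq_len(k), function(j) colMeans(X[km$cluster == j, ,
                                                  drop = FALSE]))
  ridge <- diag(1e-6 * mean(apply(X, 2, stats::var)) + 1e-12, d)
  cov_of <- function(idx, resp = NULL) {
    if (is.null(resp)) {
      xs <- X[idx, , drop = FALSE]
      if (nrow(xs) < 2L) return(diag(1, d))
      stats::cov(xs) * (nrow(xs) - 1) / nrow(xs) + ridge
    }
  }
  S <- lapply(seq_len(k), function(j) cov_of(km$cluster == j))
  ll_old <- -Inf
  resp <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + mvn_logdens(X, mu[[j]], S[[j]]), numeric(n))
    m <- apply(logd, 1, max)
    ll <- sum(m + log(rowSums(exp(logd - m))))
    resp <- exp(logd - m - log(rowSums(exp(logd - m))))
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[[j]] <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu[[j]])
      S[[j]] <- t(Xc) %*% (resp[, j] * Xc) / nk[j] + ridge
    }
    if (abs(ll - ll_old) < 1e-9 * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(cluster = max.col(resp), weights = w, means = mu, covs = S,
       loglik = ll_old)
}

#' DBSCAN clustering
#'
#' Brute-force density-based clustering. Points with fewer than `min_pts`
#' neighbours within `eps` that are not reachable from a core point are
#' labelled noise (cluster 0).
#'
#' @param X numeric matrix.
#' @param eps neighbourhood radius.
#' @param min_pts core-point threshold (default 4).
#' @return integer cluster labels, 0 = noise.
#' @export
dbscan_cluster <- function(X, eps, min_pts = 4L) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (m in nb[[q]]) {
        if (lab[m] == 0L) {
          lab[m] <- cur
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  lab
}

#' Mean-shift clustering
#'
#' Flat-kernel mean shift: each point iterates to the mean of its
#' `bandwidth`-neighbourhood until convergence; converged modes closer
#' than `bandwidth / 2` are merged into one cluster.
#'
#' @param X numeric matrix.
#' @param bandwidth neighbourhood radius.
#' @param max_iter iteration cap per point.
#' @return integer cluster labels (1-based).
#' @export
meanshift_cluster <- function(X, bandwidth, max_iter = 300L) {
  X <- as.matrix(X)
  n <- nrow(X)
  modes <- X
  for (i in seq_len(n)) {
    p <- X[i, ]
    for (it in seq_len(max_iter)) {
      d2 <- colSums((t(X) - p)^2)
      inb <- d2 <= bandwidth^2
      np <- colMeans(X[inb, , drop = FALSE])
      if (sqrt(sum((np - p)^2)) < 1e-6 * bandwidth) { p <- np; break }
      p <- np
    }
    modes[i, ] <- p
  }
  lab <- integer(n)
  centers <- NULL
  cur <- 0L
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (!is.null(centers)) {
      dc <- sqrt(colSums((t(centers) - modes[i, ])^2))
      jm <- which.min(dc)
      if (length(dc) && dc[jm] < bandwidth / 2) {
        lab[i] <- jm
        assigned <- TRUE
      }
    }
    if (!assigned) {
      cur <- cur + 1L
      centers <- rbind(centers, modes[i, ])
      lab[i] <- cur
    }
  }
  lab
}

# Largest cluster -> AF (majority class); all other clusters and DBSCAN
# noise -> SR. When clustering is degenerate (one cluster, no noise) the
# mapping is still applied and a warning raised.
clusters_to_labels <- function(cluster) {
  pos <- cluster[cluster > 0L]
  if (length(pos) == 0L) return(rep("SR", length(cluster)))
  sizes <- tabulate(pos)
  major <- which.max(sizes)
  if (length(sizes) == 1L && all(cluster > 0L))
    warning("clustering produced a single cluster and no noise; ",
            "all samples mapped to AF")
  ifelse(cluster == major, "AF", "SR")
}

tune_eps <- function(X, min_pts) {
  D <- stats::dist(X)
  cand <- unique(stats::quantile(D, seq(0.05, 0.95, by = 0.05)))
  cand <- cand[cand > 0]
  best <- cand[1]; best_key <- c(-Inf, -Inf)
  for (e in cand) {
    lab <- dbscan_cluster(X, eps = e, min_pts = min_pts)
    ncl <- length(unique(lab[lab > 0L]))
    key <- c(as.numeric(ncl == 2L), mean(lab > 0L))
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- e; best_key <- key
    }
  }
  best
}

tune_bandwidth <- function(X) {
  D <- stats::dist(X)
  cand <- unique(stats::quantile(D, seq(0.1, 0.9, by = 0.1)))
  cand <- cand[cand > 0]
  for (b in cand) {
    lab <- meanshift_cluster(X, bandwidth = b)
    if (length(unique(lab)) == 2L) return(b)
  }
  stats::median(D)
}

#' Unsupervised baseline rhythm classifiers
#'
#' The five comparison methods: clustering of autoencoder latents
#' (`"AE_DBSCAN"`, `"AE_GMM"`) and direct clustering of the volumetric
#' features (`"DBSCAN"`, `"GMM"`, `"MEANSHIFT"`). Features are z-scored;
#' DBSCAN's radius and mean shift's bandwidth are tuned over distance
#' quantiles (preferring a two-cluster solution); the largest cluster is
#' mapped to AF and everything else, including noise, to SR.
#'
#' @param X numeric matrix (samples x features).
#' @param labels character truth labels over `{"AF", "SR"}`.
#' @param method one of `"AE_DBSCAN"`, `"AE_GMM"`, `"DBSCAN"`, `"GMM"`,
#'   `"MEANSHIFT"`.
#' @param eps,bandwidth optional fixed hyperparameters (skip tuning).
#' @param min_pts DBSCAN core threshold (default 4).
#' @param latent_dim,activation autoencoder settings for the AE variants.
#' @param seed integer seed (autoencoder and GMM initialisation).
#' @return list with `report` (a [classification_report()]), `pred` and
#'   `cluster`.
#' @export
baseline_classifiers <- function(X, labels,
                                 method = c("AE_DBSCAN", "AE_GMM", "DBSCAN",
                                            "GMM", "MEANSHIFT"),
                                 eps = NULL, bandwidth = NULL, min_pts = 4L,
                                 latent_dim = 2L, activation = "tanh",
                                 seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 4L) stop("need at least 4 samples")
  Z <- standardize_apply(X, standardize_fit(X))
  if (startsWith(method, "AE_")) {
    ae <- autoencoder_fit(X, latent_dim = latent_dim,
                          activation = activation, seed = seed)
    Z <- autoencoder_encode(ae, X)
  }
  cluster <- switch(method,
    AE_DBSCAN = , DBSCAN = {
      if (is.null(eps)) eps <- tune_eps(Z, min_pts)
      dbscan_cluster(Z, eps = eps, min_pts = min_pts)
    },
    AE_GMM = , GMM = gmm_cluster(Z, k = 2L, seed = seed)$cluster,
    MEANSHIFT = {
      if (is.null(bandwidth)) bandwidth <- tune_bandwidth(Z)
      meanshift_cluster(Z, bandwidth = bandwidth)
    })
  pred <- clusters_to_labels(cluster)
  list(report = classification_report(pred, labels), pred = pred,
       cluster = cluster)
}
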