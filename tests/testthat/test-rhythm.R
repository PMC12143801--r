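test_that("kernel_eval matches the printed kernel formulas", {
  expect_equal(kernel_eval(ocsvm_config("linear"), c(1, 0, 0), c(0, 1, 0)), 0)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3)
    g <- runif(1, 0.1, 2)
    expect_equal(kernel_eval(ocsvm_config("rbf", gamma = g), x, x), 1)
    expect_equal(kernel_eval(ocsvm_config("rbf", gamma = g), x, y),
                 exp(-g * sum((x - y)^2)), tolerance = 1e-12)
    expect_equal(kernel_eval(ocsvm_config("poly", c = 0.3, degree = 3), x, y),
                 (x[1] * y[1] + x[2] * y[2] + x[3] * y[3] + 0.3)^3,
                 tolerance = 1e-12)
    expect_equal(kernel_eval(ocsvm_config("sigmoid", gamma = g, r = 0.2),
                             x, y),
                 tanh(g * sum(x * y) + 0.2), tolerance = 1e-12)
  }
  expect_error(kernel_eval(ocsvm_config("linear"), 1:2, 1:3), "dimension")
})

test_that("default_gamma is 1 / (n * var) with the pooled variance", {
  X <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1), nrow = 4)   # pooled var 0.25, n 4
  expect_equal(default_gamma(X), 1.0)
  set.seed(9)
  Y <- matrix(rnorm(30), 10)
  expect_equal(default_gamma(2 * Y), default_gamma(Y) / 4, tolerance = 1e-12)
  v <- mean((Y - mean(Y))^2)
  expect_equal(default_gamma(Y), 1 / (10 * v), tolerance = 1e-12)
  expect_error(default_gamma(matrix(1, 5, 3)), "variance")
})

test_that("fit_ocsvm honours the nu-property and degenerate inputs", {
  set.seed(10)
  X <- matrix(rnorm(90, sd = 0.5), ncol = 3)
  m <- fit_ocsvm(X, ocsvm_config("rbf", nu = 0.05))
  # margin support vectors sit numerically at f = 0; count with a
  # numerical-zero guard (scikit-learn shows the same behaviour)
  expect_gte(mean(decision_scores(m, X)$f >= -1e-8), 0.9)

  dup <- matrix(rep(c(1, 2, 3), each = 12), ncol = 3)
  md <- fit_ocsvm(dup, ocsvm_config("rbf", gamma = 0.5, nu = 0.1))
  expect_true(all(decision_scores(md, dup)$f >= -1e-8))

  # nu-monotonicity of the training-outlier fraction (within 1/n)
  n <- nrow(X)
  fr <- vapply(c(0.05, 0.10, 0.15, 0.20), function(nu) {
    mm <- fit_ocsvm(X, ocsvm_config("rbf", nu = nu))
    mean(mm$train_f < -1e-8)
  }, numeric(1))
  expect_true(all(diff(fr) >= -1 / n - 1e-12))
})

test_that("the nu bound holds across the whole default grid", {
  tab <- make_rhythm_table(separated_rhythm_config(2))
  X <- scale(as.matrix(tab[, c("laei", "laef", "ap")]))
  n <- nrow(X)
  for (cfg in ocsvm_default_grid()) {
    m <- tryCatch(fit_ocsvm(X, cfg), error = function(e) NULL)
    if (is.null(m)) next
    frac_out <- mean(m$train_f < -1e-8)
    expect_lte(frac_out, cfg$nu + 1 / n + 1e-9)
  }
})

test_that("decision scores expose signed distances consistently", {
  set.seed(12)
  X <- matrix(rnorm(60), ncol = 2)
  m <- fit_ocsvm(X, ocsvm_config("rbf", nu = 0.2))
  sc <- decision_scores(m, X)
  expect_equal(sc$dist, abs(sc$f), tolerance = 1e-15)
  # an interior (margin) support vector sits on the boundary
  interior <- m$coef < max(m$coef) - 1e-10
  if (any(interior)) {
    fi <- decision_scores(m, m$sv[interior, , drop = FALSE])$f
    expect_lt(max(abs(fi)), 1e-6)
  }
  # a far outlier gets a large negative score
  far <- matrix(c(50, 50), ncol = 2)
  expect_lt(decision_scores(m, far)$f, -0.01)
  expect_error(decision_scores(m, matrix(1, 2, 3)), "dimension")
})

test_that("grid search maximises mean |f| and penalises invalid fits", {
  set.seed(13)
  X <- matrix(rnorm(45), ncol = 3)
  one <- list(ocsvm_config("rbf", nu = 0.1))
  gs1 <- ocsvm_grid_search(X, one)
  expect_identical(gs1$best, one[[1]])

  grid <- list(ocsvm_config("rbf", nu = 0.1),
               ocsvm_config("poly", c = 0.2, degree = 3, nu = 0.1),
               ocsvm_config("linear", nu = 0.1))
  gs <- ocsvm_grid_search(X, grid)
  oracle <- vapply(grid, function(cf)
    mean(abs(fit_ocsvm(X, cf)$train_f)), numeric(1))
  expect_equal(gs$scores$score, oracle, tolerance = 1e-9)
  expect_identical(gs$best, grid[[which.max(oracle)]])
  # deterministic: identical rerun
  expect_identical(ocsvm_grid_search(X, grid)$scores, gs$scores)
  expect_error(ocsvm_grid_search(X, list()), "empty")
})

test_that("group_kfold_deterministic is contiguous and order-driven", {
  f33 <- group_kfold_deterministic(sprintf("p%02d", 1:33), 5)
  expect_identical(as.integer(table(f33)), c(7L, 7L, 7L, 6L, 6L))
  expect_true(all(diff(f33) >= 0))                  # contiguous by order
  f10 <- group_kfold_deterministic(1:10, 5)
  expect_identical(as.integer(table(f10)), rep(2L, 5))
  # assignment depends only on position: any id vector of the same length
  # maps positions to the same folds
  expect_identical(group_kfold_deterministic(sample(33), 5), f33)
  expect_error(group_kfold_deterministic(1:3, 5), "at least")
})

test_that("classification_report applies the printed formulas", {
  p <- c("SR", "SR", "AF", "AF")
  t_ <- c("SR", "SR", "AF", "AF")
  r <- classification_report(p, t_)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$acc, 100)
  expect_equal(r$b_acc, 100)

  # tp = 7, fn = 3, tn = 19, fp = 3
  pred <- c(rep("SR", 7), rep("AF", 3), rep("AF", 19), rep("SR", 3))
  truth <- c(rep("SR", 10), rep("AF", 22))
  r2 <- classification_report(pred, truth)
  expect_identical(c(r2$tp, r2$fn, r2$tn, r2$fp), c(7L, 3L, 19L, 3L))
  expect_equal(r2$sensitivity, 70)
  expect_equal(r2$specificity, 100 * 19 / 22, tolerance = 1e-9)
  expect_equal(r2$acc, 100 * 26 / 32, tolerance = 1e-9)

  set.seed(15)
  for (i in 1:100) {
    a <- sample(c("AF", "SR"), 20, replace = TRUE)
    b <- sample(c("AF", "SR"), 20, replace = TRUE)
    rr <- classification_report(a, b)
    expect_equal(rr$b_acc, mean(c(rr$sensitivity, rr$specificity)),
                 tolerance = 1e-12)
  }
  expect_error(classification_report(c("SR", "XX"), c("SR", "AF")), "labels")
})

test_that("tuned OCSVM separates well-separated AF/SR clusters", {
  tab <- make_rhythm_table(separated_rhythm_config(7))
  X <- as.matrix(tab[, c("laei", "laef", "ap")])
  res <- evaluate_ocsvm(X, tab$label, ids = tab$patient_id)
  expect_gte(res$report$b_acc, 90)
  # grid search is deterministic: identical winners on rerun
  res2 <- evaluate_ocsvm(X, tab$label, ids = tab$patient_id)
  expect_identical(res$pred, res2$pred)
  expect_identical(res$configs, res2$configs)
})

test_that("feature ablation reruns the pipeline per feature subset", {
  tab <- make_rhythm_table(separated_rhythm_config(3))
  X <- as.matrix(tab[, c("laei", "laef", "ap")])
  ab <- feature_ablation(X, tab$label,
                         subsets = list("laei", c("laei", "ap"),
                                        c("laei", "laef", "ap")))
  expect_named(ab, c("laei", "laei+ap", "laei+laef+ap"))
  full <- evaluate_ocsvm(X, tab$label)
  expect_equal(ab[["laei+laef+ap"]]$acc, full$report$acc)
  expect_s3_class(ab[["laei"]], "classification_report")
  expect_error(feature_ablation(X, tab$label, subsets = list(character(0))),
               "empty")
  expect_error(feature_ablation(X, tab$label, subsets = list("bogus")),
               "unknown")
})

test_that("ap-only separation favours ap-containing subsets", {
  # classes differ only in AP; LAEI/LAEF are identically distributed
  cfg <- rhythm_sim_config(n_af = 22L, n_sr = 11L,
                           af_mean = c(laei = 30, laef = 23, ap = 100),
                           sr_mean = c(laei = 30, laef = 23, ap = 60),
                           af_cov = diag(c(6, 4, 3)^2),
                           sr_cov = diag(c(6, 4, 3)^2),
                           seed = 21)
  tab <- make_rhythm_table(cfg)
  X <- as.matrix(tab[, c("laei", "laef", "ap")])
  ab <- feature_ablation(X, tab$label,
                         subsets = list("laei", "ap", c("laef", "ap")))
  expect_gt(ab[["ap"]]$b_acc, ab[["laei"]]$b_acc)
  expect_gt(ab[["laef+ap"]]$b_acc, ab[["laei"]]$b_acc)
})
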