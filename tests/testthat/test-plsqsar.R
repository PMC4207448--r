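# PLS fitting, leave-one-out component selection and model ranking.

test_that("variance filter drops exactly the near-constant columns", {
  set.seed(5)
  fm <- structure(list(
    molecule_ids = paste0("m", 1:6),
    steric = cbind(rep(1, 6), rnorm(6, sd = 1), rnorm(6, sd = 0.001)),
    electrostatic = cbind(rnorm(6, sd = 2), rep(-3, 6), rnorm(6)),
    kept_point_indices = c(10L, 20L, 30L),
    grid = NULL), class = "FieldMatrix")
  red <- filter_columns(fm, min_sd = 0.1)
  want_s <- which(apply(fm$steric, 2, sd) >= 0.1)
  want_e <- which(apply(fm$electrostatic, 2, sd) >= 0.1)
  expect_equal(red$steric_cols, fm$kept_point_indices[want_s])
  expect_equal(red$elec_cols, fm$kept_point_indices[want_e])
  expect_equal(ncol(red$steric), length(want_s))
  # min_sd = 0 is the identity
  id <- filter_columns(fm, min_sd = 0)
  expect_equal(dim(id$steric), dim(fm$steric))
  expect_equal(dim(id$electrostatic), dim(fm$electrostatic))
})

test_that("an exactly linear response is fit perfectly", {
  set.seed(3)
  # two descriptors, two components: the latent space spans the signal
  X2 <- matrix(rnorm(30 * 2), 30)
  y2 <- 2 + 1.5 * X2[, 1] - 0.7 * X2[, 2]
  f2 <- fit_pls(X2, y2, noc = 2, block = NULL)
  expect_equal(f2$r2, 1.0, tolerance = 1e-9)
  expect_lt(f2$mse, 1e-12)
  # p descriptors, p components: PLS reaches the exact least-squares fit
  X <- matrix(rnorm(30 * 6), 30)
  y <- 2 + 1.5 * X[, 2] - 0.7 * X[, 5]
  f <- fit_pls(X, y, noc = 6, block = NULL)
  expect_equal(f$r2, 1.0, tolerance = 1e-9)
  expect_equal(f$fitted, y, tolerance = 1e-6)
})

test_that("one component matches the closed-form X'y solution", {
  set.seed(4)
  X <- matrix(rnorm(20 * 8), 20)
  y <- rnorm(20)
  f <- fit_pls(X, y, noc = 1, block = NULL)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w <- as.numeric(t(Xc) %*% yc)
  w <- w / sqrt(sum(w^2))
  t1 <- as.numeric(Xc %*% w)
  beta1 <- w * sum(t1 * yc) / sum(t1^2)
  expect_equal(f$coefficients, beta1, tolerance = 1e-10)
})

test_that("row permutation leaves the coefficients unchanged", {
  set.seed(6)
  X <- matrix(rnorm(18 * 10), 18)
  y <- rnorm(18)
  f1 <- fit_pls(X, y, noc = 3, block = NULL)
  p <- sample(18)
  f2 <- fit_pls(X[p, ], y[p], noc = 3, block = NULL)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_error(fit_pls(X, rep(1, 18), 2), "zero variance")
})

test_that("block scaling equalizes the blocks' total variance", {
  set.seed(8)
  X <- cbind(matrix(rnorm(15 * 4, sd = 10), 15),
             matrix(rnorm(15 * 4, sd = 0.1), 15))
  block <- rep(c("S", "E"), each = 4)
  f <- block_scale_factors(X, block)
  Xs <- sweep(X, 2, unname(f[block]), "*")
  tv <- tapply(apply(Xs, 2, var), block, sum)
  expect_equal(unname(tv["S"]), unname(tv["E"]), tolerance = 1e-12)
})

test_that("leave-one-out selects the true dimensionality when noiseless", {
  set.seed(9)
  X <- matrix(rnorm(20 * 10), 20)
  y <- X[, 1] - 2 * X[, 2]
  cv <- loo_q2(X, y, noc_max = 6, block = NULL)
  expect_gt(cv$q2[[cv$best_noc]], 0.99)
  expect_error(loo_q2(X[1:3, ], y[1:3], 2), "at least 4")
})

test_that("pure-noise responses earn negative q2 on average", {
  set.seed(11)
  q2s <- vapply(1:20, function(r) {
    X <- matrix(rnorm(20 * 15), 20)
    y <- rnorm(20)
    max(loo_q2(X, y, noc_max = 5, block = NULL)$q2)
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("cross-validated q2 never beats the training r2", {
  set.seed(12)
  for (r in 1:5) {
    X <- matrix(rnorm(16 * 12), 16)
    y <- X[, 1] + rnorm(16, sd = runif(1, 0.1, 2))
    cv <- loo_q2(X, y, noc_max = 6, block = NULL)
    for (a in seq_along(cv$q2)) {
      f <- fit_pls(X, y, noc = a, block = NULL)
      expect_lte(cv$q2[[a]], f$r2 + 1e-9)
    }
  }
})

test_that("coefficients reproduce the fitted values exactly", {
  set.seed(14)
  X <- matrix(rnorm(15 * 9), 15)
  y <- X[, 3] + rnorm(15, sd = 0.3)
  f <- fit_pls(X, y, noc = 4, block = NULL)
  manual <- f$y_mean +
    as.numeric(sweep(X, 2, f$x_mean) %*% f$coefficients)
  expect_equal(manual, f$fitted, tolerance = 1e-10)
  expect_equal(predict(f, X), f$fitted, tolerance = 1e-10)
})

test_that("asking for more components than the rank warns and caps", {
  set.seed(15)
  X <- matrix(rnorm(8 * 3), 8)
  y <- rnorm(8)
  expect_warning(f <- fit_pls(X, y, noc = 6, block = NULL), "components")
  expect_lte(f$noc, 3)
})

test_that("models with planted field signal outrank noise models", {
  fx <- make_planted_feature_sets(k = 4, n_molecules = 8, n_noise = 3,
                                  jitter_sd = 0.1, seed = 21)
  cfg <- run_config(min_sd = 0.01, dist_tol = 1.2)
  als <- elucidate(fx$dataset, fx$ensembles, fx$feature_sets, cfg)
  expect_gte(length(als), 1)
  al <- als[[1]]
  fm <- filter_columns(compute_field_matrix(al, fx$ensembles),
                       min_sd = 0.01)
  X <- field_design_matrix(fm)
  j <- which.max(apply(X, 2, sd))
  set.seed(22)
  y_signal <- 6 + scale(X[, j])[, 1] + rnorm(8, sd = 0.05)
  ds <- fx$dataset
  for (i in seq_along(ds$records)) {
    ds$records[[i]]$pIC50 <- y_signal[match(ds$records[[i]]$id,
                                            fm$molecule_ids)]
  }
  models <- build_models(als, fx$ensembles, ds, cfg)
  expect_lte(length(models), length(als))
  stats <- model_stats_table(models)
  expect_equal(stats$q2, sort(stats$q2, decreasing = TRUE))
  expect_identical(models[[1]]$stats$q2,
                   max(vapply(models, function(m) m$stats$q2, numeric(1))))
})
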