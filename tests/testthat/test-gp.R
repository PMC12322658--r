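hyp <- function(sf2 = 1, ls = c(1, 1), sn2 = 1e-6) {
  gp_hyperparams(sf2, ls, sn2)
}

test_that("Matern-5/2 kernel satisfies its closed-form identities", {
  h <- hyp(sf2 = 2.5, ls = c(0.7, 1.3))
  v <- c(0.2, 0.4)
  expect_equal(matern52(v, v, h), 2.5)
  expect_equal(matern52(v, v + c(100, 100), h), 0, tolerance = 1e-12)
  # unit distance with unit hyperparameters
  expect_equal(matern52(c(0, 0), c(1, 0), hyp()),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  # symmetry and boundedness
  set.seed(8)
  for (i in 1:10) {
    a <- runif(2, -3, 3); b <- runif(2, -3, 3)
    expect_equal(matern52(a, b, h), matern52(b, a, h))
    expect_lte(matern52(a, b, h), h$signal_variance)
  }
  # ARD: stretching a length scale increases covariance along that axis
  h2 <- hyp(ls = c(10, 1))
  expect_gt(matern52(c(0, 0), c(1, 0), h2), matern52(c(0, 0), c(1, 0), hyp()))
  expect_error(gp_hyperparams(-1, c(1, 1), 0.1))
})

test_that("kernel matrix matches a brute-force double loop and factorizes with noise", {
  set.seed(21)
  V <- rbind(I = runif(5, 0, 70), n = sample(1:8, 5, replace = TRUE))
  ts <- gp_training_set(V, rnorm(5))
  h <- hyp(sf2 = 1.7, ls = c(0.4, 0.9), sn2 = 0.01)
  K <- kernel_matrix(ts, h)
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(K[i, j], ref_kernel(ts$Vs[, i], ts$Vs[, j],
                                       h$signal_variance, h$length_scales))
    }
  }
  # single point: 1x1 matrix [sigma_f^2]
  ts1 <- gp_training_set(rbind(10, 2), 0.5, standardize = FALSE)
  expect_equal(kernel_matrix(ts1, h), matrix(1.7, 1, 1))
  # duplicated training point: rank-deficient K still factorizes with noise
  Vdup <- rbind(I = c(10, 10, 50), n = c(1, 1, 3))
  tsd <- gp_training_set(Vdup, c(1, 1, 2))
  expect_silent(log_marginal_likelihood(tsd, h))
})

test_that("log marginal likelihood matches the univariate closed form", {
  # single observation, unit total variance, zero label
  ts <- gp_training_set(rbind(0, 0), 0, standardize = FALSE)
  h <- gp_hyperparams(0.6, c(1, 1), 0.4)
  expect_equal(log_marginal_likelihood(ts, h), -0.5 * log(2 * pi))
  # nonzero label: -y^2/(2 s2) - log(s2)/2 - log(2 pi)/2
  y1 <- 1.7
  ts2 <- gp_training_set(rbind(0, 0), y1, standardize = FALSE)
  h2 <- gp_hyperparams(2, c(1, 1), 0.5)
  expect_equal(log_marginal_likelihood(ts2, h2),
               -0.5 * y1^2 / 2.5 - 0.5 * log(2.5) - 0.5 * log(2 * pi))
})

test_that("log marginal likelihood agrees with the direct-solve reference and is permutation invariant", {
  set.seed(31)
  V <- rbind(I = runif(8, 0, 70), n = runif(8, 1, 8))
  L <- sin(V[1, ] / 20) + 0.1 * V[2, ]
  ts <- gp_training_set(V, L)
  h <- hyp(sf2 = 1.3, ls = c(0.5, 1.1), sn2 = 0.05)
  expect_equal(log_marginal_likelihood(ts, h),
               ref_log_marginal(ts$Vs, ts$ys, 1.3, c(0.5, 1.1), 0.05),
               tolerance = 1e-9)
  perm <- sample(8)
  tsp <- gp_training_set(V[, perm], L[perm])
  expect_equal(log_marginal_likelihood(tsp, h), log_marginal_likelihood(ts, h),
               tolerance = 1e-9)
})

test_that("posterior interpolates training labels at negligible noise", {
  set.seed(41)
  V <- rbind(I = c(0, 10, 30, 50, 70), n = c(1, 3, 8, 1, 3))
  L <- c(0.3, 0.25, 0.12, 0.2, 0.15)
  ts <- gp_training_set(V, L)
  h <- hyp(sf2 = 1, ls = c(0.5, 0.8), sn2 = 1e-12)
  for (i in seq_len(ncol(V))) {
    post <- gp_posterior(ts, h, V[, i])
    expect_equal(post$mean, L[i], tolerance = 1e-6)
    expect_lt(post$variance_scaled, 1e-6)
  }
})

test_that("posterior reverts to the prior far from data and variance stays in bounds", {
  V <- rbind(I = c(10, 30, 50), n = c(1, 3, 8))
  L <- c(5, 7, 6)
  ts <- gp_training_set(V, L)
  h <- hyp(sf2 = 2, ls = c(0.3, 0.3), sn2 = 0.1)
  far <- gp_posterior(ts, h, c(7000, 800))
  expect_equal(far$mean_scaled, 0, tolerance = 1e-8)   # zero prior mean
  expect_equal(far$mean, mean(L), tolerance = 1e-6)    # un-standardized
  expect_equal(far$variance_scaled, 2, tolerance = 1e-6)
  set.seed(51)
  for (i in 1:20) {
    post <- gp_posterior(ts, h, c(runif(1, 0, 70), runif(1, 1, 8)),
                         include_noise = TRUE)
    expect_gte(post$variance_scaled, 0)
    expect_lte(post$variance_scaled, 2 + 0.1 + 1e-9)
  }
})

test_that("posterior agrees with an independent reference GP on a fixed 10-point problem", {
  set.seed(61)
  V <- rbind(I = seq(0, 70, length.out = 10),
             n = rep(c(1, 3, 8, 5, 2), 2))
  L <- 0.1 + 0.3 * exp(-((V[1, ] - 30) / 25)^2) + 0.02 * V[2, ]
  ts <- gp_training_set(V, L)
  h <- hyp(sf2 = 1.4, ls = c(0.6, 1.2), sn2 = 1e-4)
  tests <- list(c(20, 2), c(55, 6), c(0, 8), c(35, 3.5))
  for (v in tests) {
    post <- gp_posterior(ts, h, v)
    ref <- ref_gp_posterior(ts$Vs, ts$ys, 1.4, c(0.6, 1.2), 1e-4,
                            v / ts$feature_scale)
    expect_equal(post$mean_scaled, ref$mean, tolerance = 1e-6)
    expect_equal(post$variance_scaled, ref$variance, tolerance = 1e-6)
  }
})

test_that("posterior predictions are invariant under training-row reordering", {
  set.seed(71)
  V <- rbind(I = runif(12, 0, 70), n = sample(1:8, 12, replace = TRUE))
  L <- rnorm(12)
  h <- hyp(sf2 = 1, ls = c(0.7, 0.7), sn2 = 0.01)
  perm <- sample(12)
  for (v in list(c(25, 4), c(60, 2))) {
    a <- gp_posterior(gp_training_set(V, L), h, v)
    b <- gp_posterior(gp_training_set(V[, perm], L[perm]), h, v)
    expect_equal(a$mean, b$mean, tolerance = 1e-9)
    expect_equal(a$variance, b$variance, tolerance = 1e-9)
  }
})

test_that("hyperparameter training recovers known length scales within a factor of two", {
  set.seed(81)
  nd <- 30
  V <- rbind(I = runif(nd, 0, 70), n = runif(nd, 1, 8))
  true_h <- hyp(sf2 = 1, ls = c(0.3, 0.6), sn2 = 1e-3)
  Vs <- V / DEFAULT_FEATURE_SCALE
  K <- matrix(NA_real_, nd, nd)
  for (i in 1:nd) for (j in 1:nd) {
    K[i, j] <- ref_kernel(Vs[, i], Vs[, j], 1, c(0.3, 0.6))
  }
  y <- drop(t(chol(K + 1e-3 * diag(nd))) %*% rnorm(nd))
  ts <- gp_training_set(V, y, standardize = FALSE)
  fit <- train_gp(ts, restarts = 8, seed = 2)
  expect_lt(abs(log2(fit$length_scales[1] / 0.3)), 1)
  expect_lt(abs(log2(fit$length_scales[2] / 0.6)), 1)
  # achieved likelihood is at least that of the generating hyperparameters
  # (they lie inside the search box, so the optimum cannot be worse)
  expect_gte(attr(fit, "log_marginal") + 0.1,
             log_marginal_likelihood(ts, true_h))
  # determinism
  fit2 <- train_gp(ts, restarts = 8, seed = 2)
  expect_identical(fit$length_scales, fit2$length_scales)
  expect_identical(fit$signal_variance, fit2$signal_variance)
  expect_identical(fit$noise_variance, fit2$noise_variance)
})

test_that("constant labels train to a near-constant predictor", {
  V <- rbind(I = c(0, 10, 30, 50, 70, 20), n = c(1, 1, 3, 3, 8, 8))
  ts <- gp_training_set(V, rep(0.42, 6))
  fit <- train_gp(ts, restarts = 4, seed = 3)
  post <- gp_posterior(ts, fit, c(40, 5))
  expect_equal(post$mean, 0.42, tolerance = 1e-3)
})

test_that("the six-parameter surrogate predicts, floors, and validates inputs", {
  surf <- make_truth_surface()
  results <- truth_fit_results(surf)
  sets <- build_training_set(results)
  models <- train_surrogate(sets, restarts = 4, seed = 5)
  # interpolation: prediction at a training condition matches the label
  p <- predict_params(models, condition(10, 3))
  truth <- unclass(surf(10, 3))
  expect_equal(unclass(p)[["mu_max"]], truth[["mu_max"]], tolerance = 0.05)
  expect_equal(unclass(p)[["alpha"]], truth[["alpha"]], tolerance = 0.1)
  expect_named(attr(p, "variances"), param_names())
  expect_warning(predict_params(models, list(light_intensity = 20,
                                             copy_number = 2.5)),
                 "non-integer")
  # mismatched feature matrices across the six GPs are rejected
  bad <- sets
  bad$mu_max <- gp_training_set(bad$mu_max$V[, -1], bad$mu_max$L[-1])
  expect_error(train_surrogate(bad, restarts = 2, seed = 1), "same feature")
})

test_that("non-positive posterior means are floored at the parameter lower bound", {
  # linear-label mode with a dominant negative label: the posterior mean
  # near the middle point is negative and must be floored
  V <- rbind(I = c(10, 20, 30), n = c(1, 1, 1))
  sets <- lapply(param_names(), function(pn) {
    gp_training_set(V, c(1, -2, 1), label_name = pn, standardize = FALSE)
  })
  names(sets) <- param_names()
  models <- structure(lapply(sets, function(ts) {
    list(train = ts, hyper = gp_hyperparams(1, c(0.3, 0.3), 1e-8))
  }), class = "param_surrogate")
  w <- capture_warnings(p <- predict_params(models, condition(20, 1)))
  expect_match(w, "floored", all = FALSE)
  expect_length(w, 6)
  expect_equal(unclass(p)[["mu_max"]], default_param_bounds()[1, "mu_max"])
})

test_that("surrogate persistence round-trips bit-exactly", {
  surf <- make_truth_surface()
  sets <- build_training_set(truth_fit_results(surf, intensities = c(0, 30, 70)))
  models <- train_surrogate(sets, restarts = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".gp")
  write_surrogate(models, path)
  back <- read_surrogate(path)
  for (pn in param_names()) {
    expect_identical(back[[pn]]$train$V, models[[pn]]$train$V)
    expect_identical(back[[pn]]$train$L, models[[pn]]$train$L)
    expect_identical(back[[pn]]$train$ys, models[[pn]]$train$ys)
    expect_identical(back[[pn]]$hyper$signal_variance,
                     models[[pn]]$hyper$signal_variance)
    expect_identical(back[[pn]]$hyper$length_scales,
                     models[[pn]]$hyper$length_scales)
    expect_identical(back[[pn]]$hyper$noise_variance,
                     models[[pn]]$hyper$noise_variance)
  }
  # predictions are identical through the round trip
  a <- predict_params(models, condition(42, 3))
  b <- predict_params(back, condition(42, 3))
  expect_identical(unclass(a)[], unclass(b)[])
})
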