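test_that("kinetic laws satisfy their saturation identities", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    mu_m <- p[["mu_max"]]; kg <- p[["k_g"]]
    expect_identical(specific_growth_rate(0, p), 0)
    expect_equal(specific_growth_rate(kg, p), mu_m / 2)
    expect_equal(specific_growth_rate(9 * kg, p), 0.9 * mu_m)
    expect_identical(production_rate(0, p), 0)
    expect_equal(production_rate(p[["beta"]], p), p[["alpha"]] / 2)
    expect_equal(production_rate(3 * p[["beta"]], p), 0.75 * p[["alpha"]])
    expect_identical(degradation_rate(p), p[["d_p"]])
    expect_identical(uptake_rate(0, p), 0)
    expect_equal(uptake_rate(mu_m, p), p[["Y_gb"]] * mu_m)
    # linearity of uptake in the yield coefficient
    p2 <- p; p2[["Y_gb"]] <- 2 * p[["Y_gb"]]
    expect_equal(uptake_rate(0.1, p2), 2 * uptake_rate(0.1, p))
    # production monotone nondecreasing and bounded by alpha
    mus <- seq(0, 5 * p[["beta"]], length.out = 20)
    qp <- production_rate(mus, p)
    expect_true(all(diff(qp) >= 0))
    expect_true(all(qp <= p[["alpha"]]))
  }
})

test_that("kinetic laws reject out-of-domain inputs", {
  p <- test_params()
  expect_error(specific_growth_rate(-0.1, p))
  expect_error(production_rate(-1, p))
  expect_error(uptake_rate(-1, p))
  expect_error(kinetic_params(0, 0.1, 1, 0.1, 0.1, 1))
  expect_error(kinetic_params(0.3, 0.1, 1, 0.1, -0.1, 1))
  expect_error(condition(-5, 1))
  expect_error(condition(10, 2.5))
  expect_error(condition(10, -1))
})

test_that("model right-hand side composes the four kinetic laws", {
  p <- test_params()
  # starved state is a fixed point
  d0 <- model_rhs(c(c_b = 0.5, c_p = 0, c_g = 0, n = 3), p)
  expect_equal(unname(d0), c(0, 0, 0, 0))
  # half-saturation growth term
  d1 <- model_rhs(c(c_b = 1, c_p = 0, c_g = p[["k_g"]], n = 1), p)
  expect_equal(d1[["c_b"]], p[["mu_max"]] / 2)
  # copy-number derivative is exactly zero for any state
  set.seed(7)
  for (i in 1:5) {
    st <- c(c_b = runif(1, 0.01, 5), c_p = runif(1, 0, 1e4),
            c_g = runif(1, 0, 20), n = sample(0:8, 1))
    d <- model_rhs(st, p)
    expect_identical(d[["n"]], 0)
    mu <- specific_growth_rate(st[["c_g"]], p)
    expect_equal(d[["c_p"]],
                 production_rate(mu, p) - (p[["d_p"]] + mu) * st[["c_p"]])
    expect_equal(d[["c_g"]], -uptake_rate(mu, p) * st[["c_b"]])
  }
  expect_error(model_rhs(c(c_b = NaN, c_p = 0, c_g = 1, n = 1), p))
  expect_error(model_rhs(c(c_b = -1, c_p = 0, c_g = 1, n = 1), p))
})

test_that("simulation without substrate is a constant trajectory", {
  p <- test_params()
  tr <- simulate_model(c(c_b = 0.4, c_p = 0, c_g = 0), p, seq(0, 10, 1))
  expect_equal(tr$states$c_b, rep(0.4, 11))
  expect_equal(tr$states$c_p, rep(0, 11))
  expect_equal(tr$states$c_g, rep(0, 11))
})

test_that("simulation matches the exponential-growth closed form when substrate is saturating", {
  p <- kinetic_params(mu_max = 0.3, k_g = 1e-3, alpha = 1e3,
                      beta = 0.05, d_p = 1e-4, Y_gb = 0.5)
  tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 10), p, seq(0, 8, 0.5))
  expect_true(all(tr$states$c_g > 10 * p[["k_g"]]))
  expected <- 0.1 * exp(0.3 * tr$times)
  expect_true(all(abs(tr$states$c_b / expected - 1) < 0.01))
  # log-linearity: fitted slope equals mu_max within 1%
  slope <- coef(lm(log(tr$states$c_b) ~ tr$times))[2]
  expect_equal(unname(slope), 0.3, tolerance = 0.01)
})

test_that("substrate-biomass conservation and monotonicity hold along trajectories", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_params()
    cb0 <- runif(1, 0.05, 1); cg0 <- runif(1, 1, 20)
    tr <- simulate_model(c(c_b = cb0, c_p = 0, c_g = cg0), p, seq(0, 24, 2))
    total <- tr$states$c_g + p[["Y_gb"]] * tr$states$c_b
    tol <- 10 * 1e-10 * (1 + cg0 + p[["Y_gb"]] * cb0)
    expect_lt(max(abs(total - (cg0 + p[["Y_gb"]] * cb0))), max(tol, 1e-8))
    expect_true(all(diff(tr$states$c_b) >= -1e-10))
    expect_true(all(diff(tr$states$c_g) <= 1e-10))
  }
})

test_that("final biomass agrees with the conservation law after substrate exhaustion", {
  p <- test_params()
  tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 10), p, seq(0, 48, 2))
  fin <- tr$states[nrow(tr$states), ]
  expect_lt(fin$c_g, 1e-3 * 10)
  expect_equal(fin$c_b, 0.1 + 10 / p[["Y_gb"]], tolerance = 1e-4)
})

test_that("adaptive solver agrees with a fixed-step RK4 reference integrator", {
  p <- test_params()
  times <- seq(0, 24, 2)
  tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 10), p, times)
  ref <- rk4_simulate(c(c_b = 0.1, c_p = 0, c_g = 10), p, times, h = 1e-3)
  for (ch in c("c_b", "c_p", "c_g")) {
    scale <- max(abs(ref[, ch]))
    expect_lt(max(abs(tr$states[[ch]] - ref[, ch])) / scale, 1e-4)
  }
})

test_that("protein reaches the quasi-steady state q_p/(d_p + mu) under pinned growth rate", {
  # pin mu ~= mu_max by making substrate effectively inexhaustible
  p <- kinetic_params(mu_max = 0.3, k_g = 1e-3, alpha = 1e3,
                      beta = 0.05, d_p = 0.05, Y_gb = 0.1)
  mu_star <- 0.3
  horizon <- 10 / (p[["d_p"]] + mu_star)
  tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 1e6), p,
                       seq(0, horizon * 1.2, length.out = 25))
  qss <- production_rate(mu_star, p) / (p[["d_p"]] + mu_star)
  late <- tr$states$c_p[tr$times >= horizon]
  expect_true(all(abs(late / qss - 1) < 0.01))
})

test_that("trajectories reject invalid grids and report the copy number throughout", {
  p <- test_params()
  expect_error(simulate_model(c(c_b = 0.1, c_p = 0, c_g = 1), p, c(0, 0, 1)))
  expect_error(simulate_model(c(c_b = 0, c_p = 0, c_g = 1), p, c(0, 1)))
  tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 1), p, c(0, 1, 2),
                       condition = condition(30, 5))
  expect_true(all(tr$states$n == 5L))
})

test_that("trajectory tables round-trip through the delimited-text schema", {
  p <- test_params()
  tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 10), p, seq(0, 24, 3),
                       condition = condition(50, 3))
  tab <- trajectory_table(tr, replicate = 2L)
  expect_named(tab, c("time_h", "od", "protein_au", "glucose_g_per_L",
                      "copy_number", "light_umol_m2_s", "replicate"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_table(tab, path)
  back <- read_trajectory_table(path)
  expect_equal(back, tab, tolerance = 1e-12)
  expect_error(read_trajectory_table(file.path(tempdir(), "nope.tsv")),
               "not found")
})
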