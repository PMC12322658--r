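# Independent reference implementations used as oracles, plus small fixture
# builders. These deliberately avoid the package's own code paths: the
# integrator is a fixed-step classical Runge-Kutta loop, and the reference GP
# uses direct solve() on the covariance matrix with its own kernel formula.

# Fixed-step RK4 integration of the batch model.
rk4_simulate <- function(initial, params, times, h = 1e-3) {
  p <- unclass(params)
  f <- function(y) {
    cg <- max(y[3], 0)
    mu <- p[["mu_max"]] * cg / (cg + p[["k_g"]])
    qp <- p[["alpha"]] * mu / (p[["beta"]] + mu)
    c(mu * y[1],
      qp - (p[["d_p"]] + mu) * y[2],
      -p[["Y_gb"]] * mu * y[1])
  }
  y <- as.numeric(initial[c("c_b", "c_p", "c_g")])
  out <- matrix(NA_real_, length(times), 3)
  t <- times[1]
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    while (t < times[i] - 1e-12) {
      step <- min(h, times[i] - t)
      k1 <- f(y)
      k2 <- f(y + step / 2 * k1)
      k3 <- f(y + step / 2 * k2)
      k4 <- f(y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- y
  }
  colnames(out) <- c("c_b", "c_p", "c_g")
  out
}

# Reference Matern-5/2 covariance, written independently of matern52().
ref_kernel <- function(a, b, sf2, ls) {
  r2 <- sum(((a - b) / ls)^2)
  r <- sqrt(r2)
  sf2 * (1 + sqrt(5) * r + 5 / 3 * r2) * exp(-sqrt(5) * r)
}

# Reference GP posterior by direct solve() on scaled inputs: Vs (2 x nd)
# scaled features, ys scaled labels, vs scaled test point.
ref_gp_posterior <- function(Vs, ys, sf2, ls, sn2, vs) {
  nd <- ncol(Vs)
  K <- matrix(NA_real_, nd, nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      K[i, j] <- ref_kernel(Vs[, i], Vs[, j], sf2, ls)
    }
  }
  A <- K + sn2 * diag(nd)
  ks <- vapply(seq_len(nd), function(i) ref_kernel(Vs[, i], vs, sf2, ls),
               numeric(1))
  list(mean = drop(ks %*% solve(A, ys)),
       variance = ref_kernel(vs, vs, sf2, ls) - drop(ks %*% solve(A, ks)))
}

# Reference log marginal likelihood by direct determinant/solve.
ref_log_marginal <- function(Vs, ys, sf2, ls, sn2) {
  nd <- ncol(Vs)
  K <- matrix(NA_real_, nd, nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      K[i, j] <- ref_kernel(Vs[, i], Vs[, j], sf2, ls)
    }
  }
  A <- K + sn2 * diag(nd)
  -0.5 * drop(ys %*% solve(A, ys)) - 0.5 * determinant(A)$modulus[1] -
    nd / 2 * log(2 * pi)
}

# Fit-result stand-ins built directly from a truth surface (no optimization),
# for tests of the GP/hybrid stages in isolation.
truth_fit_results <- function(surface, copy_numbers = c(1, 3, 8),
                              intensities = c(0, 5, 10, 30, 50, 70)) {
  out <- list()
  for (n in copy_numbers) {
    for (I in intensities) {
      out[[length(out) + 1L]] <- list(condition = condition(I, n),
                                      params = surface(I, n))
    }
  }
  out
}

# Default kinetic parameters used across model-core tests.
test_params <- function() {
  kinetic_params(mu_max = 0.35, k_g = 0.15, alpha = 1e4,
                 beta = 0.05, d_p = 0.02, Y_gb = 1)
}

# Random positive parameter draw inside the default bounds.
random_params <- function() {
  b <- default_param_bounds()
  p <- 10^stats::runif(6, log10(b[1, ]), log10(b[2, ]))
  names(p) <- param_names()
  do.call(kinetic_params, as.list(p))
}
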