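# Canonical global-best particle swarm optimizer.
#
# Used for per-condition kinetic parameter estimation; kept generic so it is
# testable on analytic benchmarks. Deterministic given the seed.

#' Particle-swarm settings
#'
#' Defaults are the standard constriction-factor-equivalent choices
#' (inertia 0.72, cognitive = social = 1.49).
#'
#' @param swarm_size Number of particles (>= 5, unless `degenerate = TRUE`).
#' @param iterations Number of velocity/position updates.
#' @param inertia Inertia weight w at the first iteration.
#' @param inertia_final Inertia weight at the last iteration; the weight
#'   decreases linearly between the two (equal values give the classic
#'   constant-inertia update).
#' @param cognitive,social Acceleration coefficients c1, c2.
#' @param vmax_frac Velocity clamp as a fraction of the box span per
#'   dimension (`Inf` disables clamping).
#' @param seed Integer seed; identical seed + settings give bit-identical
#'   results.
#' @param degenerate Allow swarm_size < 5 (used in tests of edge behavior).
#' @return A list of class `pso_settings`.
#' @export
pso_settings <- function(swarm_size = 40, iterations = 300, inertia = 0.9,
                         inertia_final = 0.4, cognitive = 1.49, social = 1.49,
                         vmax_frac = 0.5, seed = 1L, degenerate = FALSE) {
  if (!degenerate && swarm_size < 5) stop("swarm_size must be >= 5")
  if (swarm_size < 1 || iterations < 1) stop("invalid swarm settings")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, inertia_final = inertia_final,
                 cognitive = cognitive, social = social,
                 vmax_frac = vmax_frac, seed = as.integer(seed)),
            class = "pso_settings")
}

#' Minimize a function with a global-best particle swarm
#'
#' Canonical PSO: velocities updated as
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with elementwise
#' uniform r1, r2; positions reflected at the box bounds (velocity component
#' negated on reflection). Objective values that are `NA`/`NaN` are treated
#' as `+Inf`. The best-ever position is returned.
#'
#' @param objective Function of a numeric vector returning a scalar.
#' @param lower,upper Bound vectors (finite, `lower < upper`).
#' @param settings A [pso_settings()] object.
#' @param init Optional matrix of start positions (rows = particles) used to
#'   seed the first particles, e.g. a heuristic guess; remaining particles
#'   are sampled uniformly in the box.
#' @param trace If `TRUE`, record the global-best objective after every
#'   iteration in the result's `history`.
#' @return A list of class `pso_result`: `par`, `value`, `n_evaluations`,
#'   `seed`, `converged` (best value is finite), and optionally `history`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' pso_minimize(sphere, c(-5, -5), c(5, 5),
#'              pso_settings(swarm_size = 30, iterations = 200, seed = 1))
#' @export
pso_minimize <- function(objective, lower, upper, settings = pso_settings(),
                         init = NULL, trace = FALSE) {
  d <- length(lower)
  if (length(upper) != d || d < 1) stop("lower/upper must have equal length")
  if (!all(is.finite(lower)) || !all(is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper")
  }
  ns <- settings$swarm_size
  span <- upper - lower

  evl <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(settings$seed)

  x <- matrix(stats::runif(ns * d), ns, d) * rep(span, each = ns) +
    rep(lower, each = ns)
  if (!is.null(init)) {
    init <- rbind(init)
    k <- min(nrow(init), ns)
    x[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 rep(lower, each = k)), rep(upper, each = k))
  }
  v <- (matrix(stats::runif(ns * d), ns, d) - 0.5) * rep(span, each = ns)

  fx <- apply(x, 1, evl)
  n_eval <- ns
  pbest <- x; fpbest <- fx
  gi <- which.min(fpbest)
  gbest <- pbest[gi, ]; fgbest <- fpbest[gi]
  history <- if (trace) numeric(settings$iterations) else NULL

  vmax <- settings$vmax_frac * span
  n_it <- settings$iterations
  for (it in seq_len(n_it)) {
    w <- settings$inertia +
      (settings$inertia_final - settings$inertia) *
      (if (n_it > 1) (it - 1) / (n_it - 1) else 0)
    r1 <- matrix(stats::runif(ns * d), ns, d)
    r2 <- matrix(stats::runif(ns * d), ns, d)
    gmat <- matrix(gbest, ns, d, byrow = TRUE)
    v <- w * v +
      settings$cognitive * r1 * (pbest - x) +
      settings$social * r2 * (gmat - x)
    if (is.finite(settings$vmax_frac)) {
      for (j in seq_len(d)) v[, j] <- pmin(pmax(v[, j], -vmax[j]), vmax[j])
    }
    x <- x + v
    # reflect at bounds
    for (j in seq_len(d)) {
      lo <- x[, j] < lower[j]
      x[lo, j] <- 2 * lower[j] - x[lo, j]
      v[lo, j] <- -v[lo, j]
      hi <- x[, j] > upper[j]
      x[hi, j] <- 2 * upper[j] - x[hi, j]
      v[hi, j] <- -v[hi, j]
      # pathological overshoot: clip
      x[, j] <- pmin(pmax(x[, j], lower[j]), upper[j])
    }
    fx <- apply(x, 1, evl)
    n_eval <- n_eval + ns
    imp <- fx < fpbest
    pbest[imp, ] <- x[imp, , drop = FALSE]
    fpbest[imp] <- fx[imp]
    gi <- which.min(fpbest)
    if (fpbest[gi] < fgbest) {
      fgbest <- fpbest[gi]; gbest <- pbest[gi, ]
    }
    if (trace) history[it] <- fgbest
  }

  structure(list(par = gbest, value = fgbest, n_evaluations = n_eval,
                 seed = settings$seed, converged = is.finite(fgbest),
                 history = history),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("PSO result: f = %.6g after %d evaluations (seed %d)\n",
              x$value, x$n_evaluations, x$seed))
  cat("  par:", paste(signif(x$par, 6), collapse = ", "), "\n")
  invisible(x)
}
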