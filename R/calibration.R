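# Per-condition kinetic parameter estimation.
#
# Each (light intensity, copy number) condition is fitted independently:
# replicate OD and fluorescence time courses are pooled into one weighted
# least-squares objective and minimized by particle swarm in log10-parameter
# space. The fitted six-vectors become training labels for the GP surrogates.

#' Default parameter search box
#'
#' Log-uniform plausible ranges for yeast batch kinetics: mu_max in
#' `[0.01, 1]` 1/h, k_g in `[1e-3, 5]` g/L, alpha in `[1, 1e6]` a.u./h,
#' beta in `[1e-3, 1]` 1/h, d_p in `[1e-4, 0.5]` 1/h, Y_gb in `[0.1, 10]`
#' (g/L)/OD.
#'
#' @return A 2-row matrix (`low`, `high`) with one column per parameter.
#' @export
default_param_bounds <- function() {
  b <- rbind(low = c(0.01, 1e-3, 1, 1e-3, 1e-4, 0.1),
             high = c(1, 5, 1e6, 1, 0.5, 10))
  colnames(b) <- param_names()
  b
}

check_bounds <- function(bounds) {
  if (!is.matrix(bounds) || nrow(bounds) != 2L ||
      !all(param_names() %in% colnames(bounds))) {
    stop("bounds must be a 2 x 6 matrix with rows low/high and the six parameter columns")
  }
  bounds <- bounds[, param_names(), drop = FALSE]
  if (any(bounds[1, ] <= 0) || any(bounds[1, ] >= bounds[2, ])) {
    stop("bounds must satisfy 0 < low < high for every parameter")
  }
  bounds
}

#' Define a per-condition fit problem
#'
#' @param observed Data frame in the measurement schema (see
#'   [trajectory_table()]) for a single condition: columns `time_h`, `od`,
#'   `protein_au`, `replicate` (any other columns are ignored). At least 3
#'   observation times per replicate.
#' @param initial_glucose Initial substrate concentration, g/L (the only
#'   substrate information used by the fit).
#' @param condition The [condition()] being fitted.
#' @param bounds Parameter box, default [default_param_bounds()].
#' @param weights Named nonnegative weights for the `od` and `protein`
#'   channels.
#' @param cp0 Initial protein; default 0 (dark pre-growth gives no
#'   expression before induction). Set `cp0 = NA` to use the first protein
#'   reading.
#' @return A list of class `fit_problem`.
#' @export
fit_problem <- function(observed, initial_glucose, condition,
                        bounds = default_param_bounds(),
                        weights = c(od = 1, protein = 1), cp0 = 0) {
  need <- c("time_h", "od", "protein_au", "replicate")
  if (!all(need %in% names(observed))) {
    stop("observed must have columns ", paste(need, collapse = ", "))
  }
  counts <- table(observed$replicate)
  if (any(counts < 3)) stop("each replicate needs at least 3 observation times")
  if (!is.finite(initial_glucose) || initial_glucose <= 0) {
    stop("initial_glucose must be > 0")
  }
  bounds <- check_bounds(bounds)
  if (any(weights < 0) || !all(c("od", "protein") %in% names(weights))) {
    stop("weights must be nonnegative and name od and protein")
  }
  structure(list(observed = observed, initial_glucose = initial_glucose,
                 condition = condition, bounds = bounds,
                 weights = weights, cp0 = cp0),
            class = "fit_problem")
}

# Initial state implied by the data: OD at the earliest time (averaged over
# replicates), protein 0 (or first reading), substrate = initial_glucose.
initial_state_from_problem <- function(problem) {
  obs <- problem$observed
  t0 <- min(obs$time_h)
  cb0 <- mean(obs$od[obs$time_h == t0])
  cp0 <- problem$cp0
  if (is.na(cp0)) cp0 <- max(mean(obs$protein_au[obs$time_h == t0]), 0)
  c(c_b = cb0, c_p = cp0, c_g = problem$initial_glucose)
}

#' Weighted relative least-squares fit objective
#'
#' Simulates the model at the observation times and accumulates squared
#' residuals over channels and replicates. Each channel's residual sum is
#' divided by the channel's mean squared observation so that OD (order 0.1-20)
#' and fluorescence (order 1e3-1e5 a.u.) contribute comparably, then scaled
#' by the channel weight. Solver failures return `+Inf` so a global optimizer
#' can keep going.
#'
#' @param params A [kinetic_params()] object (or positive named vector).
#' @param problem A [fit_problem()].
#' @return Dimensionless objective >= 0 (`+Inf` if the model cannot be
#'   integrated at `params`).
#' @export
fit_objective <- function(params, problem) {
  obs <- problem$observed
  times <- sort(unique(c(0, obs$time_h)))
  y0 <- initial_state_from_problem(problem)
  tr <- tryCatch(
    simulate_model(y0, params, times, condition = problem$condition),
    error = function(e) NULL)
  if (is.null(tr)) return(Inf)
  pred_od <- stats::approx(tr$times, tr$states$c_b, xout = obs$time_h)$y
  pred_pr <- stats::approx(tr$times, tr$states$c_p, xout = obs$time_h)$y
  ms_od <- mean(obs$od^2)
  ms_pr <- mean(obs$protein_au^2)
  ss_od <- sum((pred_od - obs$od)^2) / ifelse(ms_od > 0, ms_od, 1)
  ss_pr <- sum((pred_pr - obs$protein_au)^2) / ifelse(ms_pr > 0, ms_pr, 1)
  val <- problem$weights[["od"]] * ss_od + problem$weights[["protein"]] * ss_pr
  if (!is.finite(val)) Inf else val
}

# Moment-based heuristic start: yield from the OD plateau, growth rate from
# the steepest log-OD slope, alpha from the protein level near substrate
# exhaustion. Used to seed one PSO particle; the swarm does the real work.
heuristic_start <- function(problem) {
  obs <- problem$observed
  agg <- stats::aggregate(cbind(od, protein_au) ~ time_h, data = obs, FUN = mean)
  agg <- agg[order(agg$time_h), ]
  cb0 <- agg$od[1]
  cbf <- max(agg$od)
  Ygb <- problem$initial_glucose / max(cbf - cb0, 0.05)
  lo <- log(pmax(agg$od, 1e-6))
  sl <- diff(lo) / diff(agg$time_h)
  mu <- max(min(max(sl, na.rm = TRUE), 0.99), 0.011)
  dp <- 0.02
  cpf <- max(agg$protein_au)
  alpha <- max(cpf * (dp + mu), 1.5)
  c(mu_max = mu, k_g = 0.1, alpha = alpha, beta = 0.05, d_p = dp, Y_gb = Ygb)
}

#' Fit the kinetic parameters of one condition
#'
#' Runs [pso_minimize()] over [fit_objective()] in log10-parameter space
#' (positions reflected at the log-bounds). One particle is seeded with a
#' moment-based heuristic estimate; the rest start uniformly in the box.
#' The swarm's best point is then polished with chained derivative-free
#' Nelder-Mead restarts (the least-squares valley between `alpha` and `beta`
#' is long and narrow; the simplex follows it much further down than the
#' swarm alone). With `n_starts > 1`, independent swarms are run from seeds
#' derived from `settings$seed` and the best polished result is kept.
#'
#' @param problem A [fit_problem()].
#' @param settings A [pso_settings()] object.
#' @param nm_restarts Number of chained Nelder-Mead polish runs after the
#'   swarm (0 disables polishing).
#' @param n_starts Number of independent swarm starts.
#' @return A list of class `fit_result`: `params` ([kinetic_params()]),
#'   `objective_value`, `n_evaluations`, `seed`, `converged`, `condition`.
#' @export
fit_condition <- function(problem, settings = pso_settings(),
                          nm_restarts = 4, n_starts = 1) {
  bounds <- problem$bounds
  lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])
  obj_log <- function(z) {
    if (any(z < lo) || any(z > hi)) return(1e10)
    p <- 10^z
    names(p) <- param_names()
    fit_objective(p, problem)
  }
  h <- heuristic_start(problem)
  h <- pmin(pmax(h, bounds[1, ]), bounds[2, ])

  best_z <- NULL; best_val <- Inf; n_eval <- 0L; any_finite <- FALSE
  for (s in seq_len(n_starts)) {
    st <- settings
    st$seed <- if (n_starts == 1) settings$seed else
      as.integer((settings$seed + 7919L * (s - 1L)) %% .Machine$integer.max)
    res <- pso_minimize(obj_log, lo, hi, settings = st,
                        init = rbind(log10(h)))
    n_eval <- n_eval + res$n_evaluations
    if (res$converged) any_finite <- TRUE else next
    z <- res$par; val <- res$value
    for (k in seq_len(nm_restarts)) {
      nm <- stats::optim(z, obj_log, method = "Nelder-Mead",
                         control = list(maxit = 1500, reltol = 1e-14))
      n_eval <- n_eval + nm$counts[["function"]]
      improved <- nm$value < val * (1 - 1e-6)
      z <- nm$par; val <- nm$value
      if (!improved) break
    }
    if (val < best_val) { best_val <- val; best_z <- z }
  }
  if (!any_finite || is.null(best_z)) {
    stop("model never integrable within bounds")
  }
  p <- 10^best_z
  names(p) <- param_names()
  structure(list(params = do.call(kinetic_params, as.list(p)),
                 objective_value = best_val,
                 n_evaluations = n_eval,
                 seed = settings$seed, converged = TRUE,
                 condition = problem$condition),
            class = "fit_result")
}

#' Fit every condition of a measurement dataset
#'
#' Splits a measurement table by (light intensity, copy number), builds a
#' [fit_problem()] per condition (replicates pooled) and fits each one.
#' Per-condition PSO seeds are derived deterministically from
#' `settings$seed`.
#'
#' @param tab Measurement table in the [trajectory_table()] schema, all
#'   conditions together.
#' @param initial_glucose Initial substrate, g/L (scalar, or named vector
#'   keyed by `"n<i>_I<j>"`).
#' @param settings [pso_settings()].
#' @param bounds Parameter box.
#' @return A list of `fit_result` objects, ordered by copy number then
#'   light intensity.
#' @export
fit_all_conditions <- function(tab, initial_glucose = 10,
                               settings = pso_settings(),
                               bounds = default_param_bounds(),
                               nm_restarts = 4, n_starts = 1) {
  key <- interaction(tab$copy_number, tab$light_umol_m2_s, drop = TRUE)
  pieces <- split(tab, key)
  meta <- unique(tab[, c("copy_number", "light_umol_m2_s")])
  meta <- meta[order(meta$copy_number, meta$light_umol_m2_s), ]
  results <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    n <- meta$copy_number[i]; I <- meta$light_umol_m2_s[i]
    piece <- tab[tab$copy_number == n & tab$light_umol_m2_s == I, ]
    cg0 <- if (length(initial_glucose) == 1L) initial_glucose else
      initial_glucose[[sprintf("n%d_I%g", n, I)]]
    prob <- fit_problem(piece, cg0, condition(I, n), bounds = bounds)
    st <- settings
    st$seed <- as.integer((settings$seed * 1000L + i) %% .Machine$integer.max)
    results[[i]] <- fit_condition(prob, st, nm_restarts = nm_restarts,
                                  n_starts = n_starts)
  }
  results
}

#' Tabulate fit results
#'
#' @param results List of `fit_result` objects.
#' @return Data frame: `copy_number`, `light_umol_m2_s`, the six parameters,
#'   `objective`, `seed`.
#' @export
fit_report <- function(results) {
  rows <- lapply(results, function(r) {
    p <- as.list(unclass(r$params))
    cbind(data.frame(copy_number = r$condition$copy_number,
                     light_umol_m2_s = r$condition$light_intensity),
          as.data.frame(p),
          data.frame(objective = r$objective_value, seed = r$seed))
  })
  do.call(rbind, rows)
}

#' Assemble GP training sets from per-condition fits
#'
#' Builds, for each of the six kinetic parameters, a training set with
#' feature matrix `V` (2 x nd: light intensity and copy number per condition)
#' and label row `L` (the fitted value of that parameter). Rows are ordered
#' deterministically by copy number then light intensity. Duplicate
#' conditions with differing labels are kept with a warning: the GP noise
#' variance absorbs the disagreement.
#'
#' @param results List of `fit_result` objects from at least 2 distinct
#'   conditions.
#' @return Named list of six `gp_training_set` objects (see
#'   [gp_training_set()]).
#' @export
build_training_set <- function(results) {
  if (length(results) < 2L) stop("need at least 2 distinct conditions")
  I <- vapply(results, function(r) r$condition$light_intensity, numeric(1))
  n <- vapply(results, function(r) r$condition$copy_number, numeric(1))
  if (length(unique(paste(I, n))) < 2L) stop("need at least 2 distinct conditions")
  if (anyDuplicated(paste(I, n))) {
    warning("duplicate (I, n) conditions kept; GP noise will absorb label spread")
  }
  ord <- order(n, I)
  V <- rbind(I = I[ord], n = n[ord])
  out <- lapply(param_names(), function(pn) {
    L <- vapply(results, function(r) unclass(r$params)[[pn]], numeric(1))[ord]
    gp_training_set(V, L, label_name = pn, log_labels = TRUE)
  })
  names(out) <- param_names()
  out
}
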