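# Hybrid model: GP-predicted kinetic parameters embedded in the ODE system.

#' Simulate a trajectory under GP-predicted parameters
#'
#' The six kinetic parameters at `(I, n)` are predicted by the trained
#' surrogate and fed to [simulate_model()]. Deterministic given the models.
#' Conditions outside the rectangular hull of the training features require
#' `extrapolate = TRUE` (the zero-mean GP reverts to its prior off data and
#' the implied kinetics are not trustworthy); extrapolated predictions carry
#' the GP variances for inspection either way (attribute
#' `param_variances`).
#'
#' @param models A `param_surrogate` from [train_surrogate()].
#' @param condition A [condition()].
#' @param initial Named initial state (`c_b`, `c_p`, `c_g`).
#' @param times Output time grid, hours.
#' @param extrapolate Allow conditions outside the training hull.
#' @return A `trajectory` (see [simulate_model()]) with attribute
#'   `param_variances`.
#' @export
predict_trajectory <- function(models, condition, initial, times,
                               extrapolate = FALSE) {
  check_hull(models, condition, extrapolate)
  p <- predict_params(models, condition)
  tr <- simulate_model(initial, p, times, condition = condition)
  attr(tr, "param_variances") <- attr(p, "variances")
  tr
}

check_hull <- function(models, condition, extrapolate) {
  V <- models[[1]]$train$V
  inI <- condition$light_intensity >= min(V[1, ]) &
    condition$light_intensity <= max(V[1, ])
  inn <- condition$copy_number >= min(V[2, ]) &
    condition$copy_number <= max(V[2, ])
  if (!(inI && inn) && !extrapolate) {
    stop(sprintf(paste0("condition (I=%g, n=%g) lies outside the training hull; ",
                        "set extrapolate = TRUE to override"),
                 condition$light_intensity, condition$copy_number))
  }
  invisible(TRUE)
}

#' Scan the light-dose landscape predicted by the hybrid model
#'
#' For every copy number and every intensity on the grid, simulates the
#' hybrid model over the horizon and records the final protein level (total
#' and per OD) and final biomass. Per copy number, the production-maximizing
#' intensity is reported together with a plateau interval: all grid
#' intensities whose objective is within `plateau_tol` of the maximum.
#'
#' @param models A `param_surrogate`.
#' @param copy_numbers Integer vector of strains to scan.
#' @param intensity_grid Intensities to scan, umol m^-2 s^-1.
#' @param initial Initial state; default OD 0.1, no protein, 10 g/L glucose
#'   (the characterization-experiment start).
#' @param horizon Simulation horizon, hours.
#' @param objective `"total"` (final protein, default) or `"per_od"`.
#' @param plateau_tol Relative tolerance defining the optimum plateau.
#' @param extrapolate Allow grid points outside the training hull.
#' @return A list of class `dose_surface`: `surface` (data frame
#'   `copy_number`, `light_umol_m2_s`, `final_protein`, `final_od`,
#'   `protein_per_od`, `is_argmax`) and `optima` (data frame `copy_number`,
#'   `opt_intensity`, `opt_lo`, `opt_hi`, `objective`).
#' @export
scan_dose_landscape <- function(models, copy_numbers, intensity_grid,
                                initial = c(c_b = 0.1, c_p = 0, c_g = 10),
                                horizon = 24, objective = c("total", "per_od"),
                                plateau_tol = 0.02, extrapolate = FALSE) {
  objective <- match.arg(objective)
  stopifnot(length(intensity_grid) >= 1)
  times <- seq(0, horizon, length.out = 49)
  rows <- list(); opt <- list()
  for (n in copy_numbers) {
    vals <- vapply(intensity_grid, function(I) {
      tr <- predict_trajectory(models, condition(I, n), initial, times,
                               extrapolate = extrapolate)
      fin <- tr$states[nrow(tr$states), ]
      c(fin$c_p, fin$c_b)
    }, numeric(2))
    final_protein <- vals[1, ]; final_od <- vals[2, ]
    per_od <- final_protein / final_od
    score <- if (objective == "total") final_protein else per_od
    best <- max(score)
    plateau <- score >= best * (1 - plateau_tol)
    rows[[as.character(n)]] <- data.frame(
      copy_number = n, light_umol_m2_s = intensity_grid,
      final_protein = final_protein, final_od = final_od,
      protein_per_od = per_od, is_argmax = plateau)
    opt[[as.character(n)]] <- data.frame(
      copy_number = n,
      opt_intensity = intensity_grid[which.max(score)],
      opt_lo = min(intensity_grid[plateau]),
      opt_hi = max(intensity_grid[plateau]),
      objective = objective)
  }
  structure(list(surface = do.call(rbind, rows),
                 optima = do.call(rbind, opt),
                 objective = objective),
            class = "dose_surface")
}

#' @export
print.dose_surface <- function(x, ...) {
  cat(sprintf("Dose-response surface (%s protein objective):\n", x$objective))
  for (i in seq_len(nrow(x$optima))) {
    o <- x$optima[i, ]
    cat(sprintf("  n = %d: optimal I = %g umol m^-2 s^-1 (plateau %g-%g)\n",
                o$copy_number, o$opt_intensity, o$opt_lo, o$opt_hi))
  }
  invisible(x)
}

#' Export a dose surface as a delimited table
#'
#' @param surface A `dose_surface`.
#' @param path File path (tab-delimited).
#' @return The path, invisibly.
#' @export
write_dose_surface <- function(surface, path) {
  utils::write.table(surface$surface, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
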