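# Trajectory container and ODE integration.
#
# Only c_b, c_p, c_g are integrated; copy number has zero derivative by
# construction, so it is carried as a constant and replicated into the output
# rather than wasting a solver dimension.

#' Simulate a batch trajectory of the production model
#'
#' Integrates the three dynamic states (cell density, intracellular protein,
#' substrate) with a stiff-capable adaptive solver (`deSolve::lsoda`) and
#' returns a trajectory object. Substrate is analytically non-negative under
#' the Monod form; tiny negative excursions within the absolute solver
#' tolerance are clamped to zero in the output, anything larger is an error.
#'
#' @param initial Named numeric vector with `c_b` (> 0), `c_p` (>= 0) and
#'   `c_g` (>= 0), in OD, fluorescence a.u. and g/L respectively.
#' @param params A [kinetic_params()] object.
#' @param times Strictly increasing numeric grid of output times, hours.
#' @param condition Optional [condition()]; its copy number is reported in
#'   the trajectory (default: copy number 0, darkness).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A `trajectory` object: a list with `times`, `states` (data frame
#'   with columns `time_h`, `c_b`, `c_p`, `c_g`, `n`), `condition`, `params`.
#' @examples
#' p <- kinetic_params(0.35, 0.15, 1e4, 0.05, 0.02, 0.5)
#' tr <- simulate_model(c(c_b = 0.1, c_p = 0, c_g = 10), p, seq(0, 24, 2))
#' head(as.data.frame(tr))
#' @export
simulate_model <- function(initial, params, times,
                           condition = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  need <- c("c_b", "c_p", "c_g")
  if (!all(need %in% names(initial))) {
    stop("initial must name c_b, c_p and c_g")
  }
  y0 <- initial[need]
  if (!all(is.finite(y0))) stop("non-finite initial state")
  if (y0[["c_b"]] <= 0) stop("initial c_b must be > 0")
  if (y0[["c_g"]] < 0 || y0[["c_p"]] < 0) stop("initial c_g and c_p must be >= 0")
  if (is.null(condition)) condition <- condition(0, 0L)

  out <- deSolve::lsoda(y = y0, times = times, func = "odx_derivs",
                        dllname = "optodose", initfunc = "odx_initparms",
                        parms = as.numeric(unclass(params)[param_names()]),
                        rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop(sprintf("ODE solver failed near t = %g h", max(out[, 1])))
  }
  if (nrow(out) < length(times)) {
    stop(sprintf("ODE solver failed near t = %g h", out[nrow(out), 1]))
  }
  cg_out <- out[, "c_g"]
  neg <- cg_out < 0
  if (any(cg_out < -10 * atol * (1 + y0[["c_g"]]))) {
    stop("substrate went negative beyond solver tolerance; check parameters")
  }
  cg_out[neg] <- 0

  states <- data.frame(time_h = out[, "time"],
                       c_b = out[, "c_b"],
                       c_p = pmax(out[, "c_p"], 0),
                       c_g = cg_out,
                       n = condition$copy_number)
  structure(list(times = states$time_h, states = states,
                 condition = condition, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Batch trajectory: %d time points over [%g, %g] h (I = %g, n = %d)\n",
    length(x$times), min(x$times), max(x$times),
    x$condition$light_intensity, x$condition$copy_number))
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final: OD %.3g, protein %.4g a.u., glucose %.3g g/L\n",
              fin$c_b, fin$c_p, fin$c_g))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) x$states

#' Export a trajectory (or a list of them) to the measurement-table schema
#'
#' Columns: `time_h`, `od`, `protein_au`, `glucose_g_per_L`, `copy_number`,
#' `light_umol_m2_s`, `replicate`. This is the tidy schema used by all file
#' interfaces of the package.
#'
#' @param x A `trajectory` or list of trajectories.
#' @param replicate Replicate index (recycled over the list).
#' @return A data frame in the measurement schema.
#' @export
trajectory_table <- function(x, replicate = 1L) {
  if (inherits(x, "trajectory")) x <- list(x)
  replicate <- rep_len(replicate, length(x))
  rows <- mapply(function(tr, rep) {
    data.frame(time_h = tr$states$time_h,
               od = tr$states$c_b,
               protein_au = tr$states$c_p,
               glucose_g_per_L = tr$states$c_g,
               copy_number = tr$condition$copy_number,
               light_umol_m2_s = tr$condition$light_intensity,
               replicate = as.integer(rep))
  }, x, replicate, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Write / read measurement tables
#'
#' Plain tab-delimited text in the measurement schema of
#' [trajectory_table()]. Reading validates the header.
#'
#' @param tab Data frame in the measurement schema.
#' @param path File path.
#' @return `read_trajectory_table` returns the data frame.
#' @export
write_trajectory_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("time_h", "od", "protein_au", "glucose_g_per_L",
            "copy_number", "light_umol_m2_s", "replicate")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("measurement table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  tab
}
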