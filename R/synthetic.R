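# Synthetic ground truth and the simulated characterization experiment.
#
# The generator emulates the strain-characterization design: 3 EL222 copy
# numbers (1, 3, 8) x 6 light intensities (0, 5, 10, 30, 50, 70
# umol m^-2 s^-1) x 3 replicates, batch cultures started at OD 0.1 in 1%
# (10 g/L) glucose. The truth surface encodes copy-number-dependent
# phototoxicity: the product I*n drives a logistic toxicity factor on both
# growth and production, so the production-maximizing intensity decreases
# as copy number increases.

#' Default settings of the synthetic truth surface
#'
#' Closed-form parameter surfaces:
#' \itemize{
#'   \item `tox(x) = 1 / (1 + (x / x50)^p)` with `x = I * n` (phototoxic
#'     load: more EL222 activated by more light);
#'   \item activation `a(I, n) = leak + (1 - leak) * I / (I + K_I(n))` with
#'     `K_I(n) = K0 / n` (higher copy number sensitizes the promoter);
#'   \item `alpha(I, n) = alpha0 * n / (n + n_half) * a(I, n) * tox(I * n)`;
#'   \item `mu_max(I, n) = mu0 * tox(I * n)`;
#'   \item `k_g`, `beta`, `d_p`, `Y_gb` constant.
#' }
#'
#' @return Named list of surface constants.
#' @export
truth_surface_settings <- function() {
  list(mu0 = 0.35,        # 1/h, unstressed max growth rate
       alpha0 = 4e4,      # a.u./h, production ceiling
       n_half = 2,        # copies, EL222 saturation of expression capacity
       K0 = 25,           # umol m^-2 s^-1, activation half-saturation at n = 1
       leak = 0.05,       # dark leakiness of the light-driven promoter
       x50 = 58,          # phototoxic load (I*n) at half growth inhibition
       p_tox = 2,         # steepness of the toxicity response
       k_g = 0.15,        # g/L
       beta = 0.05,       # 1/h
       d_p = 0.02,        # 1/h
       Y_gb = 1)          # (g/L)/OD
}

#' Build a ground-truth parameter surface
#'
#' @param settings Named list as from [truth_surface_settings()]; all
#'   entries must be strictly positive (except `leak`, in `[0, 1)`).
#' @return A function of class `truth_surface`: `f(I, n)` returning a
#'   [kinetic_params()] object.
#' @export
make_truth_surface <- function(settings = truth_surface_settings()) {
  s <- settings
  pos <- unlist(s[setdiff(names(s), "leak")])
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all truth-surface settings must be strictly positive")
  }
  if (s$leak < 0 || s$leak >= 1) stop("leak must be in [0, 1)")
  f <- function(I, n) {
    if (I < 0 || n < 0) stop("I and n must be >= 0")
    tox <- 1 / (1 + ((I * n) / s$x50)^s$p_tox)
    act <- s$leak + (1 - s$leak) * I / (I + s$K0 / max(n, 0.5))
    alpha <- s$alpha0 * n / (n + s$n_half) * act * tox
    kinetic_params(mu_max = s$mu0 * tox,
                   k_g = s$k_g,
                   alpha = max(alpha, 1e-6),
                   beta = s$beta,
                   d_p = s$d_p,
                   Y_gb = s$Y_gb)
  }
  class(f) <- c("truth_surface", class(f))
  attr(f, "settings") <- s
  f
}

#' Default experimental design of the synthetic characterization
#'
#' @return List: `copy_numbers` (1, 3, 8), `intensities`
#'   (0, 5, 10, 30, 50, 70), `replicates` (3), `timepoints`
#'   (0, 2, 4, 6, 8, 12, 15, 24 h), `od0` (0.1), `glucose0` (10 g/L).
#' @export
default_design <- function() {
  list(copy_numbers = c(1L, 3L, 8L),
       intensities = c(0, 5, 10, 30, 50, 70),
       replicates = 3L,
       timepoints = c(0, 2, 4, 6, 8, 12, 15, 24),
       od0 = 0.1,
       glucose0 = 10)
}

#' Measurement noise model
#'
#' OD readings get multiplicative lognormal noise; fluorescence gets
#' multiplicative lognormal noise plus an additive Gaussian floor
#' (instrument background scatter).
#'
#' @param sigma_od Lognormal sigma of the OD channel.
#' @param sigma_fluor Lognormal sigma of the fluorescence channel.
#' @param fluor_floor Standard deviation of the additive fluorescence
#'   floor, a.u.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(sigma_od = 0.02, sigma_fluor = 0.02,
                        fluor_floor = 20) {
  if (sigma_od < 0 || sigma_fluor < 0 || fluor_floor < 0) {
    stop("noise magnitudes must be >= 0")
  }
  structure(list(sigma_od = sigma_od, sigma_fluor = sigma_fluor,
                 fluor_floor = fluor_floor),
            class = "noise_model")
}

#' Simulate the characterization experiment on a truth surface
#'
#' For every (copy number, intensity) condition the ground-truth parameters
#' are evaluated, the batch ODEs are integrated from the design's initial
#' state, and the noise model is applied independently per replicate.
#' Byte-identical output for identical `seed`.
#'
#' @param surface A `truth_surface` from [make_truth_surface()].
#' @param noise A [noise_model()]; use `noise_model(0, 0, 0)` for noiseless
#'   fixtures.
#' @param design Design list as from [default_design()].
#' @param seed Master integer seed; per-replicate streams are derived from
#'   it deterministically.
#' @return List: `measurements` (data frame in the [trajectory_table()]
#'   schema, noisy), `truth_params` (data frame: condition plus the six true
#'   parameters), `noiseless` (same schema as `measurements`, replicate 0,
#'   noise-free means).
#' @export
generate_design <- function(surface, noise = noise_model(),
                            design = default_design(), seed = 1L) {
  stopifnot(inherits(surface, "truth_surface"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  y0 <- c(c_b = design$od0, c_p = 0, c_g = design$glucose0)
  meas <- list(); truth <- list(); clean <- list()
  for (n in design$copy_numbers) {
    for (I in design$intensities) {
      p <- surface(I, n)
      cond <- condition(I, n)
      tr <- simulate_model(y0, p, design$timepoints, condition = cond)
      clean[[sprintf("n%d_I%g", n, I)]] <- trajectory_table(tr, replicate = 0L)
      truth[[sprintf("n%d_I%g", n, I)]] <-
        cbind(data.frame(copy_number = n, light_umol_m2_s = I),
              as.data.frame(as.list(unclass(p))))
      for (r in seq_len(design$replicates)) {
        nt <- length(design$timepoints)
        od <- tr$states$c_b *
          exp(stats::rnorm(nt, 0, noise$sigma_od))
        fl <- tr$states$c_p *
          exp(stats::rnorm(nt, 0, noise$sigma_fluor)) +
          stats::rnorm(nt, 0, noise$fluor_floor)
        meas[[sprintf("n%d_I%g_r%d", n, I, r)]] <- data.frame(
          time_h = design$timepoints,
          od = od,
          protein_au = pmax(fl, 0),
          glucose_g_per_L = NA_real_,
          copy_number = n,
          light_umol_m2_s = I,
          replicate = r)
      }
    }
  }
  list(measurements = do.call(rbind, c(meas, make.row.names = FALSE)),
       truth_params = do.call(rbind, c(truth, make.row.names = FALSE)),
       noiseless = do.call(rbind, c(clean, make.row.names = FALSE)))
}

#' Write / read a synthetic dataset as plain-text fixtures
#'
#' Writes `measurements.tsv` (measurement schema), `truth_params.tsv`
#' (condition table with the six true parameters) and `noiseless.tsv` into
#' `directory`. Values are written in full precision so the round trip
#' through [read_fixtures()] reproduces the dataset exactly.
#'
#' @param dataset List as returned by [generate_design()].
#' @param directory Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory)
  }
  wr <- function(tab, file) {
    tf <- tab
    for (j in seq_along(tf)) {
      if (is.double(tf[[j]])) tf[[j]] <- sprintf("%.17g", tf[[j]])
    }
    utils::write.table(tf, file.path(directory, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(dataset$measurements, "measurements.tsv")
  wr(dataset$truth_params, "truth_params.tsv")
  wr(dataset$noiseless, "noiseless.tsv")
  invisible(directory)
}

#' @rdname write_fixtures
#' @param directory Directory holding the three fixture files.
#' @export
read_fixtures <- function(directory) {
  rd <- function(file) {
    path <- file.path(directory, file)
    if (!file.exists(path)) stop("fixture file not found: ", path)
    tab <- utils::read.delim(path)
    # an all-NA numeric column (unmeasured glucose) reads back as logical
    for (j in seq_along(tab)) {
      if (is.logical(tab[[j]]) && all(is.na(tab[[j]]))) {
        tab[[j]] <- as.numeric(tab[[j]])
      }
    }
    tab
  }
  list(measurements = rd("measurements.tsv"),
       truth_params = rd("truth_params.tsv"),
       noiseless = rd("noiseless.tsv"))
}
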