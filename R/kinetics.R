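#' Kinetic parameter set for the batch production model
#'
#' Bundles the six kinetic parameters of the Monod-type batch model:
#' maximum specific growth rate, substrate half-saturation, maximum specific
#' production rate, growth-rate half-saturation for production, first-order
#' protein degradation rate, and the substrate-per-biomass yield coefficient.
#'
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param k_g Substrate half-saturation constant, g/L.
#' @param alpha Maximum specific production rate, fluorescence a.u./h.
#' @param beta Growth-rate half-saturation for production, 1/h.
#' @param d_p First-order protein degradation rate, 1/h.
#' @param Y_gb Substrate-per-biomass yield coefficient, (g/L)/OD.
#'
#' @return An object of class `kinetic_params`: a named numeric vector of
#'   length six. All entries must be strictly positive and finite.
#' @examples
#' kinetic_params(mu_max = 0.35, k_g = 0.15, alpha = 1e4,
#'                beta = 0.05, d_p = 0.02, Y_gb = 0.5)
#' @export
kinetic_params <- function(mu_max, k_g, alpha, beta, d_p, Y_gb) {
  p <- c(mu_max = mu_max, k_g = k_g, alpha = alpha,
         beta = beta, d_p = d_p, Y_gb = Y_gb)
  if (!all(is.finite(p)) || any(p <= 0)) {
    stop("all six kinetic parameters must be strictly positive and finite")
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (batch production model):\n")
  units <- c(mu_max = "1/h", k_g = "g/L", alpha = "a.u./h",
             beta = "1/h", d_p = "1/h", Y_gb = "(g/L)/OD")
  for (nm in names(units)) {
    cat(sprintf("  %-7s %12.6g  %s\n", nm, unclass(x)[[nm]], units[[nm]]))
  }
  invisible(x)
}

#' Canonical order of the kinetic parameter names
#' @return Character vector of the six parameter names.
#' @export
param_names <- function() {
  c("mu_max", "k_g", "alpha", "beta", "d_p", "Y_gb")
}

#' Experimental condition: light intensity and EL222 copy number
#'
#' A condition identifies one strain-times-dose experiment: the blue-light
#' photon flux density applied to the culture and the number of EL222
#' transcription-factor gene copies integrated in the strain. Copy number is
#' constant over any experiment (it is a property of the strain).
#'
#' @param light_intensity Photon flux density, umol m^-2 s^-1, >= 0.
#' @param copy_number EL222 gene copy number; a non-negative whole number.
#'   A numeric is accepted only if it is exactly whole; fractional values are
#'   rejected rather than silently rounded.
#' @return An object of class `condition` (a list with elements
#'   `light_intensity` and `copy_number`).
#' @examples
#' condition(light_intensity = 50, copy_number = 3)
#' @export
condition <- function(light_intensity, copy_number) {
  if (!is.numeric(light_intensity) || length(light_intensity) != 1L ||
      !is.finite(light_intensity) || light_intensity < 0) {
    stop("light_intensity must be a single finite number >= 0")
  }
  if (!is.numeric(copy_number) || length(copy_number) != 1L ||
      !is.finite(copy_number) || copy_number < 0 ||
      copy_number != as.integer(copy_number)) {
    stop("copy_number must be a single non-negative whole number")
  }
  structure(list(light_intensity = as.numeric(light_intensity),
                 copy_number = as.integer(copy_number)),
            class = "odx_condition")
}

#' @export
print.odx_condition <- function(x, ...) {
  cat(sprintf("Condition: I = %g umol m^-2 s^-1, EL222 copies n = %d\n",
              x$light_intensity, x$copy_number))
  invisible(x)
}

#' Specific growth rate (Monod law)
#'
#' mu = mu_max * c_g / (c_g + k_g): a saturating (hyperbolic) function of the
#' substrate concentration.
#'
#' @param c_g Substrate (glucose) concentration, g/L; must be >= 0.
#' @param params A [kinetic_params()] object.
#' @return Specific growth rate in 1/h, in `[0, mu_max)`.
#' @export
specific_growth_rate <- function(c_g, params) {
  if (any(!is.finite(c_g)) || any(c_g < 0)) {
    stop("c_g must be finite and >= 0")
  }
  params[["mu_max"]] * c_g / (c_g + params[["k_g"]])
}

#' Specific production rate
#'
#' q_p = alpha * mu / (beta + mu): production is a saturating function of the
#' growth rate, so protein expression is growth-coupled and bounded by alpha.
#'
#' @param mu Specific growth rate, 1/h; must be >= 0.
#' @inheritParams specific_growth_rate
#' @return Specific production rate, a.u./h.
#' @export
production_rate <- function(mu, params) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("mu must be finite and >= 0")
  }
  params[["alpha"]] * mu / (params[["beta"]] + mu)
}

#' Specific protein degradation rate
#'
#' Constant first-order degradation: q_d = d_p.
#'
#' @inheritParams specific_growth_rate
#' @return Degradation rate, 1/h.
#' @export
degradation_rate <- function(params) {
  params[["d_p"]]
}

#' Specific substrate uptake rate
#'
#' q_g = Y_gb * mu: uptake linearly coupled to growth through the yield
#' coefficient. The carbon source is treated generically (the model is
#' substrate-agnostic); concentrations are in g/L.
#'
#' @inheritParams production_rate
#' @return Uptake rate, (g/L) per OD per h.
#' @export
uptake_rate <- function(mu, params) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("mu must be finite and >= 0")
  }
  params[["Y_gb"]] * mu
}

#' Right-hand side of the batch model ODEs
#'
#' State derivative of the four-state system (cell density `c_b`, intracellular
#' protein `c_p`, substrate `c_g`, copy number `n`):
#' \deqn{\dot c_b = \mu c_b, \quad
#'       \dot c_p = q_p - (q_d + \mu) c_p, \quad
#'       \dot c_g = -q_g c_b, \quad
#'       \dot n = 0.}
#' Copy number is a constant of the strain, so its derivative is exactly zero.
#'
#' @param state Named numeric vector with elements `c_b` (> 0), `c_p` (>= 0),
#'   `c_g` (>= 0) and `n`.
#' @inheritParams specific_growth_rate
#' @return Named numeric derivative vector `(c_b, c_p, c_g, n)`.
#' @export
model_rhs <- function(state, params) {
  if (!all(is.finite(state))) stop("non-finite state")
  c_b <- state[["c_b"]]; c_p <- state[["c_p"]]; c_g <- state[["c_g"]]
  if (c_b <= 0) stop("c_b must be > 0")
  if (c_g < 0) stop("c_g must be >= 0")
  if (c_p < 0) stop("c_p must be >= 0")
  mu <- specific_growth_rate(c_g, params)
  qp <- production_rate(mu, params)
  qd <- degradation_rate(params)
  qg <- uptake_rate(mu, params)
  c(c_b = mu * c_b,
    c_p = qp - (qd + mu) * c_p,
    c_g = -qg * c_b,
    n = 0)
}
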