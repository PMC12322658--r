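# Structured-text run configuration for the command-line driver.

#' Read a pipeline run configuration
#'
#' YAML with any of the fields: `seed`, `sigma_od`, `sigma_fluor`,
#' `fluor_floor`, `glucose`, `swarm_size`, `iterations`, `inertia`,
#' `inertia_final`, `cognitive`, `social`, `nm_restarts`, `n_starts`,
#' `gp_restarts`, `horizon`, `objective`, and `bounds` (a mapping from
#' parameter name to a `[low, high]` pair overriding
#' [default_param_bounds()]). Unknown fields are rejected so typos fail
#' loudly. Command-line flags override config values.
#'
#' @param path YAML file path.
#' @return Named list of settings (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("seed", "sigma_od", "sigma_fluor", "fluor_floor", "glucose",
             "swarm_size", "iterations", "inertia", "inertia_final",
             "cognitive", "social", "nm_restarts", "n_starts",
             "gp_restarts", "horizon", "objective", "bounds")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$bounds)) {
    b <- default_param_bounds()
    for (pn in names(cfg$bounds)) {
      if (!pn %in% param_names()) stop("unknown parameter in bounds: ", pn)
      pair <- as.numeric(cfg$bounds[[pn]])
      if (length(pair) != 2) stop("bounds for ", pn, " must be [low, high]")
      b[, pn] <- pair
    }
    cfg$bounds <- check_bounds(b)
  }
  structure(cfg, class = "run_config")
}

# Merge: explicit flag value wins over config, config over default.
cfg_or <- function(cfg, field, flag_value, default) {
  if (!is.null(flag_value)) return(flag_value)
  if (!is.null(cfg[[field]])) return(cfg[[field]])
  default
}
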