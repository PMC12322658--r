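# Plate-reader corrections and light-unit conversion.

#' Background- and autofluorescence-corrected fluorescence per OD
#'
#' Normalized expression from raw plate-reader wells: the media blank is
#' subtracted from both fluorescence and OD of the producer strain and of a
#' non-fluorescent control grown under the same condition, each ratio is
#' formed, and the control ratio (cellular autofluorescence per OD) is
#' subtracted:
#' \deqn{\frac{F_s - F_m}{OD_s - OD_m} - \frac{F_c - F_m}{OD_c - OD_m}.}
#' Dim wells can legitimately come out negative; no clamping is applied.
#'
#' @param strain,media,control Lists or one-row data frames with numeric
#'   elements `fluorescence` and `od` (raw instrument values) for the producer
#'   strain, the cell-free media blank, and the non-fluorescent control.
#' @return Fluorescence a.u. per OD (may be negative).
#' @examples
#' normalized_fluorescence_per_od(
#'   strain  = list(fluorescence = 1000, od = 2.0),
#'   media   = list(fluorescence = 100,  od = 0.1),
#'   control = list(fluorescence = 300,  od = 2.0))
#' @export
normalized_fluorescence_per_od <- function(strain, media, control) {
  den_s <- strain$od - media$od
  den_c <- control$od - media$od
  if (!is.finite(den_s) || den_s <= 0) {
    stop("strain OD does not exceed the media blank OD")
  }
  if (!is.finite(den_c) || den_c <= 0) {
    stop("control OD does not exceed the media blank OD")
  }
  (strain$fluorescence - media$fluorescence) / den_s -
    (control$fluorescence - media$fluorescence) / den_c
}

#' Total fluorescence with autofluorescence control subtracted
#'
#' @param strain_raw Raw fluorescence of the producer strain, a.u.
#' @param control_raw Raw fluorescence of the non-fluorescent control strain
#'   under the same condition, a.u.
#' @return `strain_raw - control_raw`, a.u.
#' @export
total_fluorescence <- function(strain_raw, control_raw) {
  strain_raw - control_raw
}

# CODATA values; rounding happens only at display time.
.PLANCK <- 6.62607015e-34      # J s
.LIGHTSPEED <- 299792458       # m/s
.AVOGADRO <- 6.02214076e23     # 1/mol

#' Convert photon flux density to irradiance
#'
#' Photon flux density (umol photons m^-2 s^-1, as read by a quantum meter)
#' is converted to irradiance (W/m^2) through the photon energy
#' E = h c / lambda: `flux * 1e-6 * N_A * h * c / (lambda * 1e-9)`.
#' The mapping is exactly linear in flux and inversely proportional to
#' wavelength.
#'
#' @param flux Photon flux density, umol m^-2 s^-1, >= 0 (vectorized).
#' @param wavelength_nm Wavelength, nm, > 0. Default 462 nm, a typical
#'   blue-LED panel peak used for EL222 induction.
#' @return Irradiance, W/m^2.
#' @examples
#' photon_flux_to_irradiance(c(5, 70))   # ~1.3 and ~18.2 W/m^2 at 462 nm
#' @export
photon_flux_to_irradiance <- function(flux, wavelength_nm = 462) {
  if (any(!is.finite(flux)) || any(flux < 0)) stop("flux must be >= 0")
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop("wavelength_nm must be > 0")
  }
  flux * 1e-6 * .AVOGADRO * .PLANCK * .LIGHTSPEED / (wavelength_nm * 1e-9)
}

#' Read a raw plate table
#'
#' Tab- or comma-delimited text with columns `well`, `role`
#' (one of `strain`, `media_blank`, `no_fluor_control`), `fluorescence`,
#' `od`, `condition`. Wells with raw OD above `linearity_max` are flagged
#' with a warning (plate readers saturate; the wet protocol dilutes such
#' samples) but are not altered.
#'
#' @param path File path.
#' @param linearity_max OD linear-range ceiling used only for the flag.
#' @return Data frame of the table with an added logical column
#'   `above_linear_range`.
#' @export
read_plate_table <- function(path, linearity_max = 8) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("well", "role", "fluorescence", "od", "condition")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("plate table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  ok_roles <- c("strain", "media_blank", "no_fluor_control")
  bad <- setdiff(unique(tab$role), ok_roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  tab$above_linear_range <- tab$od > linearity_max
  if (any(tab$above_linear_range)) {
    warning(sum(tab$above_linear_range),
            " well(s) above the OD linear-range ceiling of ", linearity_max)
  }
  tab
}

#' Normalize every strain well of a plate table
#'
#' Applies [normalized_fluorescence_per_od()] and [total_fluorescence()]
#' to each `strain` well, pairing it with the `media_blank` and
#' `no_fluor_control` wells that share its `condition` label. One blank and
#' one control per condition are expected; with several, their readings are
#' averaged. The `condition` tag is free text, so both correction modes are
#' expressible: encode the timepoint in the tag (e.g. `"I5_t8h"`) for
#' time-matched blanks, or use one tag per dose for a single shared blank.
#'
#' @param plate Data frame from [read_plate_table()].
#' @return Data frame: `well`, `condition`, `fluor_per_od`, `total_fluor`.
#' @export
normalize_plate <- function(plate) {
  strains <- plate[plate$role == "strain", , drop = FALSE]
  if (!nrow(strains)) stop("plate table contains no strain wells")
  out <- lapply(seq_len(nrow(strains)), function(i) {
    s <- strains[i, ]
    blank <- plate[plate$role == "media_blank" & plate$condition == s$condition, ]
    ctrl <- plate[plate$role == "no_fluor_control" & plate$condition == s$condition, ]
    if (!nrow(blank)) stop("no media_blank for condition ", s$condition)
    if (!nrow(ctrl)) stop("no no_fluor_control for condition ", s$condition)
    m <- list(fluorescence = mean(blank$fluorescence), od = mean(blank$od))
    k <- list(fluorescence = mean(ctrl$fluorescence), od = mean(ctrl$od))
    data.frame(well = s$well, condition = s$condition,
               fluor_per_od = normalized_fluorescence_per_od(
                 list(fluorescence = s$fluorescence, od = s$od), m, k),
               total_fluor = total_fluorescence(s$fluorescence,
                                                mean(ctrl$fluorescence)))
  })
  do.call(rbind, out)
}
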