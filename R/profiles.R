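# Bragg-curve position profiles.
#
# A position profile pins the radiation quality at one location along the
# Bragg curve: a label (plateau / proximal / distal), the mean proton energy
# of the local kinetic-energy spectrum, and the lineal-energy spectrum with
# its dose-averaged mean yD. The bundled profiles cover the proximal 36% and
# 80% points of the peak (P36, P80) and the distal 20% point (D20) of a
# passively scattered 150 MeV proton beam; only their yD values are pinned,
# the spectrum shapes are parametric lognormal fits.

#' Position profile
#'
#' @param label position label, e.g. "P36", "P80", "D20".
#' @param yd_bar_keV_um dose-averaged mean lineal energy (keV/um), > 0.
#' @param cv coefficient of variation of the lognormal lineal-energy spectrum
#'   (used when `spectrum` is not supplied).
#' @param mean_proton_energy_MeV mean proton kinetic energy at the position.
#' @param depth_mm optional depth in water (mm).
#' @param spectrum optional [le_spectrum()]; its computed yD must match
#'   `yd_bar_keV_um` within 1% (calibration contract).
#' @return an object of class `position_profile`.
#' @export
position_profile <- function(label, yd_bar_keV_um, cv = 0.8,
                             mean_proton_energy_MeV = NA_real_,
                             depth_mm = NA_real_, spectrum = NULL) {
  if (!is.numeric(yd_bar_keV_um) || yd_bar_keV_um <= 0)
    stop_invalid("yd_bar_keV_um must be > 0")
  if (is.null(spectrum)) {
    spectrum <- calibrate_lognormal(yd_bar_keV_um, cv)
  } else {
    stopifnot(inherits(spectrum, "le_spectrum"))
    got <- yd_bar(spectrum)
    if (abs(got - yd_bar_keV_um) > 0.01 * yd_bar_keV_um)
      stop_invalid(sprintf("spectrum yD (%.4g) disagrees with stated yD (%.4g) by more than 1%%",
                           got, yd_bar_keV_um))
  }
  structure(list(label = as.character(label),
                 yd_bar_keV_um = yd_bar_keV_um,
                 mean_proton_energy_MeV = mean_proton_energy_MeV,
                 depth_mm = depth_mm,
                 spectrum = spectrum),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile> %s: yD = %.3g keV/um, mean E = %.3g MeV\n",
              x$label, x$yd_bar_keV_um, x$mean_proton_energy_MeV))
  invisible(x)
}

#' Bundled Bragg-curve position profiles
#'
#' Reads position profiles from a YAML file (default: the profiles bundled
#' with the package: P36, P80 and D20 with yD of 1.10, 1.80 and 7.25 keV/um
#' and mean proton energies 88.2, 33.6 and 12.9 MeV).
#'
#' @param file YAML file; `NULL` for the bundled profiles.
#' @return named list of [position_profile()] objects.
#' @export
bragg_profiles <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "beam_profiles.yaml", package = "braggdna",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(file)
  if (is.null(raw$positions)) stop_invalid("profile YAML must contain a 'positions' list")
  profs <- lapply(raw$positions, function(p) {
    position_profile(label = p$label,
                     yd_bar_keV_um = p$yd_bar_keV_um,
                     cv = if (is.null(p$cv)) 0.8 else p$cv,
                     mean_proton_energy_MeV = if (is.null(p$mean_proton_energy_MeV)) NA_real_ else p$mean_proton_energy_MeV,
                     depth_mm = if (is.null(p$depth_mm)) NA_real_ else p$depth_mm)
  })
  names(profs) <- vapply(profs, `[[`, "", "label")
  profs
}

#' Bundled reference experiment summary
#'
#' Per-position reference values (D37/D10 doses from clonogenic survival,
#' 53BP1 focus-resolution half-lives, yD, and strand-break yields and
#' fractions) for FaDu cells irradiated at the P36, P80 and D20 positions of
#' a passively scattered 150 MeV proton Bragg curve. Used to parameterise the
#' synthetic generators and as worked-example input for
#' [report_fractions()].
#'
#' @return data.frame, one row per position.
#' @export
reference_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_summary.csv",
                              package = "braggdna", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
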