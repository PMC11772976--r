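# Genome bookkeeping and nucleus geometry.

#' Genome model
#'
#' The genome is represented as equal-length chromatin segments laid end to
#' end; segments are independent for damage clustering (lesions never
#' co-cluster across a segment boundary). The effective genome size is
#' `n_segments * segment_length_bp`, by default the ~6.4 Gbps DNA content of a
#' normal human cell.
#'
#' @param genome_size_Gbps total DNA content in giga base pairs.
#' @param segment_length_bp length of one chromatin segment (bp).
#' @return an object of class `genome_model` with fields `n_segments`,
#'   `segment_length_bp` and the realised `genome_size_Gbps`.
#' @export
genome_model <- function(genome_size_Gbps = 6.4, segment_length_bp = 1e6) {
  if (!is.numeric(genome_size_Gbps) || genome_size_Gbps <= 0)
    stop_invalid("genome_size_Gbps must be > 0")
  if (!is_count(segment_length_bp) || segment_length_bp <= 0)
    stop_invalid("segment_length_bp must be a positive integer")
  n <- max(1L, as.integer(round(genome_size_Gbps * 1e9 / segment_length_bp)))
  structure(list(n_segments = n,
                 segment_length_bp = as.integer(segment_length_bp),
                 genome_size_Gbps = as.numeric(n) * as.numeric(segment_length_bp) / 1e9),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %.3f Gbps in %d segments of %d bp\n",
              x$genome_size_Gbps, x$n_segments, x$segment_length_bp))
  invisible(x)
}

#' Nucleus geometry (ellipsoid)
#'
#' Semi-axes of the ellipsoidal cell nucleus in micrometres, as extracted by
#' fitting an ellipse to maximum-intensity projections of nuclear stains plus
#' an axial semi-axis. Defaults are representative of an adherent carcinoma
#' nucleus.
#'
#' @param semi_x_um,semi_y_um,semi_z_um semi-axes (um), all > 0.
#' @return an object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(semi_x_um = 9, semi_y_um = 6, semi_z_um = 2.5) {
  ax <- c(semi_x_um, semi_y_um, semi_z_um)
  if (!is.numeric(ax) || any(!is.finite(ax)) || any(ax <= 0))
    stop_invalid("all nucleus semi-axes must be finite and > 0")
  structure(list(semi_x_um = semi_x_um, semi_y_um = semi_y_um, semi_z_um = semi_z_um),
            class = "nucleus_geometry")
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf("<nucleus_geometry> semi-axes %.2f x %.2f x %.2f um, V = %.1f um^3, mean chord = %.2f um\n",
              x$semi_x_um, x$semi_y_um, x$semi_z_um,
              ellipsoid_volume(x), mean_chord_length(x)))
  invisible(x)
}

#' Ellipsoid volume, surface and mean chord length
#'
#' The mean chord length of a convex body under uniform isotropic randomness
#' is the Cauchy formula 4V/S. The scalene-ellipsoid surface uses the
#' Thomsen approximation (p = 1.6075, relative error < 1.1%).
#'
#' @param nucleus a [nucleus_geometry()].
#' @return volume (um^3), surface (um^2) or mean chord length (um).
#' @export
mean_chord_length <- function(nucleus) {
  4 * ellipsoid_volume(nucleus) / ellipsoid_surface(nucleus)
}

#' @rdname mean_chord_length
#' @export
ellipsoid_volume <- function(nucleus) {
  stopifnot(inherits(nucleus, "nucleus_geometry"))
  4 / 3 * pi * nucleus$semi_x_um * nucleus$semi_y_um * nucleus$semi_z_um
}

#' @rdname mean_chord_length
#' @export
ellipsoid_surface <- function(nucleus) {
  stopifnot(inherits(nucleus, "nucleus_geometry"))
  p <- 1.6075
  a <- nucleus$semi_x_um^p; b <- nucleus$semi_y_um^p; cc <- nucleus$semi_z_um^p
  4 * pi * ((a * b + a * cc + b * cc) / 3)^(1 / p)
}
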