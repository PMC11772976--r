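# Lineal-energy spectra and microdosimetric means.
#
# The lineal energy y of a single energy-deposition event is the energy
# imparted divided by the mean chord length of the site (keV/um). Radiation
# quality along a Bragg curve is summarised by the dose-averaged mean
# yD = E[y^2] / E[y], which up-weights the rare dense events that dominate
# dose. Spectra are represented either as discrete (y, weight) tables or as a
# parametric lognormal frequency distribution f(y).

#' Discrete lineal-energy spectrum
#'
#' @param y lineal-energy values (keV/um), all positive.
#' @param weights frequency weights f(y); non-negative, normalized to sum to 1.
#'   Defaults to uniform weights.
#' @return an object of class `le_spectrum`.
#' @examples
#' sp <- le_spectrum(c(1, 3), c(0.5, 0.5))
#' yd_bar(sp)  # 2.5
#' @seealso [lognormal_spectrum()], [yd_bar()]
#' @export
le_spectrum <- function(y, weights = NULL) {
  if (length(y) == 0L) stop_invalid("empty spectrum: at least one y value is required")
  if (!is.numeric(y) || any(!is.finite(y)) || any(y <= 0))
    stop_invalid("lineal energies must be finite and > 0")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(weights) != length(y) || any(!is.finite(weights)) || any(weights < 0))
    stop_invalid("weights must be non-negative and match y in length")
  s <- sum(weights)
  if (s <= 0) stop_invalid("all-zero weights")
  structure(list(form = "discrete", y = as.numeric(y), w = as.numeric(weights) / s),
            class = "le_spectrum")
}

#' Lognormal lineal-energy spectrum
#'
#' Parametric frequency distribution f(y) = Lognormal(meanlog, sdlog).
#' Closed forms: frequency mean yF = exp(meanlog + sdlog^2/2), dose-averaged
#' mean yD = exp(meanlog + 3 sdlog^2 / 2).
#'
#' @param meanlog,sdlog lognormal parameters (sdlog >= 0; sdlog = 0 degenerates
#'   to a point mass at exp(meanlog)).
#' @return an object of class `le_spectrum`.
#' @export
lognormal_spectrum <- function(meanlog, sdlog) {
  stopifnot(is.numeric(meanlog), length(meanlog) == 1L, is.finite(meanlog),
            is.numeric(sdlog), length(sdlog) == 1L, is.finite(sdlog), sdlog >= 0)
  structure(list(form = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "le_spectrum")
}

#' @export
print.le_spectrum <- function(x, ...) {
  if (x$form == "lognormal") {
    cat(sprintf("<le_spectrum> lognormal(meanlog = %.4g, sdlog = %.4g), yF = %.4g, yD = %.4g keV/um\n",
                x$meanlog, x$sdlog, yf_bar(x), yd_bar(x)))
  } else {
    cat(sprintf("<le_spectrum> discrete, %d support points, yF = %.4g, yD = %.4g keV/um\n",
                length(x$y), yf_bar(x), yd_bar(x)))
  }
  invisible(x)
}

#' Dose-averaged mean lineal energy
#'
#' Computes yD = sum(w y^2) / sum(w y) for discrete spectra, or the closed
#' form exp(meanlog + 3 sdlog^2 / 2) for lognormal spectra.
#'
#' @param spectrum an [le_spectrum()].
#' @return yD in keV/um.
#' @export
yd_bar <- function(spectrum) {
  stopifnot(inherits(spectrum, "le_spectrum"))
  if (spectrum$form == "lognormal")
    return(exp(spectrum$meanlog + 1.5 * spectrum$sdlog^2))
  sum(spectrum$w * spectrum$y^2) / sum(spectrum$w * spectrum$y)
}

#' Frequency-mean lineal energy
#'
#' yF = sum(w y), or exp(meanlog + sdlog^2/2) for lognormal spectra. Always
#' yF <= yD (Cauchy--Schwarz), with equality only for a point mass.
#'
#' @inheritParams yd_bar
#' @return yF in keV/um.
#' @export
yf_bar <- function(spectrum) {
  stopifnot(inherits(spectrum, "le_spectrum"))
  if (spectrum$form == "lognormal")
    return(exp(spectrum$meanlog + 0.5 * spectrum$sdlog^2))
  sum(spectrum$w * spectrum$y)
}

#' Calibrate a lognormal spectrum to a target dose-averaged mean
#'
#' Inverts the lognormal closed form: sdlog^2 = log(1 + cv^2) and
#' meanlog = log(target) - 3 sdlog^2 / 2, so that `yd_bar()` of the returned
#' spectrum equals `target_yd_bar` exactly. `cv` is the coefficient of
#' variation of the frequency distribution.
#'
#' @param target_yd_bar desired yD (keV/um), > 0.
#' @param cv coefficient of variation of f(y), > 0 (cv -> 0 degenerates to a
#'   point mass at the target).
#' @return a lognormal [le_spectrum()].
#' @export
calibrate_lognormal <- function(target_yd_bar, cv) {
  if (!is.numeric(target_yd_bar) || length(target_yd_bar) != 1L ||
      !is.finite(target_yd_bar) || target_yd_bar <= 0)
    stop_invalid("target_yd_bar must be > 0")
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop_invalid("cv must be >= 0")
  sdlog2 <- log1p(cv^2)
  lognormal_spectrum(meanlog = log(target_yd_bar) - 1.5 * sdlog2,
                     sdlog = sqrt(sdlog2))
}

#' Sample lineal energies from a spectrum
#'
#' Independent draws from the frequency distribution f(y). The empirical
#' dose-averaged mean sum(y^2)/sum(y) converges to `yd_bar(spectrum)` as n
#' grows.
#'
#' @inheritParams yd_bar
#' @param n number of draws (n = 0 returns an empty numeric vector).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return numeric vector of n lineal energies (keV/um).
#' @export
sample_lineal_energy <- function(spectrum, n, seed = NULL) {
  stopifnot(inherits(spectrum, "le_spectrum"))
  if (!is_count(n)) stop_invalid("n must be a non-negative integer")
  if (n == 0L) return(numeric(0))
  with_seed(seed, {
    if (spectrum$form == "lognormal") {
      stats::rlnorm(n, spectrum$meanlog, spectrum$sdlog)
    } else if (length(spectrum$y) == 1L) {
      rep(spectrum$y, n)
    } else {
      sample(spectrum$y, n, replace = TRUE, prob = spectrum$w)
    }
  })
}

#' Write / read a discrete spectrum as two-column CSV
#'
#' Lognormal spectra are discretised on `n_points` quantile-spaced support
#' points before writing.
#'
#' @param spectrum an [le_spectrum()].
#' @param path file path.
#' @param n_points discretisation size for parametric spectra.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   returns a discrete [le_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path, n_points = 512L) {
  stopifnot(inherits(spectrum, "le_spectrum"))
  if (spectrum$form == "lognormal") {
    p <- (seq_len(n_points) - 0.5) / n_points
    y <- stats::qlnorm(p, spectrum$meanlog, spectrum$sdlog)
    w <- rep(1 / n_points, n_points)
  } else {
    y <- spectrum$y; w <- spectrum$w
  }
  utils::write.csv(data.frame(y_keV_um = y, weight = w), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  le_spectrum(d$y_keV_um, d$weight)
}
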