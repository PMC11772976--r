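# Linear-quadratic clonogenic survival.
#
# S(D) = exp(-alpha D - beta D^2). The fit is done on log survival, where the
# model is linear in (D, D^2): a weighted linear least-squares problem with
# non-negativity constraints on alpha and beta, solved exactly by a tiny
# active-set enumeration (unconstrained 2x2 solve, then each single-parameter
# boundary, then the origin; lowest feasible weighted SSE wins). Zero-dose
# points are used for plating-efficiency normalization and excluded from the
# residuals.

#' Fit the linear-quadratic survival model
#'
#' @param doses_Gy dose of each observation (Gy); at least 3 distinct positive
#'   doses are required.
#' @param surviving_fraction surviving fraction of each observation, in
#'   (0, 1] after plating-efficiency normalization. Replicate observations at
#'   the same dose are pooled.
#' @param sem optional per-observation standard error of the surviving
#'   fraction, used when `weighting = "sem_inverse_sq"`.
#' @param weighting `"sem_inverse_sq"` (weights 1/SEM^2; requires `sem`) or
#'   `"unweighted"`.
#' @param normalize_zero_dose divide all survival values by the mean survival
#'   at 0 Gy when 0 Gy observations are present (default `TRUE`); 0 Gy points
#'   never enter the residuals.
#' @return an object of class `lq_fit`: list with `alpha` (1/Gy), `beta`
#'   (1/Gy^2), `d37_Gy`, `d10_Gy` (NA when unattainable, i.e. alpha = beta =
#'   0), `wsse` and the fitted data.
#' @examples
#' d <- rep(c(2, 4, 6), each = 3)
#' s <- exp(-0.3 * d - 0.03 * d^2)
#' fit <- fit_lq(d, s)
#' c(fit$alpha, fit$beta)
#' @export
fit_lq <- function(doses_Gy, surviving_fraction, sem = NULL,
                   weighting = c("sem_inverse_sq", "unweighted"),
                   normalize_zero_dose = TRUE) {
  weighting <- match.arg(weighting)
  if (length(doses_Gy) != length(surviving_fraction))
    stop_invalid("doses_Gy and surviving_fraction lengths differ")
  if (any(!is.finite(doses_Gy)) || any(doses_Gy < 0))
    stop_invalid("doses must be finite and >= 0")
  if (any(!is.finite(surviving_fraction)) || any(surviving_fraction <= 0))
    stop_invalid("surviving fractions must be finite and > 0")

  sf <- surviving_fraction
  if (normalize_zero_dose && any(doses_Gy == 0)) {
    pe <- mean(sf[doses_Gy == 0])
    sf <- sf / pe
  }
  keep <- doses_Gy > 0
  d <- doses_Gy[keep]; s <- sf[keep]
  if (length(unique(d)) < 3L)
    stop_invalid("at least 3 distinct positive doses are required")
  # flat data (e.g. S = 1 everywhere) is not an error: the constrained fit
  # returns alpha = beta = 0 and D37/D10 come back NA (unattainable)

  w <- if (weighting == "sem_inverse_sq") {
    if (is.null(sem)) stop_invalid("sem required for sem_inverse_sq weighting")
    semk <- sem[keep]
    if (any(!is.finite(semk)) || any(semk <= 0))
      stop_invalid("sem must be finite and > 0")
    1 / semk^2
  } else {
    rep(1, length(d))
  }

  y <- -log(s)  # model: y = alpha d + beta d^2
  x1 <- d; x2 <- d^2
  wsse_of <- function(a, b) sum(w * (y - a * x1 - b * x2)^2)
  cand <- list()
  # unconstrained 2x2 normal equations
  A <- matrix(c(sum(w * x1 * x1), sum(w * x1 * x2),
                sum(w * x1 * x2), sum(w * x2 * x2)), 2)
  rhs <- c(sum(w * x1 * y), sum(w * x2 * y))
  ab <- tryCatch(solve(A, rhs), error = function(e) c(NA_real_, NA_real_))
  if (all(is.finite(ab)) && all(ab >= 0)) cand[[length(cand) + 1L]] <- ab
  a_only <- max(0, sum(w * x1 * y) / sum(w * x1 * x1))
  b_only <- max(0, sum(w * x2 * y) / sum(w * x2 * x2))
  cand[[length(cand) + 1L]] <- c(a_only, 0)
  cand[[length(cand) + 1L]] <- c(0, b_only)
  cand[[length(cand) + 1L]] <- c(0, 0)
  sse <- vapply(cand, function(p) wsse_of(p[1], p[2]), 0)
  best <- cand[[which.min(sse)]]
  alpha <- best[1]; beta <- best[2]

  structure(list(alpha = alpha, beta = beta,
                 d37_Gy = tryCatch(dose_at_survival(list(alpha = alpha, beta = beta), 0.37),
                                   error = function(e) NA_real_),
                 d10_Gy = tryCatch(dose_at_survival(list(alpha = alpha, beta = beta), 0.10),
                                   error = function(e) NA_real_),
                 wsse = min(sse), weighting = weighting,
                 data = data.frame(dose_Gy = d, surviving_fraction = s, weight = w)),
            class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("<lq_fit> alpha = %.4g /Gy, beta = %.4g /Gy^2, D37 = %.3g Gy, D10 = %.3g Gy\n",
              x$alpha, x$beta, x$d37_Gy, x$d10_Gy))
  invisible(x)
}

#' Predicted LQ surviving fraction
#'
#' @param params an `lq_fit` or a list with `alpha`, `beta`.
#' @param dose_Gy doses (Gy).
#' @return surviving fractions exp(-alpha D - beta D^2).
#' @export
lq_survival <- function(params, dose_Gy) {
  exp(-params$alpha * dose_Gy - params$beta * dose_Gy^2)
}

#' Dose at a given surviving fraction
#'
#' Inverts alpha D + beta D^2 = -log(s). Uses the numerically stable root
#' `2 L / (alpha + sqrt(alpha^2 + 4 beta L))` with `L = -log(s)`, which
#' reduces to `L / alpha` as beta -> 0.
#'
#' @param params an `lq_fit` or a list with `alpha`, `beta` (not both zero).
#' @param s target surviving fraction, strictly between 0 and 1.
#' @return the dose (Gy).
#' @examples
#' dose_at_survival(list(alpha = -log(0.37) / 2, beta = 0), 0.37)  # 2 Gy
#' @export
dose_at_survival <- function(params, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0 || s >= 1)
    stop_invalid("s must lie strictly between 0 and 1")
  a <- params$alpha; b <- params$beta
  if (!is.finite(a) || !is.finite(b) || a < 0 || b < 0 || (a == 0 && b == 0))
    stop_invalid("alpha + beta must be positive with alpha, beta >= 0")
  L <- -log(s)
  2 * L / (a + sqrt(a^2 + 4 * b * L))
}

#' LQ parameters from two survival quantiles
#'
#' Solves the 2x2 linear system alpha D + beta D^2 = -log(s) at (D37, 0.37)
#' and (D10, 0.10). Convenience for parameterising the synthetic survival
#' generator from reported D37/D10 doses.
#'
#' @param d37_Gy,d10_Gy doses at 37% and 10% survival (0 < d37 < d10).
#' @return list with `alpha`, `beta`.
#' @export
lq_from_doses <- function(d37_Gy, d10_Gy) {
  if (!(d37_Gy > 0) || !(d10_Gy > d37_Gy))
    stop_invalid("need 0 < d37_Gy < d10_Gy")
  A <- matrix(c(d37_Gy, d37_Gy^2, d10_Gy, d10_Gy^2), 2, byrow = TRUE)
  ab <- solve(A, c(-log(0.37), -log(0.10)))
  if (any(ab < -1e-9)) stop_invalid("quantile pair implies a negative LQ parameter")
  list(alpha = max(ab[1], 0), beta = max(ab[2], 0))
}

#' Fold change relative to a reference
#'
#' Ratios reference/target, reported to 2 decimals, as used to express the
#' reduction of D37/D10 doses at the distal position relative to the plateau.
#'
#' @param reference reference value (> 0).
#' @param target values to compare.
#' @param digits decimals to round to (default 2).
#' @return rounded reference/target ratios.
#' @examples
#' fold_change(3.0, 1.6)  # 1.88
#' @export
fold_change <- function(reference, target, digits = 2) {
  if (!is.numeric(reference) || any(reference <= 0))
    stop_invalid("reference must be > 0")
  round(reference / target, digits)
}

#' Simulate a clonogenic survival experiment
#'
#' Draws surviving fractions S(D) * exp(eps) with eps ~ Normal(0, noise_sd)
#' (multiplicative lognormal noise), including noisy 0 Gy plating controls.
#'
#' @param params list with `alpha`, `beta`.
#' @param doses_Gy dose levels (default 0, 2, 4, 6 Gy).
#' @param n_replicates replicates per dose (default 3).
#' @param noise_sd standard deviation of the log-scale noise (0 = noiseless).
#' @param seed optional integer seed.
#' @return data.frame with columns dose_Gy, replicate, surviving_fraction.
#' @export
simulate_survival <- function(params, doses_Gy = c(0, 2, 4, 6), n_replicates = 3,
                              noise_sd = 0.1, seed = NULL) {
  stopifnot(is.numeric(noise_sd), noise_sd >= 0, is_count(n_replicates), n_replicates >= 1)
  d <- rep(doses_Gy, each = n_replicates)
  with_seed(seed, {
    eps <- if (noise_sd > 0) stats::rnorm(length(d), 0, noise_sd) else 0
    data.frame(dose_Gy = d,
               replicate = rep(seq_len(n_replicates), times = length(doses_Gy)),
               surviving_fraction = lq_survival(params, d) * exp(eps))
  })
}

#' Read/write survival tables
#'
#' CSV layout: columns `position`, `dose_Gy`, `replicate`,
#' `surviving_fraction` (one row per replicate dish).
#'
#' @param x data.frame in the layout above.
#' @param path file path.
#' @return `read_survival_csv` returns the data.frame; `write_survival_csv`
#'   returns `path` invisibly.
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "dose_Gy", "surviving_fraction")
  if (!all(need %in% names(d)))
    stop_invalid("survival CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_survival_csv
#' @export
write_survival_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
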