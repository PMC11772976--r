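# Synthetic two-channel nucleus images and their quantification.
#
# Channel 1 emulates a DNA counterstain (DAPI): filled ellipses over a dark
# background. Channel 2 emulates a damage-focus stain (53BP1): diffuse
# nucleoplasmic signal plus bright Gaussian foci inside the nuclei. Both
# channels carry additive Gaussian noise. Quantification mirrors the standard
# ImageJ-style pipeline: nuclei are segmented on the DAPI channel (Otsu
# threshold, hole filling, size filter, optional watershed split, optional
# border exclusion), foci are detected per nucleus by thresholding at
# mean + k * SD of the in-nucleus signal, and nucleus semi-axes come from the
# second-moment (inertia-equivalent) ellipse of the labelled region.

#' Synthetic image configuration
#'
#' @param image_size_px image side length (pixels; square images).
#' @param pixel_size_um physical pixel size (um).
#' @param n_nuclei number of nuclei to place (non-overlapping, rejection
#'   sampled; an error is raised if they cannot be placed).
#' @param nucleus_semi_axes_px length-2 range (min, max) from which each
#'   nucleus' semi-axes are drawn uniformly (major >= minor by construction).
#' @param foci_per_nucleus Poisson mean of the number of foci per nucleus.
#' @param focus_sigma_px Gaussian sigma of a focus (pixels).
#' @param min_focus_sep_px minimum center-to-center separation between foci of
#'   one nucleus (pixels); candidate foci that cannot be placed after 100
#'   tries are dropped, and the ground-truth table records only placed foci.
#'   Keeps synthetic foci optically resolvable, as counted foci are.
#' @param focus_amplitude peak intensity of a focus above the nucleoplasm.
#' @param nucleus_level DAPI intensity inside nuclei.
#' @param nucleoplasm_level diffuse focus-channel intensity inside nuclei.
#' @param background_level intensity outside nuclei (both channels).
#' @param noise_sd additive Gaussian noise SD (both channels).
#' @param rng_seed integer seed.
#' @return an object of class `synth_image_config`.
#' @export
synth_image_config <- function(image_size_px = 512L, pixel_size_um = 0.25,
                               n_nuclei = 8L, nucleus_semi_axes_px = c(18, 30),
                               foci_per_nucleus = 12, focus_sigma_px = 1.5,
                               min_focus_sep_px = 6,
                               focus_amplitude = 0.30, nucleus_level = 0.5,
                               nucleoplasm_level = 0.08, background_level = 0.02,
                               noise_sd = 0.03, rng_seed = 1L) {
  stopifnot(is_count(image_size_px), image_size_px >= 32,
            pixel_size_um > 0, is_count(n_nuclei),
            length(nucleus_semi_axes_px) == 2L, all(nucleus_semi_axes_px > 0),
            foci_per_nucleus >= 0, focus_sigma_px > 0, min_focus_sep_px >= 0,
            focus_amplitude >= 0,
            nucleus_level > 0, background_level >= 0, noise_sd >= 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, n_nuclei = as.integer(n_nuclei),
                 nucleus_semi_axes_px = sort(nucleus_semi_axes_px),
                 foci_per_nucleus = foci_per_nucleus,
                 focus_sigma_px = focus_sigma_px, min_focus_sep_px = min_focus_sep_px,
                 focus_amplitude = focus_amplitude,
                 nucleus_level = nucleus_level, nucleoplasm_level = nucleoplasm_level,
                 background_level = background_level, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_image_config")
}

#' Render a synthetic two-channel image
#'
#' @param config a [synth_image_config()].
#' @return an object of class `synth_image`: list with `dapi` and `signal`
#'   (numeric matrices, x by y), `nuclei` (ground-truth data.frame: nucleus_id,
#'   cx, cy, a_px, b_px, theta), `foci` (ground-truth data.frame: nucleus_id,
#'   x, y) and the `config`.
#' @export
render_synthetic_image <- function(config) {
  stopifnot(inherits(config, "synth_image_config"))
  n <- config$image_size_px
  with_seed(config$rng_seed, {
    dapi <- matrix(config$background_level, n, n)
    signal <- matrix(config$background_level, n, n)
    xs <- matrix(rep(seq_len(n), n), n, n)
    ys <- matrix(rep(seq_len(n), each = n), n, n)

    nuc <- data.frame(nucleus_id = integer(0), cx = numeric(0), cy = numeric(0),
                      a_px = numeric(0), b_px = numeric(0), theta = numeric(0))
    foci <- data.frame(nucleus_id = integer(0), x = numeric(0), y = numeric(0))
    if (config$n_nuclei > 0L) {
      rmax <- config$nucleus_semi_axes_px[2]
      margin <- rmax + 3
      placed <- 0L; tries <- 0L
      while (placed < config$n_nuclei) {
        tries <- tries + 1L
        if (tries > 2000L)
          stop_invalid("could not place ", config$n_nuclei,
                       " non-overlapping nuclei; enlarge image_size_px or shrink the nuclei")
        cx <- stats::runif(1, margin, n - margin)
        cy <- stats::runif(1, margin, n - margin)
        if (placed > 0L &&
            any((nuc$cx - cx)^2 + (nuc$cy - cy)^2 < (2 * rmax + 4)^2)) next
        ab <- sort(stats::runif(2, config$nucleus_semi_axes_px[1], rmax),
                   decreasing = TRUE)
        theta <- stats::runif(1, 0, pi)
        placed <- placed + 1L
        nuc <- rbind(nuc, data.frame(nucleus_id = placed, cx = cx, cy = cy,
                                     a_px = ab[1], b_px = ab[2], theta = theta))
      }
      for (i in seq_len(nrow(nuc))) {
        ct <- cos(nuc$theta[i]); st <- sin(nuc$theta[i])
        dx <- xs - nuc$cx[i]; dy <- ys - nuc$cy[i]
        u <- (dx * ct + dy * st) / nuc$a_px[i]
        v <- (-dx * st + dy * ct) / nuc$b_px[i]
        inside <- u^2 + v^2 <= 1
        dapi[inside] <- config$nucleus_level
        signal[inside] <- config$nucleoplasm_level
        n_f <- stats::rpois(1, config$foci_per_nucleus)
        if (n_f > 0L) {
          # uniform in the ellipse interior, kept away from the rim and apart
          # from already-placed foci of this nucleus
          fx <- numeric(0); fy <- numeric(0)
          for (k in seq_len(n_f)) {
            for (try in seq_len(100L)) {
              r <- sqrt(stats::runif(1)) * 0.85
              phi <- stats::runif(1, 0, 2 * pi)
              fu <- r * cos(phi) * nuc$a_px[i]
              fv <- r * sin(phi) * nuc$b_px[i]
              px <- nuc$cx[i] + fu * ct - fv * st
              py <- nuc$cy[i] + fu * st + fv * ct
              if (length(fx) == 0L ||
                  min((fx - px)^2 + (fy - py)^2) >= config$min_focus_sep_px^2) {
                fx <- c(fx, px); fy <- c(fy, py)
                break
              }
            }
          }
          n_f <- length(fx)
        }
        if (n_f > 0L) {
          foci <- rbind(foci, data.frame(nucleus_id = i, x = fx, y = fy))
          for (k in seq_len(n_f)) {
            win <- ceiling(4 * config$focus_sigma_px)
            xr <- max(1, floor(fx[k]) - win):min(n, ceiling(fx[k]) + win)
            yr <- max(1, floor(fy[k]) - win):min(n, ceiling(fy[k]) + win)
            gx <- outer((xr - fx[k])^2, (yr - fy[k])^2, "+")
            signal[xr, yr] <- signal[xr, yr] +
              config$focus_amplitude * exp(-gx / (2 * config$focus_sigma_px^2))
          }
        }
      }
    }
    if (config$noise_sd > 0) {
      dapi <- dapi + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
      signal <- signal + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
    }
    structure(list(dapi = dapi, signal = signal, nuclei = nuc, foci = foci,
                   config = config),
              class = "synth_image")
  })
}

#' @export
print.synth_image <- function(x, ...) {
  cat(sprintf("<synth_image> %dx%d px, %d nuclei, %d ground-truth foci\n",
              nrow(x$dapi), ncol(x$dapi), nrow(x$nuclei), nrow(x$foci)))
  invisible(x)
}

#' Write / read a two-channel image as TIFF
#'
#' Channels are stored as two frames of a 32-bit float TIFF (values clipped to
#' `[0, 1]` on write).
#'
#' @param image a `synth_image` or list with `dapi` and `signal` matrices.
#' @param path file path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a list with `dapi` and `signal` matrices.
#' @export
write_image_tiff <- function(image, path) {
  arr <- array(c(pmin(pmax(image$dapi, 0), 1), pmin(pmax(image$signal, 0), 1)),
               dim = c(dim(image$dapi), 2))
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  list(dapi = img[, , 1], signal = if (dim(img)[3] >= 2) img[, , 2] else NULL)
}

#' Segment nuclei on the DNA counterstain channel
#'
#' Otsu threshold, hole filling, minimum-area filter and connected-component
#' labelling; optionally a distance-map watershed to split touching nuclei,
#' and exclusion of border-touching nuclei. A blank image yields an empty
#' mask.
#'
#' @param dapi single-channel matrix (a maximum z-projection).
#' @param min_area_px minimum object area (pixels).
#' @param exclude_border drop objects touching the image border (default
#'   `TRUE`).
#' @param split_touching apply a distance-map watershed to separate touching
#'   nuclei (default `FALSE`).
#' @return integer label matrix (0 = background, 1..K = nuclei, relabelled
#'   consecutively).
#' @export
segment_nuclei <- function(dapi, min_area_px = 200L, exclude_border = TRUE,
                           split_touching = FALSE) {
  stopifnot(is.matrix(dapi))
  img <- EBImage::Image(pmin(pmax(dapi, 0), 1))
  thr <- EBImage::otsu(img)
  mask <- img > thr
  if (sum(mask) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  mask <- EBImage::fillHull(mask)
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area_px)
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel consecutively
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Focus-detection configuration
#'
#' @param threshold_factor k in the per-nucleus threshold mean + k * SD of the
#'   focus-channel signal (default 2).
#' @param min_focus_px minimum focus area in pixels (default 4).
#' @param z_projection projection used upstream (`"max"` or `"sum"`); recorded
#'   for provenance, the detector itself operates on the supplied 2D plane.
#' @return an object of class `foci_detection_config`.
#' @export
foci_detection_config <- function(threshold_factor = 2, min_focus_px = 4L,
                                  z_projection = c("max", "sum")) {
  stopifnot(is.numeric(threshold_factor), threshold_factor > 0,
            is_count(min_focus_px), min_focus_px >= 1)
  structure(list(threshold_factor = threshold_factor,
                 min_focus_px = as.integer(min_focus_px),
                 z_projection = match.arg(z_projection)),
            class = "foci_detection_config")
}

#' Detect foci within segmented nuclei
#'
#' Per nucleus, pixels of the focus channel above mean + k * SD of the
#' in-nucleus signal are connected-component labelled; components of at least
#' `min_focus_px` pixels are scored as foci. Thresholds are per-nucleus, which
#' makes detection robust to staining gradients across the field.
#'
#' @param signal focus-channel matrix (same size as the mask).
#' @param nucleus_mask integer label matrix from [segment_nuclei()].
#' @param config a [foci_detection_config()].
#' @param pixel_size_um pixel size for area conversion (um).
#' @return data.frame, one row per focus: nucleus_id, focus_id, area_px,
#'   area_um2, mean_intensity, x, y (intensity-weighted centroid). Zero rows
#'   when the mask is empty or nothing exceeds the thresholds.
#' @export
detect_foci <- function(signal, nucleus_mask, config = foci_detection_config(),
                        pixel_size_um = 1) {
  stopifnot(is.matrix(signal), all(dim(signal) == dim(nucleus_mask)),
            inherits(config, "foci_detection_config"))
  out <- list()
  ids <- sort(unique(nucleus_mask[nucleus_mask > 0L]))
  for (id in ids) {
    inside <- nucleus_mask == id
    vals <- signal[inside]
    thr <- mean(vals) + config$threshold_factor * stats::sd(vals)
    bin <- matrix(FALSE, nrow(signal), ncol(signal))
    bin[inside] <- signal[inside] > thr
    if (!any(bin)) next
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
    k <- max(lab)
    if (k == 0) next
    for (f in seq_len(k)) {
      px <- which(lab == f)
      if (length(px) < config$min_focus_px) next
      coord <- arrayInd(px, dim(signal))
      wt <- signal[px]
      out[[length(out) + 1L]] <- data.frame(
        nucleus_id = id, focus_id = f, area_px = length(px),
        area_um2 = length(px) * pixel_size_um^2,
        mean_intensity = mean(wt),
        x = sum(coord[, 1] * wt) / sum(wt),
        y = sum(coord[, 2] * wt) / sum(wt))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(nucleus_id = integer(0), focus_id = integer(0),
                  area_px = integer(0), area_um2 = numeric(0),
                  mean_intensity = numeric(0), x = numeric(0), y = numeric(0))
}

#' Second-moment ellipse of a labelled nucleus
#'
#' Fits the inertia-equivalent ellipse of the region: eigendecomposition of
#' the pixel-coordinate covariance; for a filled ellipse the variance along a
#' principal axis is (semi-axis)^2 / 4, so semi-axes are 2 sqrt(eigenvalue).
#'
#' @param nucleus_mask integer label matrix.
#' @param nucleus_id label to fit.
#' @param pixel_size_um pixel size (um).
#' @return list with `a_um`, `b_um` (semi-axes, a >= b), `theta` (major-axis
#'   angle, radians), `area_um2` and `degenerate` (TRUE for regions too small
#'   or thin to fit, in which case axes are `NA`).
#' @export
fit_nucleus_ellipse <- function(nucleus_mask, nucleus_id, pixel_size_um = 1) {
  px <- which(nucleus_mask == nucleus_id)
  if (length(px) == 0L) stop_invalid("no such nucleus label: ", nucleus_id)
  coord <- arrayInd(px, dim(nucleus_mask))
  area <- length(px) * pixel_size_um^2
  if (length(px) < 5L) {
    return(list(a_um = NA_real_, b_um = NA_real_, theta = NA_real_,
                area_um2 = area, degenerate = TRUE))
  }
  cv <- stats::cov(coord) * (nrow(coord) - 1) / nrow(coord)  # population moments
  # + 1/12 per axis for the pixel extent (a pixel is a unit square, not a point)
  cv <- cv + diag(1 / 12, 2)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[2] <= 0) {
    return(list(a_um = NA_real_, b_um = NA_real_, theta = NA_real_,
                area_um2 = area, degenerate = TRUE))
  }
  list(a_um = 2 * sqrt(e$values[1]) * pixel_size_um,
       b_um = 2 * sqrt(e$values[2]) * pixel_size_um,
       theta = atan2(e$vectors[2, 1], e$vectors[1, 1]) %% pi,
       area_um2 = area, degenerate = FALSE)
}

#' Per-nucleus measurements of a two-channel image
#'
#' Combines segmentation, focus detection and ellipse fitting into the
#' standard per-nucleus measurement table: nuclear area, mean and integrated
#' DNA-stain density, focus count, mean focus size and intensity, and fitted
#' semi-axes.
#'
#' @param dapi,signal channel matrices.
#' @param config a [foci_detection_config()].
#' @param pixel_size_um pixel size (um).
#' @param nucleus_mask optional precomputed label matrix; segmented from
#'   `dapi` when `NULL`.
#' @param ... passed to [segment_nuclei()].
#' @return data.frame, one row per nucleus: nucleus_id, area_um2, dapi_mean,
#'   dapi_integrated_density, n_foci, mean_focus_size_um2,
#'   mean_focus_intensity, semi_axis_a_um, semi_axis_b_um.
#' @export
measure_nuclei <- function(dapi, signal, config = foci_detection_config(),
                           pixel_size_um = 1, nucleus_mask = NULL, ...) {
  if (is.null(nucleus_mask)) nucleus_mask <- segment_nuclei(dapi, ...)
  ids <- sort(unique(nucleus_mask[nucleus_mask > 0L]))
  foci <- detect_foci(signal, nucleus_mask, config, pixel_size_um)
  rows <- lapply(ids, function(id) {
    inside <- nucleus_mask == id
    ell <- fit_nucleus_ellipse(nucleus_mask, id, pixel_size_um)
    fi <- foci[foci$nucleus_id == id, , drop = FALSE]
    data.frame(nucleus_id = id,
               area_um2 = sum(inside) * pixel_size_um^2,
               dapi_mean = mean(dapi[inside]),
               dapi_integrated_density = sum(dapi[inside]),
               n_foci = nrow(fi),
               mean_focus_size_um2 = if (nrow(fi)) mean(fi$area_um2) else NA_real_,
               mean_focus_intensity = if (nrow(fi)) mean(fi$mean_intensity) else NA_real_,
               semi_axis_a_um = ell$a_um, semi_axis_b_um = ell$b_um)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(nucleus_id = integer(0), area_um2 = numeric(0),
                  dapi_mean = numeric(0), dapi_integrated_density = numeric(0),
                  n_foci = integer(0), mean_focus_size_um2 = numeric(0),
                  mean_focus_intensity = numeric(0), semi_axis_a_um = numeric(0),
                  semi_axis_b_um = numeric(0))
}

#' Match detected foci to ground truth
#'
#' Greedy nearest-first matching of detected focus centroids to ground-truth
#' centers within `max_dist_px`; reports recall, precision and the matched
#' pairs. Used to validate detection on synthetic images.
#'
#' @param detected data.frame from [detect_foci()] (columns x, y).
#' @param truth ground-truth data.frame (columns x, y).
#' @param max_dist_px maximum center distance for a match.
#' @return list with `recall`, `precision`, `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
match_foci <- function(detected, truth, max_dist_px) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0,
                n_matched = 0L, n_detected = nd, n_truth = nt))
  d2 <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  matched <- 0L
  repeat {
    m <- min(d2)
    if (!is.finite(m) || m > max_dist_px^2) break
    hit <- which(d2 == m, arr.ind = TRUE)[1, ]
    matched <- matched + 1L
    d2[hit[1], ] <- Inf
    d2[, hit[2]] <- Inf
  }
  list(recall = matched / nt, precision = matched / nd,
       n_matched = matched, n_detected = nd, n_truth = nt)
}
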