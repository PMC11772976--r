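test_that("rendering is seeded and blank without nuclei", {
  cfg0 <- synth_image_config(n_nuclei = 0L, noise_sd = 0, rng_seed = 1)
  im0 <- render_synthetic_image(cfg0)
  expect_true(all(im0$dapi == cfg0$background_level))
  expect_identical(nrow(im0$nuclei), 0L)
  expect_identical(max(segment_nuclei(im0$dapi)), 0L)
  cfg <- synth_image_config(rng_seed = 7)
  expect_identical(render_synthetic_image(cfg)$signal,
                   render_synthetic_image(cfg)$signal)
})

test_that("ground-truth focus totals follow the Poisson expectation", {
  # min_focus_sep_px = 0 disables placement thinning so counts are pure Poisson
  total <- 0L; nn <- 0L
  for (s in 1:7) {
    cfg <- synth_image_config(n_nuclei = 8L, foci_per_nucleus = 20,
                              min_focus_sep_px = 0, rng_seed = 100 + s)
    im <- render_synthetic_image(cfg)
    total <- total + nrow(im$foci); nn <- nn + nrow(im$nuclei)
  }
  expect_identical(nn, 56L)
  # 56 nuclei * 20 = 1120 expected; 4 sigma ~ 134
  expect_lt(abs(total - 1120), 4 * sqrt(1120))
})

test_that("segmentation recovers the ground-truth nuclei and their geometry", {
  cfg <- synth_image_config(rng_seed = 42)
  im <- render_synthetic_image(cfg)
  mask <- segment_nuclei(im$dapi)
  expect_identical(max(mask), nrow(im$nuclei))
  # measured area within 3% of pi*a*b, semi-axes within 2%
  meas <- measure_nuclei(im$dapi, im$signal, pixel_size_um = cfg$pixel_size_um,
                         nucleus_mask = mask)
  for (k in seq_len(nrow(meas))) {
    # match segmented label to ground-truth nucleus by centroid proximity
    px <- which(mask == meas$nucleus_id[k], arr.ind = TRUE)
    cx <- mean(px[, 1]); cy <- mean(px[, 2])
    gt <- im$nuclei[which.min((im$nuclei$cx - cx)^2 + (im$nuclei$cy - cy)^2), ]
    expect_equal(meas$area_um2[k],
                 pi * gt$a_px * gt$b_px * cfg$pixel_size_um^2, tolerance = 0.03)
    expect_equal(meas$semi_axis_a_um[k], gt$a_px * cfg$pixel_size_um, tolerance = 0.02)
    expect_equal(meas$semi_axis_b_um[k], gt$b_px * cfg$pixel_size_um, tolerance = 0.02)
  }
})

test_that("watershed splitting separates touching nuclei", {
  # two discs drawn so their masks touch
  n <- 128
  xs <- matrix(rep(1:n, n), n); ys <- t(xs)
  dapi <- matrix(0.02, n, n)
  dapi[(xs - 45)^2 + (ys - 64)^2 <= 20^2] <- 0.5
  dapi[(xs - 83)^2 + (ys - 64)^2 <= 20^2] <- 0.5
  merged <- segment_nuclei(dapi, split_touching = FALSE)
  expect_identical(max(merged), 1L)
  split <- segment_nuclei(dapi, split_touching = TRUE)
  expect_identical(max(split), 2L)
})

test_that("border-touching nuclei are excluded when requested", {
  n <- 128
  xs <- matrix(rep(1:n, n), n); ys <- t(xs)
  dapi <- matrix(0.02, n, n)
  dapi[(xs - 5)^2 + (ys - 64)^2 <= 20^2] <- 0.5   # clipped by the border
  dapi[(xs - 90)^2 + (ys - 64)^2 <= 20^2] <- 0.5  # interior
  expect_identical(max(segment_nuclei(dapi, exclude_border = TRUE)), 1L)
  expect_identical(max(segment_nuclei(dapi, exclude_border = FALSE)), 2L)
})

test_that("ellipse fitting recovers semi-axes from second moments", {
  n <- 101
  xs <- matrix(rep(1:n, n), n); ys <- t(xs)
  mask <- matrix(0L, n, n)
  mask[((xs - 51) / 30)^2 + ((ys - 51) / 20)^2 <= 1] <- 1L
  e <- fit_nucleus_ellipse(mask, 1L)
  expect_equal(e$a_um, 30, tolerance = 0.02)
  expect_equal(e$b_um, 20, tolerance = 0.02)
  expect_false(e$degenerate)
  # circle: a == b
  circ <- matrix(0L, n, n)
  circ[(xs - 51)^2 + (ys - 51)^2 <= 15^2] <- 1L
  ec <- fit_nucleus_ellipse(circ, 1L)
  expect_equal(ec$a_um, ec$b_um, tolerance = 0.02)
  # 1-pixel region is degenerate
  tiny <- matrix(0L, n, n); tiny[50, 50] <- 1L
  expect_true(fit_nucleus_ellipse(tiny, 1L)$degenerate)
  expect_error(fit_nucleus_ellipse(tiny, 99L), "no such nucleus")
})

test_that("uniform signal yields no foci and the threshold factor is monotone", {
  cfg <- synth_image_config(foci_per_nucleus = 0, rng_seed = 3)
  im <- render_synthetic_image(cfg)
  mask <- segment_nuclei(im$dapi)
  det <- detect_foci(im$signal, mask, foci_detection_config())
  expect_identical(nrow(det), 0L)
  cfg2 <- synth_image_config(rng_seed = 4)
  im2 <- render_synthetic_image(cfg2)
  mask2 <- segment_nuclei(im2$dapi)
  counts <- vapply(c(2, 4, 6), function(k) {
    nrow(detect_foci(im2$signal, mask2, foci_detection_config(threshold_factor = k)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("bright foci are detected with high recall and precision", {
  # amplitude 10x noise SD, ~12 foci per nucleus
  tot <- list(m = 0L, d = 0L, t = 0L)
  for (s in c(7, 11)) {
    cfg <- synth_image_config(rng_seed = s)
    im <- render_synthetic_image(cfg)
    mask <- segment_nuclei(im$dapi)
    det <- detect_foci(im$signal, mask, foci_detection_config(), cfg$pixel_size_um)
    m <- match_foci(det, im$foci, cfg$focus_sigma_px)
    tot$m <- tot$m + m$n_matched; tot$d <- tot$d + m$n_detected
    tot$t <- tot$t + m$n_truth
  }
  expect_gte(tot$m / tot$t, 0.95)  # recall
  expect_gte(tot$m / tot$d, 0.95)  # precision
})

test_that("an exact count of well-separated bright foci is found", {
  cfg <- synth_image_config(n_nuclei = 1L, foci_per_nucleus = 0, rng_seed = 5,
                            image_size_px = 128L)
  im <- render_synthetic_image(cfg)
  ctr <- c(im$nuclei$cx[1], im$nuclei$cy[1])
  sig <- im$signal
  offs <- cbind(c(-8, 8, 0, -8, 8), c(-8, -8, 0, 8, 8))
  for (k in 1:5) {
    fx <- ctr[1] + offs[k, 1]; fy <- ctr[2] + offs[k, 2]
    xr <- (round(fx) - 6):(round(fx) + 6); yr <- (round(fy) - 6):(round(fy) + 6)
    g <- outer((xr - fx)^2, (yr - fy)^2, "+")
    sig[xr, yr] <- sig[xr, yr] + 8 * cfg$noise_sd * exp(-g / (2 * 1.5^2))
  }
  mask <- segment_nuclei(im$dapi)
  det <- detect_foci(sig, mask, foci_detection_config())
  expect_identical(nrow(det), 5L)
})

test_that("TIFF round-trip preserves both channels", {
  cfg <- synth_image_config(image_size_px = 64L, n_nuclei = 1L,
                            nucleus_semi_axes_px = c(10, 14), rng_seed = 6)
  im <- render_synthetic_image(cfg)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(im, path)
  back <- read_image_tiff(path)
  expect_equal(dim(back$dapi), dim(im$dapi))
  # 16-bit storage: compare with an absolute quantization bound
  expect_lt(max(abs(back$dapi - pmin(pmax(im$dapi, 0), 1))), 1e-4)
  expect_lt(max(abs(back$signal - pmin(pmax(im$signal, 0), 1))), 1e-4)
})
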