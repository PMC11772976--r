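test_that("sample_lineal_energy draws from the frequency distribution", {
  # point mass
  expect_equal(sample_lineal_energy(le_spectrum(5, 1), 3, seed = 1), c(5, 5, 5))
  expect_identical(sample_lineal_energy(le_spectrum(5, 1), 0), numeric(0))
  # empirical dose-averaged mean converges to the spectrum's
  sp <- lognormal_spectrum(0, 0.5)
  y <- sample_lineal_energy(sp, 1e5, seed = 42)
  expect_equal(sum(y^2) / sum(y), yd_bar(sp), tolerance = 0.02)
  # discrete spectra too
  spd <- le_spectrum(c(1, 3), c(0.5, 0.5))
  yd <- sample_lineal_energy(spd, 2e4, seed = 7)
  expect_equal(sum(yd^2) / sum(yd), 2.5, tolerance = 0.03)
  expect_error(sample_lineal_energy(spd, -1), "non-negative")
})

test_that("mean chord length is 4V/S (exact on a sphere)", {
  sph <- nucleus_geometry(5, 5, 5)
  expect_equal(ellipsoid_volume(sph), 4 / 3 * pi * 125)
  expect_equal(ellipsoid_surface(sph), 4 * pi * 25, tolerance = 1e-12)
  expect_equal(mean_chord_length(sph), 4 * 5 / 3)
  expect_error(nucleus_geometry(0, 1, 1), "semi-axes")
})

test_that("genome bookkeeping covers the genome in equal segments", {
  g <- genome_model(6.4, 1e6)
  expect_identical(g$n_segments, 6400L)
  expect_equal(g$genome_size_Gbps, 6.4)
  g2 <- genome_model(0.005, 1e6)  # tiny genome still gets one segment
  expect_gte(g2$n_segments, 1L)
})

test_that("zero dose yields an empty lesion set and generation is reproducible", {
  prof <- position_profile("T", 2, cv = 0.8)
  gen <- genome_model(0.1, 1e5)
  nuc <- small_nucleus()
  ls0 <- generate_lesion_set(prof, gen, nuc, track_config(dose_Gy = 0, seed = 3))
  expect_identical(nrow(ls0$lesions), 0L)
  cfg <- track_config(dose_Gy = 2, seed = 123)
  ls1 <- generate_lesion_set(prof, gen, nuc, cfg)
  ls2 <- generate_lesion_set(prof, gen, nuc, cfg)
  expect_identical(serialize(ls1, NULL), serialize(ls2, NULL))
  ls3 <- generate_lesion_set(prof, gen, nuc, track_config(dose_Gy = 2, seed = 124))
  expect_false(identical(ls1$lesions, ls3$lesions))
  # lesion fields are well-formed
  expect_true(all(ls1$lesions$pos_bp >= 0 & ls1$lesions$pos_bp < gen$segment_length_bp))
  expect_true(all(ls1$lesions$strand %in% 1:2))
  expect_true(all(ls1$lesions$kind %in% c("strand_break", "base_lesion")))
  expect_true(all(ls1$lesions$source %in% c("direct", "indirect")))
})

test_that("expected lesion counts scale linearly with dose", {
  prof <- position_profile("T", 2, cv = 0.8)
  gen <- genome_model(0.1, 1e5)
  nuc <- small_nucleus()
  mean_count <- function(dose, seeds) {
    mean(vapply(seeds, function(s) {
      nrow(generate_lesion_set(prof, gen, nuc,
                               track_config(dose_Gy = dose, seed = s))$lesions)
    }, 0))
  }
  n2 <- mean_count(2, 1:200)
  n4 <- mean_count(4, 201:400)
  n1 <- mean_count(1, 401:600)
  expect_equal(n4 / n2, 2, tolerance = 0.05)
  expect_equal(n2 / n1, 2, tolerance = 0.05)
})

test_that("fluence mode runs a fixed number of primaries", {
  prof <- position_profile("T", 2, cv = 0.5)
  ls <- generate_lesion_set(prof, genome_model(0.1, 1e5), small_nucleus(),
                            track_config(dose_Gy = NULL, n_primaries = 100, seed = 9))
  expect_identical(ls$n_tracks, 100L)
  expect_gt(ls$dose_Gy, 0)  # dose estimated from deposited energy
})

test_that("lesion TSV and SDD exports round-trip / are well-formed", {
  prof <- position_profile("D20", 7.25)
  gen <- genome_model(0.05, 1e5)
  ls <- generate_lesion_set(prof, gen, small_nucleus(),
                            track_config(dose_Gy = 1, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lesion_tsv(ls, path)
  back <- read_lesion_tsv(path)
  expect_equal(back$lesions, ls$lesions)
  expect_equal(back$dose_Gy, ls$dose_Gy)
  expect_identical(back$position, "D20")
  expect_identical(back$seed, 5L)

  sdd <- withr::local_tempfile(fileext = ".sdd")
  write_sdd(ls, sdd)
  lines <- readLines(sdd)
  hdr_end <- grep("EndOfHeader", lines)
  expect_length(hdr_end, 1L)
  expect_identical(length(lines) - hdr_end, nrow(ls$lesions))
  expect_match(lines[1], "SDD version")
})

test_that("stage_seed fan-out is deterministic, bounded and token-sensitive", {
  expect_identical(stage_seed(17, "tracks", "D20", 3), stage_seed(17, "tracks", "D20", 3))
  s <- vapply(1:50, function(i) stage_seed(1, "tracks", "P36", i), 0L)
  expect_identical(length(unique(s)), 50L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(stage_seed(1, "a") == stage_seed(2, "a"))
})
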