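test_that("opposite-strand breaks pair into a DSB iff within the 10 bp window", {
  cfg <- classifier_config()
  # 5 bp apart -> one DSB site
  res <- classify_damage(lesions(L(100, 1), L(105, 2)), cfg)
  expect_identical(nrow(res$sites), 1L)
  expect_identical(res$sites$class, "DSB")
  expect_identical(nrow(res$pairs), 1L)
  # exactly at the window -> still one DSB
  res10 <- classify_damage(lesions(L(100, 1), L(110, 2)), cfg)
  expect_identical(res10$sites$class, "DSB")
  # 11 bp apart -> two separate SSB sites
  res11 <- classify_damage(lesions(L(100, 1), L(111, 2)), cfg)
  expect_identical(nrow(res11$sites), 2L)
  expect_identical(res11$sites$class, c("SSB", "SSB"))
  expect_identical(nrow(res11$pairs), 0L)
  # same strand never pairs
  expect_identical(classify_damage(lesions(L(100, 1), L(105, 1)), cfg)$sites$class, "SSB")
  # empty input
  empty <- classify_damage(lesions(L(1, 1))[0, ], cfg)
  expect_identical(nrow(empty$sites), 0L)
})

test_that("complexity labels are hierarchical and mutually exclusive", {
  cfg <- classifier_config()
  # DSB plus a base lesion within 10 bp -> DSB+
  plus <- classify_damage(
    lesions(L(100, 1), L(105, 2), L(108, 1, kind = "base_lesion")), cfg)
  expect_identical(plus$sites$class, "DSB_plus")
  # two DSBs 50 bp apart in one segment -> one DSB++ entity
  pp <- classify_damage(
    lesions(L(100, 1), L(105, 2), L(150, 1), L(155, 2)), cfg)
  expect_identical(pp$n_dsbpp_groups, 1L)
  expect_true(all(pp$sites$class == "DSB_plusplus"))
  expect_identical(nrow(pp$pairs), 2L)
  # two DSBs 200 bp apart -> two plain DSBs
  far <- classify_damage(
    lesions(L(100, 1), L(105, 2), L(300, 1), L(305, 2)), cfg)
  expect_identical(far$sites$class, c("DSB", "DSB"))
  expect_identical(far$n_dsbpp_groups, 0L)
  # segment boundaries isolate: same positions on different segments never merge
  seg <- classify_damage(
    lesions(L(100, 1, segment = 1), L(105, 2, segment = 2)), cfg)
  expect_identical(seg$sites$class, c("SSB", "SSB"))
  # base lesions alone are never scored
  base <- classify_damage(lesions(L(100, 1, kind = "base_lesion")), cfg)
  expect_identical(base$sites$class, "base_only")
})

test_that("source typing distinguishes direct, indirect, hybrid and mixed", {
  cfg <- classifier_config()
  cls <- function(...) classify_damage(lesions(...), cfg)$sites$source_type
  expect_identical(cls(L(100, 1, source = "direct"), L(105, 2, source = "direct")),
                   "direct")
  expect_identical(cls(L(100, 1, source = "indirect"), L(105, 2, source = "indirect")),
                   "indirect")
  expect_identical(cls(L(100, 1, source = "direct"), L(105, 2, source = "indirect")),
                   "hybrid")
  expect_identical(cls(L(100, 1, source = "direct"), L(105, 2, source = "direct"),
                       L(103, 1, kind = "base_lesion", source = "indirect")),
                   "mixed")
  # the per-site rule function agrees
  expect_identical(classify_source(c("direct", "direct")), "direct")
  expect_identical(classify_source(c("direct", "indirect")), "hybrid")
  expect_identical(classify_source(c("direct", "direct"), "indirect"), "mixed")
  expect_identical(classify_source(character(0)), "none")
})

test_that("tally normalizes yields per Gy per Gbps and derives ratios", {
  cfg <- classifier_config()
  # 29 SSBs and 1 DSB at 1 Gy on a 1 Gbps genome
  rows <- do.call(rbind, lapply(1:29, function(i) L(1000 * i, 1)))
  rows <- rbind(rows, L(50000, 1), L(50005, 2))
  sites <- classify_damage(rows, cfg)
  tal <- tally_damage(sites, dose_Gy = 1, genome = genome_model(1, 1e6))
  expect_equal(unname(tal$ratios["SSB_over_DSB"]), 29)
  expect_equal(unname(tal$yields["SSB_per_Gy_Gbps"]), 29)
  expect_equal(unname(tal$yields["DSB_per_Gy_Gbps"]), 1)
  expect_equal(unname(tal$ratios["DSB_fraction_of_SB"]), 1 / 30)
  # zero dose is an error; empty input gives zero counts and NA ratios
  expect_error(tally_damage(sites, dose_Gy = 0, genome = genome_model(1, 1e6)),
               "dose")
  empty <- tally_damage(classify_damage(rows[0, ], cfg), dose_Gy = 1,
                        genome = genome_model(1, 1e6))
  expect_identical(unname(empty$counts[c("SSB", "DSB_total")]), c(0L, 0L))
  expect_true(is.na(empty$ratios["SSB_over_DSB"]))
})

test_that("a DSB++ contributes constituents to the DSB total and once to the complex count", {
  cfg <- classifier_config()
  pp <- classify_damage(
    lesions(L(100, 1), L(105, 2), L(150, 1), L(155, 2)), cfg)
  tal <- tally_damage(pp, 1, genome_model(1, 1e6))
  expect_identical(unname(tal$counts["DSB_total"]), 2L)
  expect_identical(unname(tal$counts["DSB_plusplus"]), 1L)
  expect_equal(unname(tal$ratios["complex_DSB_fraction_of_DSB"]), 0.5)
  tal1 <- tally_damage(pp, 1, genome_model(1, 1e6), dsbpp_counts = "once")
  expect_identical(unname(tal1$counts["DSB_total"]), 1L)
})

test_that("sweep classification equals the exhaustive brute-force oracle", {
  set.seed(202)
  for (i in 1:250) {
    les <- random_lesions(sample(1:50, 1),
                          max_pos = sample(c(60L, 150L, 250L), 1),
                          n_segments = sample(1:2, 1))
    expect_matches_oracle(les)
  }
  # and under a non-default window pair
  set.seed(203)
  for (i in 1:50) {
    les <- random_lesions(sample(1:40, 1), max_pos = 120L)
    expect_matches_oracle(les, dsb_window = 5L, dsbpp_segment = 40L)
  }
})

test_that("every lesion lands in exactly one site and order does not matter", {
  set.seed(77)
  for (i in 1:30) {
    les <- random_lesions(sample(5:50, 1), max_pos = 200L)
    res <- classify_damage(les)
    # conservation: the site-assigned lesion table is a permutation of the input
    expect_identical(sort(res$lesions$lesion_id), seq_len(nrow(les)))
    expect_identical(sum(res$sites$n_lesions), nrow(les))
    # permutation invariance of the tally
    perm <- les[sample.int(nrow(les)), , drop = FALSE]
    t1 <- tally_damage(classify_damage(les), 1, genome_model(1, 1e6))
    t2 <- tally_damage(classify_damage(perm), 1, genome_model(1, 1e6))
    expect_identical(t1$counts, t2$counts)
  }
})

test_that("enlarging windows never loses DSBs or demotes DSB++ membership", {
  set.seed(99)
  for (i in 1:30) {
    les <- random_lesions(sample(10:50, 1), max_pos = 150L)
    dsb_counts <- vapply(c(5L, 10L, 20L), function(w) {
      nrow(classify_damage(les, classifier_config(w, 1000L))$pairs)
    }, 0L)
    expect_true(all(diff(dsb_counts) >= 0))
    pp_sites <- vapply(c(20L, 100L, 400L), function(wpp) {
      res <- classify_damage(les, classifier_config(10L, wpp))
      sum(res$sites$class == "DSB_plusplus")
    }, 0L)
    expect_true(all(diff(pp_sites) >= 0))
  }
})

test_that("source counts partition the DSB-bearing sites", {
  set.seed(55)
  for (i in 1:20) {
    les <- random_lesions(sample(10:50, 1), max_pos = 120L)
    res <- classify_damage(les)
    tal <- tally_damage(res, 1, genome_model(1, 1e6))
    bearing <- sum(res$sites$class %in% c("DSB", "DSB_plus", "DSB_plusplus"))
    expect_identical(unname(tal$counts["DSB_D"] + tal$counts["DSB_I"] +
                              tal$counts["DSB_HYB"] + tal$counts["DSB_MIX"]),
                     bearing)
  }
})

test_that("combine_tallies pools counts and renormalizes by summed dose", {
  cfg <- classifier_config()
  s1 <- classify_damage(lesions(L(100, 1), L(105, 2)), cfg)
  s2 <- classify_damage(lesions(L(100, 1), L(300, 1)), cfg)
  g <- genome_model(1, 1e6)
  tal <- combine_tallies(list(tally_damage(s1, 2, g), tally_damage(s2, 2, g)))
  expect_identical(unname(tal$counts["SSB"]), 2L)
  expect_identical(unname(tal$counts["DSB_total"]), 1L)
  expect_equal(unname(tal$yields["DSB_per_Gy_Gbps"]), 1 / 4)
})

test_that("tally CSV writer produces one labelled row per exposure", {
  path <- withr::local_tempfile(fileext = ".csv")
  tal <- tally_damage(classify_damage(lesions(L(100, 1), L(105, 2))),
                      1, genome_model(1, 1e6))
  write_tally_csv(tal, path, label = "P36")
  write_tally_csv(tal, path, label = "D20", append = TRUE)
  got <- read.csv(path)
  expect_identical(got$label, c("P36", "D20"))
  expect_true("SSB_per_Gy_Gbps" %in% names(got))
})
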