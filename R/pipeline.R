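# End-to-end experiment orchestration.
#
# One experiment covers a set of Bragg-curve positions. Per position the
# pipeline (i) simulates lesion sets for n_nuclei independent nuclei at the
# exposure dose and tallies the classified damage, (ii) simulates (or ingests)
# a clonogenic survival assay and fits the linear-quadratic model, and (iii)
# simulates (or ingests) a 53BP1 focus-kinetics series and fits the
# biexponential resolution model. The per-position rows are assembled into a
# summary table (D37, D10, half-life, yD, strand-break yields and fractions)
# from which fold-change claims are derived.

#' Experiment configuration
#'
#' @param positions named list of [position_profile()]s (default: the bundled
#'   P36/P80/D20 profiles).
#' @param dose_Gy exposure dose per nucleus for damage simulation (Gy).
#' @param n_nuclei number of independently simulated nuclei per position.
#' @param genome a [genome_model()].
#' @param nucleus a [nucleus_geometry()].
#' @param classifier a [classifier_config()].
#' @param generator a [track_config()] used as a template (dose and seed are
#'   overridden per exposure).
#' @param survival_params named list (by position label) of lists with
#'   `alpha`, `beta` for the survival generator; defaults are solved from the
#'   bundled reference D37/D10 values via [lq_from_doses()].
#' @param survival_doses_Gy dose levels of the simulated survival assay.
#' @param n_survival_replicates replicate dishes per dose per experiment.
#' @param n_survival_experiments independent pooled experiments.
#' @param survival_noise_sd log-scale noise SD of the survival generator.
#' @param foci_params named list (by position label) of biexponential
#'   parameter lists; defaults are calibrated to the bundled reference
#'   half-lives via [calibrate_biexp()].
#' @param foci_t_hours kinetics sampling times (hours).
#' @param n_foci_nuclei nuclei scored per kinetics time point.
#' @param master_seed master seed; all stage seeds fan out deterministically
#'   via [stage_seed()].
#' @param output_dir optional directory; when set, [run_experiment()] writes
#'   per-stage CSV artifacts and a provenance manifest there.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(positions = bragg_profiles(),
                              dose_Gy = 2, n_nuclei = 50,
                              genome = genome_model(),
                              nucleus = nucleus_geometry(),
                              classifier = classifier_config(),
                              generator = track_config(),
                              survival_params = NULL,
                              survival_doses_Gy = c(0, 2, 4, 6),
                              n_survival_replicates = 3,
                              n_survival_experiments = 3,
                              survival_noise_sd = 0.1,
                              foci_params = NULL,
                              foci_t_hours = c(0.25, 2, 6, 8, 15, 18, 24),
                              n_foci_nuclei = 100,
                              master_seed = 1L,
                              output_dir = NULL) {
  if (length(positions) == 0L) stop_invalid("positions must be non-empty")
  stopifnot(all(vapply(positions, inherits, TRUE, "position_profile")))
  labels <- vapply(positions, `[[`, "", "label")
  names(positions) <- labels
  ref <- reference_summary()
  if (is.null(survival_params)) {
    survival_params <- lapply(labels, function(lb) {
      i <- match(lb, ref$position)
      if (is.na(i)) list(alpha = 0.3, beta = 0.03)
      else lq_from_doses(ref$d37_Gy[i], ref$d10_Gy[i])
    })
    names(survival_params) <- labels
  }
  if (is.null(foci_params)) {
    foci_params <- lapply(labels, function(lb) {
      i <- match(lb, ref$position)
      t_half <- if (is.na(i)) 3 else ref$t_half_h[i]
      calibrate_biexp(t_half, peak_foci = 20)
    })
    names(foci_params) <- labels
  }
  structure(list(positions = positions, dose_Gy = dose_Gy, n_nuclei = n_nuclei,
                 genome = genome, nucleus = nucleus, classifier = classifier,
                 generator = generator, survival_params = survival_params,
                 survival_doses_Gy = survival_doses_Gy,
                 n_survival_replicates = n_survival_replicates,
                 n_survival_experiments = n_survival_experiments,
                 survival_noise_sd = survival_noise_sd,
                 foci_params = foci_params, foci_t_hours = foci_t_hours,
                 n_foci_nuclei = n_foci_nuclei,
                 master_seed = as.integer(master_seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Run the multi-position experiment
#'
#' Executes simulate -> classify -> tally -> fit for every position and
#' assembles the summary table. All randomness derives from
#' `config$master_seed` through [stage_seed()], so identical configurations
#' reproduce identical tables; when `config$output_dir` is set, per-stage CSV
#' artifacts and a JSON provenance manifest (file names, stage seeds) are
#' written.
#'
#' @param config an [experiment_config()].
#' @return an object of class `experiment_result`: list with `summary` (one
#'   row per position: position, yd_bar_keV_um, d37_Gy, d10_Gy, alpha, beta,
#'   t_half_h, ssb_per_Gy_Gbps, dsb_per_Gy_Gbps, ssb_over_dsb,
#'   dsb_frac_of_sb_pct, complex_frac_of_sb_pct, complex_frac_of_dsb_pct),
#'   `tallies`, `survival_fits`, `foci_fits` and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  rows <- list(); tallies <- list(); sfits <- list(); ffits <- list()
  manifest <- list(master_seed = ms, positions = list())
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (lb in names(config$positions)) {
    prof <- config$positions[[lb]]

    # --- damage simulation over n_nuclei independent nuclei
    seeds <- vapply(seq_len(config$n_nuclei), function(i)
      stage_seed(ms, "tracks", lb, i), 0L)
    nucleus_tallies <- lapply(seeds, function(sd) {
      gen <- config$generator
      gen$dose_Gy <- config$dose_Gy
      gen$seed <- sd
      ls <- generate_lesion_set(prof, config$genome, config$nucleus, gen)
      tally_damage(classify_damage(ls, config$classifier))
    })
    tal <- combine_tallies(nucleus_tallies)
    tallies[[lb]] <- tal

    # --- survival assay (simulated, pooled over independent experiments)
    sv <- do.call(rbind, lapply(seq_len(config$n_survival_experiments), function(e) {
      simulate_survival(config$survival_params[[lb]],
                        doses_Gy = config$survival_doses_Gy,
                        n_replicates = config$n_survival_replicates,
                        noise_sd = config$survival_noise_sd,
                        seed = stage_seed(ms, "survival", lb, e))
    }))
    sfit <- fit_lq(sv$dose_Gy, sv$surviving_fraction, weighting = "unweighted")
    sfits[[lb]] <- sfit

    # --- foci kinetics (simulated)
    ser <- simulate_foci_series(config$foci_params[[lb]],
                                t_hours = config$foci_t_hours,
                                n_nuclei = config$n_foci_nuclei,
                                seed = stage_seed(ms, "foci", lb))
    ffit <- fit_biexp(ser$t_hours, ser$foci_per_nucleus, ser$sem)
    ffits[[lb]] <- ffit

    rows[[lb]] <- data.frame(
      position = lb,
      yd_bar_keV_um = prof$yd_bar_keV_um,
      d37_Gy = sfit$d37_Gy, d10_Gy = sfit$d10_Gy,
      alpha = sfit$alpha, beta = sfit$beta,
      t_half_h = ffit$t_half_hours,
      ssb_per_Gy_Gbps = unname(tal$yields["SSB_per_Gy_Gbps"]),
      dsb_per_Gy_Gbps = unname(tal$yields["DSB_per_Gy_Gbps"]),
      ssb_over_dsb = unname(tal$ratios["SSB_over_DSB"]),
      dsb_frac_of_sb_pct = 100 * unname(tal$ratios["DSB_fraction_of_SB"]),
      complex_frac_of_sb_pct = 100 * unname(tal$ratios["complex_DSB_fraction_of_SB"]),
      complex_frac_of_dsb_pct = 100 * unname(tal$ratios["complex_DSB_fraction_of_DSB"]),
      stringsAsFactors = FALSE)

    if (!is.null(out_dir)) {
      write_tally_csv(tal, file.path(out_dir, paste0("tally_", lb, ".csv")), label = lb)
      sv$position <- lb
      write_survival_csv(sv, file.path(out_dir, paste0("survival_", lb, ".csv")))
      ser$position <- lb
      write_kinetics_csv(ser, file.path(out_dir, paste0("kinetics_", lb, ".csv")))
      manifest$positions[[lb]] <- list(
        track_seeds = as.integer(seeds),
        survival_seeds = vapply(seq_len(config$n_survival_experiments), function(e)
          stage_seed(ms, "survival", lb, e), 0L),
        foci_seed = stage_seed(ms, "foci", lb),
        files = paste0(c("tally_", "survival_", "kinetics_"), lb, ".csv"))
    }
  }

  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(summary = summary, tallies = tallies, survival_fits = sfits,
                 foci_fits = ffits, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Derived fold-change claims from a summary table
#'
#' Computes, per position relative to the first (plateau) row: D37 and D10
#' fold reductions; the complex-DSB share of all DSBs (complex fraction of
#' strand breaks divided by DSB fraction of strand breaks, in percent); and
#' the distal-vs-proximal complex-fraction ratio (last row over the mean of
#' the preceding rows). Folds are reported to 2 decimals.
#'
#' @param summary data.frame with columns `position`, `d37_Gy`, `d10_Gy`,
#'   `complex_frac_of_sb_pct` and `dsb_frac_of_sb_pct` -- either an
#'   [run_experiment()] summary or a reference table such as
#'   [reference_summary()].
#' @return list with `per_position` (data.frame: position, d37_fold, d10_fold,
#'   complex_share_of_dsb_pct) and `distal_complex_ratio`.
#' @examples
#' report_fractions(reference_summary())
#' @export
report_fractions <- function(summary) {
  need <- c("position", "d37_Gy", "d10_Gy", "complex_frac_of_sb_pct")
  if (!all(need %in% names(summary)))
    stop_invalid("summary must have columns: ", paste(need, collapse = ", "))
  if (nrow(summary) < 1L) stop_invalid("summary has no rows")
  per <- data.frame(
    position = summary$position,
    d37_fold = fold_change(summary$d37_Gy[1], summary$d37_Gy),
    d10_fold = fold_change(summary$d10_Gy[1], summary$d10_Gy),
    complex_share_of_dsb_pct = if ("dsb_frac_of_sb_pct" %in% names(summary))
      100 * summary$complex_frac_of_sb_pct / summary$dsb_frac_of_sb_pct
    else NA_real_,
    stringsAsFactors = FALSE)
  distal <- if (nrow(summary) >= 2L) {
    n <- nrow(summary)
    round(summary$complex_frac_of_sb_pct[n] /
            mean(summary$complex_frac_of_sb_pct[-n]), 2)
  } else NA_real_
  list(per_position = per, distal_complex_ratio = distal)
}
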