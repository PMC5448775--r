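#' Run configuration for the emulated experiments
#'
#' A serializable bundle of everything the two pipeline drivers need; a
#' saved config reproduces deterministic stages bit-identically.
#'
#' @param seed top-level integer seed; every stage derives its own child
#'   stream from it by a fixed label.
#' @param modality `"MR"` or `"CT"`.
#' @param n_kidneys cohort size.
#' @param volume_range single-kidney volume range, ml.
#' @param expert_sd,beginner_sd boundary jitter SD (mm) per virtual rater.
#' @param expert_caliper_cv,beginner_caliper_cv relative SD of each manual
#'   caliper measurement per rater.
#' @param correlation_length boundary noise correlation length, mm.
#' @param slice_miss_prob end-slice miss probability.
#' @param matrix_size,in_plane_spacing lattice overrides (`NULL` =
#'   modality default).
#' @param out_dir where pipeline CSVs are written (`NULL` = don't write).
#' @return A list of class `kv_config`.
#' @export
run_config <- function(seed = 1L, modality = "MR", n_kidneys = 30,
                       volume_range = c(600, 6600),
                       expert_sd = 1.5, beginner_sd = 2.5,
                       expert_caliper_cv = 0.05, beginner_caliper_cv = 0.08,
                       correlation_length = 20, slice_miss_prob = 0.1,
                       matrix_size = 160L, in_plane_spacing = 3,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), modality = modality,
                 n_kidneys = n_kidneys, volume_range = volume_range,
                 expert_sd = expert_sd, beginner_sd = beginner_sd,
                 expert_caliper_cv = expert_caliper_cv,
                 beginner_caliper_cv = beginner_caliper_cv,
                 correlation_length = correlation_length,
                 slice_miss_prob = slice_miss_prob,
                 matrix_size = matrix_size,
                 in_plane_spacing = in_plane_spacing,
                 out_dir = out_dir),
            class = "kv_config")
}

#' Emulate the duplicate-tracing method-comparison experiment
#'
#' Generates a phantom cohort, emulates duplicate tracings by two virtual
#' raters (expert and beginner, two sessions each), runs every estimator
#' on each tracing, and summarises reproducibility (intra-/inter-rater CV)
#' and agreement with the planimetry reference (mean % difference,
#' Bland-Altman, RMSE). Stereology and ellipsoid-method measurements are
#' taken from a mask rasterised from the same noisy tracing, so all
#' methods share one boundary per (kidney, rater, session).
#'
#' @param config a [run_config()].
#' @return List with `measurements` (long data.frame, one row per kidney x
#'   method x rater x session), `oracle` (per-kidney ground truth, ml),
#'   `reproducibility` and `agreement` summary tables (see
#'   [compare_measurements()]), and `length_correlation` (Pearson r of
#'   kidney length vs oracle volume). CSVs are written under
#'   `config$out_dir` when set.
#' @export
run_experiment_emulation <- function(config = run_config()) {
  stopifnot(inherits(config, "kv_config"))
  geom <- imaging_geometry(config$modality,
                           matrix_size = config$matrix_size,
                           in_plane_spacing = config$in_plane_spacing)
  cohort <- generate_cohort(config$n_kidneys, config$volume_range, geom,
                            seed = child_seed(config$seed, "cohort-root"))
  oracle <- attr(cohort, "oracle_ml")
  raters <- c(expert = config$expert_sd, beginner = config$beginner_sd)
  caliper_cvs <- c(expert = config$expert_caliper_cv,
                   beginner = config$beginner_caliper_cv)
  rows <- list()
  lengths_cm <- numeric(length(cohort))
  for (ki in seq_along(cohort)) {
    ph <- cohort[[ki]]
    clean <- contour_stack(ph, geom)
    for (ri in seq_along(raters)) {
      for (sess in 1:2) {
        lbl <- sprintf("trace-%d-%s-%d", ki, names(raters)[ri], sess)
        nm <- rater_noise_model(boundary_sd = raters[ri],
                                correlation_length = config$correlation_length,
                                slice_miss_prob = config$slice_miss_prob,
                                caliper_cv = caliper_cvs[ri],
                                seed = child_seed(config$seed, lbl))
        traced <- apply_rater_noise(clean, nm)
        mask <- contours_to_mask(traced)
        grid <- stereology_grid(geom,
                                seed = child_seed(config$seed,
                                                  paste0(lbl, "-grid")))
        est <- list(
          planimetry_volume(traced),
          stereology_volume(mask, grid),
          midslice_volume(traced, side = ph$side),
          ellipsoid_method_volume(apply_caliper_noise(measure_axes(mask), nm),
                                  side = ph$side),
          new_estimate("length_only", kidney_length(mask))
        )
        for (e in est)
          rows[[length(rows) + 1]] <- data.frame(
            kidney_id = sprintf("K%02d", ki), method = e$method,
            rater = names(raters)[ri], session = sess,
            skv_ml = e$skv_ml, side = ph$side, oracle_ml = oracle[ki])
        if (names(raters)[ri] == "expert" && sess == 1)
          lengths_cm[ki] <- est[[5]]$skv_ml  # cm, stored in skv slot
      }
    }
  }
  meas <- do.call(rbind, rows)
  vol_meas <- meas[meas$method != "length_only", ]
  cmp <- compare_measurements(vol_meas)
  lc <- pearson(lengths_cm, oracle)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(meas, file.path(config$out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp$reproducibility,
                     file.path(config$out_dir, "reproducibility.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp$agreement,
                     file.path(config$out_dir, "agreement.csv"),
                     row.names = FALSE)
  }
  list(measurements = meas, oracle = oracle,
       reproducibility = cmp$reproducibility, agreement = cmp$agreement,
       length_correlation = lc)
}

#' Emulate the validation (trial sensitivity) study
#'
#' For each volumetry method's published group statistics: simulates a
#' two-arm trial of the given size, tests the treatment effect by
#' baseline-adjusted ANCOVA (absolute change) and unpaired t-test
#' (percentage change), and computes the per-group sample size from the
#' printed statistics with the normal-approximation formula.
#'
#' @param config a [run_config()]; only `seed` and `out_dir` are used.
#' @param group_stats per-method arm statistics; default
#'   [trial_group_stats()].
#' @param n_treated,n_control simulated arm sizes (defaults follow the
#'   source trial: 38 / 37).
#' @param alpha,power sample-size operating characteristics.
#' @return data.frame, one row per method: simulated arm means/SDs,
#'   ANCOVA and t-test p-values, and `n_per_group`.
#' @export
run_validation_emulation <- function(config = run_config(),
                                     group_stats = trial_group_stats(),
                                     n_treated = 38, n_control = 37,
                                     alpha = 0.05, power = 0.80) {
  stopifnot(inherits(config, "kv_config"))
  methods <- unique(group_stats$method)
  out <- do.call(rbind, lapply(methods, function(me) {
    gs <- group_stats[group_stats$method == me, ]
    tr <- gs[gs$arm == "octreotide", ]
    pl <- gs[gs$arm == "placebo", ]
    rec <- simulate_trial(tr$pct_mean, tr$pct_sd, pl$pct_mean, pl$pct_sd,
                          n_treated, n_control,
                          seed = child_seed(config$seed,
                                            paste0("trial-", me)))
    ch <- tkv_change(rec$tkv_baseline, rec$tkv_year1)
    an <- ancova_group_effect(rec)
    tt <- ttest_percentage_change(rec)
    data.frame(
      method = me,
      sim_pct_mean_treated = mean(ch$pct[rec$group == "octreotide"]),
      sim_pct_sd_treated = stats::sd(ch$pct[rec$group == "octreotide"]),
      sim_pct_mean_control = mean(ch$pct[rec$group == "placebo"]),
      ancova_effect_ml = an$effect_ml, ancova_p = an$p, ttest_p = tt,
      n_per_group = sample_size(tr$pct_mean, pl$pct_mean, tr$pct_sd,
                                alpha, power))
  }))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE)
  }
  out
}
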