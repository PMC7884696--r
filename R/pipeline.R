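#' Simulate a full phantom cohort
#'
#' End-to-end cohort generator: one shared atlas; per stroked subject an
#' acute (day 1) and chronic (day 28) imaging bundle with sampled
#' structure coverage, hemispheric swelling then atrophy, and the matching
#' midline shifts; an FA map with an ipsilateral corpus-callosum decrement
#' at day 1; and longitudinal outcome tables driven by the subjects'
#' actual day-1 PoS through the damage-to-deficit model. Defaults emulate
#' a 7-stroked / 5-control cohort with acute swelling of +15.17% and a
#' +1.57 mm midline shift, chronic shift of -1.99 mm, and chronic lesion
#' shrinkage.
#'
#' @param config A [phantom_config()].
#' @param n_stroked,n_control Cohort sizes.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param acute_change_percent,chronic_change_percent Cohort-mean
#'   hemispheric change at day 1 / day 28.
#' @param acute_change_sd,chronic_change_sd Between-subject SD of the
#'   hemispheric change.
#' @param acute_shift_mm,chronic_shift_mm Cohort-mean midline shift at
#'   day 1 / day 28 (positive = toward the contralateral hemisphere).
#' @param acute_shift_sd,chronic_shift_sd Between-subject SD of the shift.
#' @param chronic_lesion_scale Multiplier on structure coverage at day 28.
#' @param fa_decrement,fa_noise_sd Day-1 FA decrement and voxel noise.
#' @param outcome_model Optional [outcome_model()]; default
#'   [default_outcome_model()] on the generated atlas.
#' @param out_dir Optional directory; when given, all volumes (NIfTI),
#'   lookup/outcome/landmark CSVs, per-subject ground-truth JSON sidecars
#'   and a manifest are written there.
#' @return A `phantom_cohort` list: `atlas`, `subjects` (list of
#'   `subject_imaging`, both timepoints), `fa` (per stroked subject),
#'   `outcomes`, `overlap_1d`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = phantom_config(), n_stroked = 7,
                            n_control = 5, seed = 1L,
                            acute_change_percent = 15.17,
                            acute_change_sd = 7.89,
                            chronic_change_percent = -3.5,
                            chronic_change_sd = 3.63,
                            acute_shift_mm = 1.57,
                            acute_shift_sd = 0.83,
                            chronic_shift_mm = -1.99,
                            chronic_shift_sd = 1.00,
                            chronic_lesion_scale = 0.37,
                            fa_decrement = 0.3, fa_noise_sd = 0.05,
                            outcome_model = NULL, out_dir = NULL) {
  if (n_stroked < 1) stop("`n_stroked` must be >= 1", call. = FALSE)
  atlas <- generate_atlas(config)
  lk <- atlas$lookup
  ips <- lk[lk$hemisphere == "right" & !lk$is_ventricle & !lk$is_cerebellum, ]
  n_str <- nrow(ips)
  profile <- tibble::tibble(
    structure_id = ips$label_id,
    mean_cov = pmax(0.60 * exp(-(seq_len(n_str) - 1) / 4), 0.05),
    incidence = pmin(1, 1.05 * exp(-(seq_len(n_str) - 1) / 8))
  )

  subjects <- list()
  fa_maps <- list()
  overlap_1d <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_stroked)) {
      sid <- sprintf("mcao%02d", s)
      severity <- stats::runif(1, 0.6, 1.4)
      hit <- stats::runif(n_str) < profile$incidence
      cov <- ifelse(hit, pmin(profile$mean_cov * severity *
                                stats::runif(n_str, 0.7, 1.3), 0.98), 0)
      cov1 <- stats::setNames(cov, profile$structure_id)
      cov1 <- cov1[cov1 > 0]
      shift1 <- stats::rnorm(1, acute_shift_mm, acute_shift_sd)
      chg1 <- max(stats::rnorm(1, acute_change_percent, acute_change_sd),
                  -50)
      subj1 <- generate_subject(
        atlas, lesion_spec(target_coverage = cov1),
        swelling_spec(midline_shift_mm = shift1,
                      volume_change_percent = chg1),
        subject_id = sid, timepoint_day = 1)
      cov28 <- cov1 * chronic_lesion_scale
      shift28 <- stats::rnorm(1, chronic_shift_mm, chronic_shift_sd)
      chg28 <- max(stats::rnorm(1, chronic_change_percent,
                                chronic_change_sd), -50)
      subj28 <- generate_subject(
        atlas, lesion_spec(target_coverage = cov28),
        swelling_spec(midline_shift_mm = shift28,
                      volume_change_percent = chg28),
        subject_id = sid, timepoint_day = 28)
      subjects[[paste0(sid, "_d1")]] <- subj1
      subjects[[paste0(sid, "_d28")]] <- subj28
      fa_maps[[sid]] <- generate_fa_map(atlas, fa_decrement, fa_noise_sd,
                                        seed = seed + 1000L + s)
      overlap_1d <- dplyr::bind_rows(
        overlap_1d,
        structure_overlap(atlas, subj1$lesion, subject_id = sid,
                          timepoint_day = 1))
    }
  })

  # outcomes from the measured day-1 PoS of each stroked subject
  struct_ids <- ips$label_id
  cohort_pos <- overlap_1d |>
    dplyr::filter(.data$structure_id %in% struct_ids) |>
    dplyr::transmute(.data$subject_id, group = "MCAO",
                     .data$structure_id, .data$pos_percent)
  if (n_control > 0) {
    cohort_pos <- dplyr::bind_rows(
      cohort_pos,
      tidyr::expand_grid(subject_id = sprintf("ctrl%02d",
                                              seq_len(n_control)),
                         structure_id = struct_ids) |>
        dplyr::mutate(group = "control", pos_percent = 0))
  }
  model <- outcome_model %||% default_outcome_model(atlas)
  outcomes <- generate_outcomes(cohort_pos, model, seed = seed + 2L)

  cohort <- structure(
    list(atlas = atlas, subjects = subjects, fa = fa_maps,
         outcomes = outcomes, overlap_1d = overlap_1d,
         outcome_model = model, config = config, seed = seed),
    class = "phantom_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$fa), " stroked subjects, ",
      dplyr::n_distinct(x$outcomes$subject_id) - length(x$fa),
      " controls; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes the atlas (NIfTI + lookup CSV), every subject's masks and the
#' FA maps/ROIs (NIfTI), a landmarks CSV, the outcomes CSV, one
#' ground-truth JSON sidecar per subject x timepoint, and a run manifest.
#'
#' @param cohort A `phantom_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(out_dir, "atlas.nii.gz"),
              file.path(out_dir, "atlas_lookup.csv"))
  landmarks <- NULL
  for (key in names(cohort$subjects)) {
    subj <- cohort$subjects[[key]]
    base <- file.path(out_dir, key)
    write_volume(subj$lesion, paste0(base, "_lesion.nii.gz"))
    write_volume(subj$hemi_ipsi, paste0(base, "_hemi_ipsi.nii.gz"))
    write_volume(subj$hemi_contra, paste0(base, "_hemi_contra.nii.gz"))
    write_volume(subj$vent_ipsi, paste0(base, "_vent_ipsi.nii.gz"))
    write_volume(subj$vent_contra, paste0(base, "_vent_contra.nii.gz"))
    jsonlite::write_json(subj$ground_truth,
                         paste0(base, "_ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    lm <- subj$landmarks
    landmarks <- dplyr::bind_rows(landmarks, tibble::tibble(
      subject_id = subj$subject_id, timepoint_day = subj$timepoint_day,
      septum_x_mm = lm$septum_xyz_mm[1], septum_y_mm = lm$septum_xyz_mm[2],
      septum_z_mm = lm$septum_xyz_mm[3],
      plane_point_x_mm = lm$plane_point_xyz_mm[1],
      plane_point_y_mm = lm$plane_point_xyz_mm[2],
      plane_point_z_mm = lm$plane_point_xyz_mm[3],
      plane_normal_x = lm$plane_normal_xyz[1],
      plane_normal_y = lm$plane_normal_xyz[2],
      plane_normal_z = lm$plane_normal_xyz[3]))
  }
  readr::write_csv(landmarks, file.path(out_dir, "landmarks.csv"))
  for (sid in names(cohort$fa)) {
    fa <- cohort$fa[[sid]]
    write_volume(fa$fa, file.path(out_dir, paste0(sid, "_d1_fa.nii.gz")))
    write_volume(fa$roi_ipsi,
                 file.path(out_dir, paste0(sid, "_d1_cc_roi_ipsi.nii.gz")))
    write_volume(fa$roi_contra,
                 file.path(out_dir, paste0(sid, "_d1_cc_roi_contra.nii.gz")))
  }
  readr::write_csv(cohort$outcomes, file.path(out_dir, "outcomes.csv"))
  write_manifest(out_dir, cohort$seed, cohort$config)
  invisible(out_dir)
}

write_manifest <- function(out_dir, seed, config, extra = list()) {
  manifest <- c(list(
    package = "lesiontopo",
    version = as.character(utils::packageVersion("lesiontopo")),
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(config),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full analysis pipeline on a phantom cohort
#'
#' Volumetrics, per-structure overlap, cohort incidence, PoS rankings, FA
#' asymmetry, and the feature-vs-outcome correlation heatmaps at each
#' outcome timepoint, with per-heatmap Benjamini-Hochberg FDR.
#'
#' @param cohort A `phantom_cohort` (see [simulate_cohort()]).
#' @param imaging_timepoint_day Imaging timepoint for the feature matrix.
#' @param outcome_timepoint_days Outcome timepoints to correlate against.
#' @param top_n_structures PoS features in the heatmaps.
#' @param min_lesioned Minimum-lesioned filter for PoS features.
#' @param threshold_voxels Presence threshold for incidence.
#' @param out_dir Optional directory for result CSVs and a manifest.
#' @return An `lt_analysis` list of tibbles: `volumetrics`, `overlap`,
#'   `incidence`, `ranking_pos`, `fa_results`, `fa_test`, `heatmaps`
#'   (one `lt_heatmap` per outcome timepoint).
#' @export
analyze_cohort <- function(cohort, imaging_timepoint_day = 1,
                           outcome_timepoint_days = c(2, 8),
                           top_n_structures = 10, min_lesioned = 3,
                           threshold_voxels = 1, out_dir = NULL) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  vols <- cohort_volumetrics(cohort$subjects)
  overlap <- purrr::map_dfr(cohort$subjects, function(s) {
    structure_overlap(cohort$atlas, s$lesion, subject_id = s$subject_id,
                      timepoint_day = s$timepoint_day)
  })
  incidence <- lesion_incidence(overlap, threshold_voxels = threshold_voxels)
  ranking <- rank_structures(
    dplyr::filter(overlap, .data$timepoint_day == imaging_timepoint_day),
    by = "pos", top_n = top_n_structures)

  fa_results <- purrr::imap_dfr(cohort$fa, function(fa, sid) {
    fa_roi_result(fa$fa, fa$roi_ipsi, fa$roi_contra,
                  tract_name = fa$tract_name, subject_id = sid,
                  timepoint_day = 1)
  })
  fa_test <- if (nrow(fa_results) >= 2) fa_asymmetry_test(fa_results)

  features <- build_feature_matrix(
    overlap, volumetrics = vols, top_n_structures = top_n_structures,
    imaging_timepoint_day = imaging_timepoint_day)
  heatmaps <- purrr::map(outcome_timepoint_days, function(tp) {
    correlate_outcomes(features, cohort$outcomes, tp,
                       min_lesioned = min_lesioned)
  })
  names(heatmaps) <- paste0("day", outcome_timepoint_days)

  res <- structure(list(volumetrics = vols, overlap = overlap,
                        incidence = incidence, ranking_pos = ranking,
                        fa_results = fa_results, fa_test = fa_test,
                        features = features, heatmaps = heatmaps),
                   class = "lt_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(vols, file.path(out_dir, "volumetrics.csv"))
    readr::write_csv(overlap, file.path(out_dir, "overlap.csv"))
    readr::write_csv(incidence, file.path(out_dir, "incidence.csv"))
    readr::write_csv(ranking, file.path(out_dir, "ranking_pos.csv"))
    readr::write_csv(fa_results, file.path(out_dir, "fa_results.csv"))
    for (nm in names(heatmaps)) {
      export_heatmap(heatmaps[[nm]],
                     file.path(out_dir, paste0("heatmap_", nm)))
    }
    write_manifest(out_dir, cohort$seed, cohort$config,
                   extra = list(stage = "analysis"))
  }
  res
}

#' Summary report tables for an analysed cohort
#'
#' Assembles publication-style summaries: cohort mean +/- SD of each
#' canonical MRI metric per timepoint (with one-sample tests of midline
#' shift against 0 and hemispheric change against no change), a wide
#' incidence table (structures x timepoints, zeros shown as dashes), and
#' the PoS ranking.
#'
#' @param analysis An `lt_analysis` from [analyze_cohort()].
#' @return List of tibbles `metric_summary`, `incidence_wide`,
#'   `ranking_pos`.
#' @export
report_cohort <- function(analysis) {
  stopifnot(inherits(analysis, "lt_analysis"))
  if (nrow(analysis$volumetrics) == 0) {
    stop("empty cohort: no volumetrics rows to summarise", call. = FALSE)
  }
  metrics <- c("lesion_volume_cm3", "lesion_percent_of_ipsi",
               "midline_shift_mm", "hemispheric_change_percent")
  metric_summary <- analysis$volumetrics |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$timepoint_day, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p_vs_normal = purrr::pmap_dbl(
      list(.data$metric, .data$mean, .data$sd, .data$n),
      function(metric, mean, sd, n) {
        if (!metric %in% c("midline_shift_mm",
                           "hemispheric_change_percent") ||
            n < 2 || !is.finite(sd) || sd == 0) return(NA_real_)
        one_sample_t(mean = mean, sd = sd, n = n, mu0 = 0)$p_value
      }))
  incidence_wide <- analysis$incidence |>
    dplyr::mutate(shown = ifelse(.data$incidence_percent == 0, "-",
                                 formatC(.data$incidence_percent,
                                         format = "f", digits = 1))) |>
    dplyr::select("structure_name", "timepoint_day", "shown") |>
    tidyr::pivot_wider(names_from = "timepoint_day",
                       values_from = "shown", names_prefix = "day_")
  list(metric_summary = metric_summary,
       incidence_wide = incidence_wide,
       ranking_pos = analysis$ranking_pos)
}
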