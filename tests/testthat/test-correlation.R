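cohort_fixture <- function(seed = 51, n_stroked = 12) {
  structures <- tibble::tibble(
    structure_id = 1:10,
    mean_pos = c(60, 50, 45, 40, 35, 30, 25, 20, 15, 10),
    incidence = 1)
  pos <- sample_cohort_pos(structures, n_stroked = n_stroked, n_control = 0,
                           seed = seed)
  baseline <- tibble::tibble(
    parameter = c("velocity", "stance_percent"), limb = "LF",
    baseline = c(198.78, 48.06), units = c("cm/s", "%"))
  beta <- dplyr::bind_rows(
    tibble::tibble(parameter = "velocity", structure_id = 1:3,
                   beta = c(0.5, 0.4, 0.35)),
    tibble::tibble(parameter = "stance_percent", structure_id = 1,
                   beta = -0.4))
  model <- outcome_model(
    baseline, beta,
    noise_sd = tibble::tibble(parameter = baseline$parameter,
                              noise_sd = 0.10 * baseline$baseline),
    halflife = tibble::tibble(parameter = baseline$parameter,
                              halflife_days = 7))
  outcomes <- generate_outcomes(pos, model, timepoints = c(-3, 2),
                                seed = seed + 1)
  list(pos = pos, outcomes = outcomes, overlap = pos_as_overlap(pos))
}

test_that("the feature matrix has the advertised shape and selection", {
  fx <- cohort_fixture()
  feats <- build_feature_matrix(fx$overlap, top_n_structures = 5,
                                imaging_timepoint_day = 1)
  expect_equal(nrow(feats), 12)
  expect_equal(sum(startsWith(names(feats), "pos:")), 5)
  # selection equals a brute-force mean-PoS sort
  means <- tapply(fx$overlap$pos_percent, fx$overlap$structure_name, mean)
  top5 <- names(sort(means, decreasing = TRUE))[1:5]
  expect_setequal(sub("^pos:", "", grep("^pos:", names(feats),
                                        value = TRUE)), top5)
  # top_n 0 with volumetrics gives the four canonical metrics only
  vols <- tibble::tibble(subject_id = unique(fx$pos$subject_id),
                         timepoint_day = 1, lesion_volume_cm3 = 1,
                         lesion_percent_of_ipsi = 2, midline_shift_mm = 0.5,
                         hemispheric_change_percent = 10)
  canon <- build_feature_matrix(fx$overlap, volumetrics = vols,
                                top_n_structures = 0)
  expect_named(canon, c("subject_id", "lesion_volume_cm3",
                        "lesion_percent_of_ipsi", "midline_shift_mm",
                        "hemispheric_change_percent"))
  # 10 PoS features + 4 canonical = 14 feature columns
  both <- build_feature_matrix(fx$overlap, volumetrics = vols,
                               top_n_structures = 10)
  expect_equal(ncol(both) - 1, 14)
})

test_that("strong damage-outcome couplings surface as negative r", {
  fx <- cohort_fixture()
  feats <- build_feature_matrix(fx$overlap, top_n_structures = 8)
  cells <- correlate_outcomes(feats, fx$outcomes, 2,
                              parameters = c("velocity", "stance_percent"))
  r1v <- cells$r[cells$feature == "pos:s01" & cells$outcome == "velocity"]
  expect_lt(r1v, -0.5)
  # a negative beta (stance rises with damage) flips the sign
  r1s <- cells$r[cells$feature == "pos:s01" &
                   cells$outcome == "stance_percent"]
  expect_gt(r1s, 0.3)
})

test_that("the minimum-lesioned filter excludes sparse structures", {
  fx <- cohort_fixture()
  ov <- fx$overlap
  # structure 8 lesioned in only 2 subjects
  sel <- ov$structure_id == 8
  ov$pos_percent[sel] <- 0
  keep2 <- which(sel)[1:2]
  ov$pos_percent[keep2] <- 30
  feats <- build_feature_matrix(ov, top_n_structures = 10)
  cells <- correlate_outcomes(feats, fx$outcomes, 2,
                              parameters = "velocity", min_lesioned = 3)
  s8 <- cells[cells$feature == "pos:s08", ]
  expect_false(s8$included)
  expect_match(s8$reason, "2 < 3")
  expect_true(is.na(s8$p_fdr))
  # excluded cells never perturb the FDR family of included cells
  cells_without <- correlate_outcomes(
    build_feature_matrix(ov[ov$structure_id != 8, ],
                         top_n_structures = 9),
    fx$outcomes, 2, parameters = "velocity", min_lesioned = 3)
  inc <- cells[cells$included, c("feature", "outcome", "p_fdr")]
  inc_wo <- cells_without[cells_without$included,
                          c("feature", "outcome", "p_fdr")]
  expect_equal(dplyr::arrange(inc, feature, outcome),
               dplyr::arrange(inc_wo, feature, outcome))
})

test_that("constant outcome columns are degeneracy-flagged, not correlated", {
  fx <- cohort_fixture()
  out <- fx$outcomes
  out$value[out$parameter == "velocity"] <- 100
  feats <- build_feature_matrix(fx$overlap, top_n_structures = 3)
  expect_warning(
    cells <- correlate_outcomes(feats, out, 2, parameters = "velocity"),
    "no cells passed")
  expect_true(all(!cells$included))
  expect_true(all(cells$reason == "zero variance"))
})

test_that("heatmap export round-trips exactly through the long CSV", {
  fx <- cohort_fixture()
  feats <- build_feature_matrix(fx$overlap, top_n_structures = 4)
  cells <- correlate_outcomes(feats, fx$outcomes, 2,
                              parameters = c("velocity", "stance_percent"))
  prefix <- file.path(withr::local_tempdir(), "hm")
  paths <- export_heatmap(cells, prefix)
  back <- read_heatmap(paste0(prefix, "_cells_long.csv"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(cells))
  wide <- readr::read_csv(paste0(prefix, "_r_wide.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(wide), 4)      # 4 features x 2 outcome columns
  expect_equal(ncol(wide), 3)
})

test_that("an autoplot heatmap builds without error", {
  fx <- cohort_fixture()
  feats <- build_feature_matrix(fx$overlap, top_n_structures = 3)
  cells <- correlate_outcomes(feats, fx$outcomes, 2)
  p <- ggplot2::autoplot(cells)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
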