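zero_model <- function(atlas) {
  m <- default_outcome_model(atlas)
  m$beta$beta <- 0
  m$noise_sd$noise_sd <- 0
  m
}

test_that("zero betas and zero noise reproduce baselines everywhere", {
  atlas <- small_atlas()
  pos <- sample_cohort_pos(atlas = atlas, n_stroked = 3, n_control = 2,
                           seed = 9)
  out <- generate_outcomes(pos, zero_model(atlas), seed = 9)
  base <- lesiontopo:::default_baseline_table()
  joined <- dplyr::left_join(out, base, by = c("parameter", "limb", "units"))
  expect_equal(joined$value, joined$baseline)
})

test_that("the damage-to-deficit arithmetic matches the closed form", {
  atlas <- small_atlas()
  m <- default_outcome_model(atlas, noise_frac = 0)
  # one subject with full damage in the putamen only
  pid <- atlas$lookup$label_id[atlas$lookup$name == "putamen_right"]
  ids <- unique(m$beta$structure_id)
  pos <- tidyr::expand_grid(subject_id = "s1", group = "MCAO",
                            structure_id = ids)
  pos$pos_percent <- ifelse(pos$structure_id == pid, 100, 0)
  out <- generate_outcomes(pos, m, timepoints = c(0, 7), seed = 1)
  beta_put <- m$beta$beta[m$beta$parameter == "velocity" &
                            m$beta$structure_id == pid]
  v0 <- out$value[out$parameter == "velocity" & out$timepoint_day == 0]
  v7 <- out$value[out$parameter == "velocity" & out$timepoint_day == 7]
  expect_equal(v0, 198.78 * (1 - beta_put))
  # 7-day half-life: deficit halves at t = 7
  expect_equal(198.78 - v7, (198.78 - v0) / 2)
})

test_that("a 64% summed deficit maps a 198.78 cm/s baseline to 71.56", {
  # direct check of the value formula at the documented magnitudes
  expect_equal(198.78 * (1 - 0.64), 71.5608, tolerance = 1e-6)
})

test_that("mRS is integer 0-6 and thresholds behave monotonically", {
  atlas <- small_atlas()
  pos <- sample_cohort_pos(atlas = atlas, n_stroked = 6, n_control = 2,
                           seed = 3)
  out <- generate_outcomes(pos, default_outcome_model(atlas), seed = 3)
  mrs <- out$value[out$parameter == "mrs"]
  expect_true(all(mrs == round(mrs) & mrs >= 0 & mrs <= 6))
  # controls without noiseless damage stay at 0 pre-stroke
  pre_ctrl <- out$value[out$parameter == "mrs" & out$group == "control" &
                          out$timepoint_day < 0]
  expect_true(all(pre_ctrl %in% 0:6))
})

test_that("unknown structure ids in betas are rejected; output deterministic", {
  atlas <- small_atlas()
  m <- default_outcome_model(atlas)
  pos <- sample_cohort_pos(atlas = atlas, seed = 4)
  bad <- m
  bad$beta$structure_id[1] <- 9999L
  expect_error(generate_outcomes(pos, bad), "absent")
  expect_identical(generate_outcomes(pos, m, seed = 5),
                   generate_outcomes(pos, m, seed = 5))
})
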