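test_that("mask volume equals voxel count times voxel volume", {
  arr <- array(FALSE, c(16, 16, 16))
  arr[seq_len(1000)] <- TRUE
  vg <- volume_grid(arr, spacing = c(1, 1, 3))
  expect_equal(mask_volume(vg), 3.000)
  expect_equal(mask_volume(volume_grid(array(FALSE, c(8, 8, 8)))), 0)
})

test_that("voxel counting equals the per-slice area x thickness oracle", {
  withr::with_seed(7, {
    arr <- array(runif(64^2 * 16) < 0.3, c(64, 64, 16))
  })
  vg <- volume_grid(arr, spacing = c(0.5, 0.5, 3))
  # slice-loop oracle: area per axial slice times slice thickness
  slice_sum <- 0
  for (k in seq_len(dim(arr)[3])) {
    slice_sum <- slice_sum + sum(arr[, , k]) * 0.5 * 0.5 * 3
  }
  expect_equal(mask_volume(vg), slice_sum / 1000)
})

test_that("volumes scale with the cube of the voxel edge length", {
  withr::with_seed(8, arr <- array(runif(20^3) < 0.4, c(20, 20, 20)))
  v1 <- mask_volume(volume_grid(arr, spacing = c(1, 1, 1)))
  v2 <- mask_volume(volume_grid(arr, spacing = c(2, 2, 2)))
  expect_equal(v2, 8 * v1)
})

test_that("hemisphere volumes subtract ventricles and cerebellum", {
  shape <- c(20, 20, 10)
  mk <- function(sel) {
    arr <- array(FALSE, shape); arr[sel] <- TRUE
    volume_grid(arr, spacing = c(5, 5, 4))  # 100 mm3 per voxel
  }
  ipsi <- mk(1:1000)
  contra <- mk(1001:2000)
  vent <- mk(1:80)          # 8 cm3 inside ipsi
  hv <- hemisphere_volumes(ipsi, contra,
                           ventricle_masks = list(ipsi = vent))
  expect_equal(hv$ipsi_cm3, 92)   # 100 - 8
  expect_equal(hv$contra_cm3, 100)
  expect_error(hemisphere_volumes(ipsi, ipsi), "overlap")
})

test_that("lesion percent and hemispheric change arithmetic", {
  # implied hemisphere volume from a 11.39 cm3 lesion at 32.64%
  expect_equal(lesion_percent_of_hemisphere(11.39, 11.39 / 0.3264), 32.64)
  expect_equal(lesion_percent_of_hemisphere(0, 34.9), 0)
  expect_equal(lesion_percent_of_hemisphere(34.9, 34.9), 100)
  expect_error(lesion_percent_of_hemisphere(1, 0), "> 0")
  expect_equal(hemispheric_change_percent(115, 100), 15)
  expect_equal(hemispheric_change_percent(100, 100), 0)
  expect_error(hemispheric_change_percent(100, 0), "> 0")
})

test_that("midline shift is the signed distance to the ideal plane", {
  lm0 <- midline_landmarks(c(0, 5, 0), c(0, 0, 0), c(-1, 0, 0))
  expect_equal(midline_shift(lm0), 0)
  # 2 mm along the (contralateral-pointing) normal
  lm2 <- midline_landmarks(c(-2, 5, 0), c(0, 0, 0), c(-1, 0, 0))
  expect_equal(midline_shift(lm2), 2)
  # non-unit normals are normalised; degenerate normals rejected
  lm3 <- midline_landmarks(c(-2, 5, 0), c(0, 0, 0), c(-10, 0, 0))
  expect_equal(midline_shift(lm3), 2)
  expect_error(midline_landmarks(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)),
               "degenerate")
})

test_that("phantom ground truth is recovered by the volumetrics chain", {
  atlas <- small_atlas()
  right_ids <- atlas$lookup$label_id[atlas$lookup$hemisphere == "right" &
                                       !atlas$lookup$is_ventricle]
  subj <- generate_subject(
    atlas,
    lesion_spec(target_coverage = stats::setNames(c(0.6, 0.3),
                                                  right_ids[1:2])),
    swelling_spec(midline_shift_mm = -1.99, volume_change_percent = 15.17))
  v <- subject_volumetrics(subj)
  gt <- subj$ground_truth
  expect_equal(v$lesion_volume_cm3, gt$lesion_volume_cm3)
  expect_equal(v$ipsi_hemisphere_cm3, gt$ipsi_hemisphere_cm3)
  expect_equal(v$hemispheric_change_percent, gt$hemispheric_change_percent)
  expect_equal(v$midline_shift_mm, -1.99)
})
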