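test_that("lesion coverage targets are achieved to within one voxel", {
  atlas <- small_atlas()
  n <- atlas$config$n_structures_per_hemisphere
  right_ids <- atlas$lookup$label_id[atlas$lookup$hemisphere == "right" &
                                       !atlas$lookup$is_ventricle]
  cov <- stats::setNames(c(1.0, 0.5, 0.25), right_ids[1:3])
  subj <- generate_subject(atlas, lesion_spec(target_coverage = cov))
  ov <- structure_overlap(atlas, subj$lesion)
  for (i in seq_along(cov)) {
    row <- ov[ov$structure_id == as.integer(names(cov)[i]), ]
    expect_equal(row$n_lesion_overlap_voxels,
                 round(cov[i] * row$n_structure_voxels),
                 ignore_attr = TRUE)
  }
  # full coverage means PoS exactly 100
  expect_equal(ov$pos_percent[ov$structure_id ==
                                as.integer(names(cov)[1])], 100)
  # lesion confined to the ipsilateral hemisphere
  h <- lesiontopo:::atlas_hemisphere_arrays(atlas)
  expect_true(all(h$right[subj$lesion$data]))
})

test_that("an empty lesion spec yields an empty mask and zero volume", {
  subj <- generate_subject(small_atlas(), lesion_spec())
  expect_equal(sum(subj$lesion$data), 0)
  expect_equal(mask_volume(subj$lesion), 0)
})

test_that("extra ellipsoid components add ipsilateral lesion voxels", {
  atlas <- small_atlas()
  subj <- generate_subject(atlas, lesion_spec(
    extra_ellipsoids = list(list(center_mm = c(12, 0, 0),
                                 radii_mm = c(8, 8, 8)))))
  expect_gt(sum(subj$lesion$data), 0)
  h <- lesiontopo:::atlas_hemisphere_arrays(atlas)
  expect_true(all(h$right[subj$lesion$data]))
})

test_that("swelling and atrophy hit the requested volume change exactly", {
  atlas <- small_atlas()
  for (pct in c(15, -10)) {
    subj <- generate_subject(atlas, lesion_spec(),
                             swelling_spec(volume_change_percent = pct))
    gt <- subj$ground_truth
    v <- subject_volumetrics(subj)
    # measured ratio equals the voxel-rounded target: within 1 voxel
    n_contra <- sum(subj$hemi_contra$data) - sum(subj$vent_contra$data)
    expect_lte(abs(v$hemispheric_change_percent - pct), 100 / n_contra)
    expect_equal(v$hemispheric_change_percent, gt$hemispheric_change_percent)
  }
})

test_that("the septum landmark reproduces the specified midline shift", {
  atlas <- small_atlas()
  for (shift in c(0, 1.57, -1.99, 4)) {
    subj <- generate_subject(atlas, lesion_spec(),
                             swelling_spec(midline_shift_mm = shift))
    expect_equal(midline_shift(subj$landmarks), shift)
  }
})

test_that("invalid lesion specs are rejected", {
  atlas <- small_atlas()
  expect_error(lesion_spec(target_coverage = c(`1` = 1.5)), "\\[0, 1\\]")
  expect_error(generate_subject(atlas,
                                lesion_spec(target_coverage = c(`999` = 0.5))),
               "unknown structure")
  # contralateral (left) structures cannot be lesioned with a right MCAO
  left_id <- atlas$lookup$label_id[atlas$lookup$hemisphere == "left"][1]
  expect_error(
    generate_subject(atlas, lesion_spec(
      target_coverage = stats::setNames(0.5, left_id))),
    "ipsilateral")
})
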