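#' Midline landmarks
#'
#' The midline-shift measurement follows the classical three-line clinical
#' procedure: an ideal midline plane is fixed from bony/non-brain anatomy,
#' and the shift is the perpendicular distance from the displaced septum
#' pellucidum to that plane. Here both are explicit inputs (supplied by the
#' phantom generator, or via a landmarks CSV for real data); automated
#' septum detection from image intensities is deliberately out of scope.
#'
#' @param septum_xyz_mm World coordinate (mm) of the septum pellucidum.
#' @param plane_point_xyz_mm A point on the ideal midline plane (mm).
#' @param plane_normal_xyz Plane normal; must have nonzero length and, by
#'   convention, point toward the contralateral hemisphere so that positive
#'   shifts mean displacement toward the contralateral side.
#' @return A `midline_landmarks` object.
#' @export
midline_landmarks <- function(septum_xyz_mm, plane_point_xyz_mm,
                              plane_normal_xyz) {
  n <- as.numeric(plane_normal_xyz)
  len <- sqrt(sum(n^2))
  if (!is.finite(len) || len < 1e-12) {
    stop("degenerate midline plane: normal has zero length", call. = FALSE)
  }
  structure(list(septum_xyz_mm = as.numeric(septum_xyz_mm),
                 plane_point_xyz_mm = as.numeric(plane_point_xyz_mm),
                 plane_normal_xyz = n / len),
            class = "midline_landmarks")
}

#' Volume of a binary mask in cubic centimetres
#'
#' Voxel-counting volumetrics: `voxel_count * voxel_volume`, which is
#' identical to the clinical per-slice area x slice-thickness summation for
#' the same mask.
#'
#' @param mask A binary `volume_grid`.
#' @return Volume in cm^3.
#' @export
#' @examples
#' m <- volume_grid(array(c(rep(TRUE, 1000), rep(FALSE, 3096)), c(16, 16, 16)),
#'                  spacing = c(1, 1, 3))
#' mask_volume(m)  # 3 cm^3
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "volume_grid"))
  assert_binary(mask)
  sum(mask_array(mask)) * voxel_volume_mm3(mask) / 1000
}

#' Ventricle- and cerebellum-corrected hemisphere volumes
#'
#' Each hemisphere volume excludes its lateral-ventricle voxels (non-brain
#' CSF) and any cerebellar voxels; the cerebellum is not part of the
#' hemispheric comparison.
#'
#' @param ipsi_mask,contra_mask Binary hemisphere `volume_grid`s; must not
#'   overlap.
#' @param ventricle_masks List with binary `volume_grid`s `ipsi` and
#'   `contra` (either may be empty).
#' @param cerebellum_mask Optional binary cerebellum `volume_grid`.
#' @return Named list `ipsi_cm3`, `contra_cm3`.
#' @export
hemisphere_volumes <- function(ipsi_mask, contra_mask,
                               ventricle_masks = list(),
                               cerebellum_mask = NULL) {
  assert_same_grid(ipsi_mask, contra_mask, "hemisphere masks")
  assert_binary(ipsi_mask, "ipsilateral hemisphere mask")
  assert_binary(contra_mask, "contralateral hemisphere mask")
  ipsi <- mask_array(ipsi_mask)
  contra <- mask_array(contra_mask)
  if (any(ipsi & contra)) {
    stop("ipsilateral and contralateral hemisphere masks overlap",
         call. = FALSE)
  }
  if (!is.null(cerebellum_mask)) {
    assert_same_grid(ipsi_mask, cerebellum_mask, "cerebellum mask")
    cb <- mask_array(cerebellum_mask)
    ipsi <- ipsi & !cb
    contra <- contra & !cb
  }
  drop_vent <- function(h, key) {
    v <- ventricle_masks[[key]]
    if (is.null(v)) return(h)
    assert_same_grid(ipsi_mask, v, "ventricle mask")
    h & !mask_array(v)
  }
  ipsi <- drop_vent(ipsi, "ipsi")
  contra <- drop_vent(contra, "contra")
  voxvol <- voxel_volume_mm3(ipsi_mask)
  list(ipsi_cm3 = sum(ipsi) * voxvol / 1000,
       contra_cm3 = sum(contra) * voxvol / 1000)
}

#' Lesion volume as a percentage of the ipsilateral hemisphere
#' @param lesion_cm3,ipsi_cm3 Volumes in cm^3; `ipsi_cm3` must be > 0.
#' @return Percentage in \[0, 100\].
#' @export
lesion_percent_of_hemisphere <- function(lesion_cm3, ipsi_cm3) {
  if (!is.finite(ipsi_cm3) || ipsi_cm3 <= 0) {
    stop("ipsilateral hemisphere volume must be > 0", call. = FALSE)
  }
  100 * lesion_cm3 / ipsi_cm3
}

#' Hemispheric swelling / atrophy as a signed percentage
#'
#' `100 * (ipsi / contra - 1)`: positive values indicate ipsilateral
#' swelling, negative values atrophy. (Equivalently, the ipsi/contra ratio
#' reported as a percentage change from 100%.)
#'
#' @param ipsi_cm3,contra_cm3 Hemisphere volumes in cm^3; `contra_cm3 > 0`.
#' @return Signed percentage.
#' @export
hemispheric_change_percent <- function(ipsi_cm3, contra_cm3) {
  if (!is.finite(contra_cm3) || contra_cm3 <= 0) {
    stop("contralateral hemisphere volume must be > 0", call. = FALSE)
  }
  100 * (ipsi_cm3 / contra_cm3 - 1)
}

#' Midline shift from landmarks
#'
#' Signed perpendicular distance from the septum pellucidum to the ideal
#' midline plane, positive when the septum is displaced toward the
#' contralateral hemisphere (the direction of the plane normal).
#'
#' @param landmarks A [midline_landmarks()] object.
#' @return Signed shift in mm.
#' @export
midline_shift <- function(landmarks) {
  stopifnot(inherits(landmarks, "midline_landmarks"))
  sum((landmarks$septum_xyz_mm - landmarks$plane_point_xyz_mm) *
        landmarks$plane_normal_xyz)
}

#' Canonical stroke volumetrics for one subject
#'
#' Computes the standard clinical MRI metrics from one subject's masks:
#' lesion volume, ventricle-corrected hemisphere volumes, lesion percent of
#' the ipsilateral hemisphere, hemispheric change, and midline shift.
#'
#' @param subject A `subject_imaging` bundle (see [generate_subject()]).
#' @return One-row tibble with columns `subject_id`, `timepoint_day`,
#'   `lesion_volume_cm3`, `ipsi_hemisphere_cm3`, `contra_hemisphere_cm3`,
#'   `lesion_percent_of_ipsi`, `hemispheric_change_percent`,
#'   `midline_shift_mm`.
#' @export
subject_volumetrics <- function(subject) {
  stopifnot(inherits(subject, "subject_imaging"))
  lesion_cm3 <- mask_volume(subject$lesion)
  hv <- hemisphere_volumes(subject$hemi_ipsi, subject$hemi_contra,
                           ventricle_masks = list(ipsi = subject$vent_ipsi,
                                                  contra = subject$vent_contra),
                           cerebellum_mask = subject$cerebellum)
  tibble::tibble(
    subject_id = subject$subject_id,
    timepoint_day = subject$timepoint_day,
    lesion_volume_cm3 = lesion_cm3,
    ipsi_hemisphere_cm3 = hv$ipsi_cm3,
    contra_hemisphere_cm3 = hv$contra_cm3,
    lesion_percent_of_ipsi = lesion_percent_of_hemisphere(lesion_cm3,
                                                          hv$ipsi_cm3),
    hemispheric_change_percent = hemispheric_change_percent(hv$ipsi_cm3,
                                                            hv$contra_cm3),
    midline_shift_mm = midline_shift(subject$landmarks)
  )
}

#' @describeIn subject_volumetrics Volumetrics for a list of subjects,
#'   one row each.
#' @param subjects List of `subject_imaging` objects.
#' @export
cohort_volumetrics <- function(subjects) {
  purrr::map_dfr(subjects, subject_volumetrics)
}
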