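#' Lesion and swelling specifications for phantom subjects
#'
#' `lesion_spec()` states, per atlas structure, the fraction of that
#' structure's voxels the synthetic infarct must cover, plus optional free
#' ellipsoidal lesion components; `swelling_spec()` states the hemispheric
#' volume change and the midline shift of the septum landmark. Both are
#' exact ground truth: the generated subject achieves the stated coverage to
#' within one voxel and the stated shift exactly (it is applied rigidly).
#'
#' @param target_coverage Named numeric vector mapping atlas `label_id`
#'   (names, coercible to integer) to a coverage fraction in \[0, 1\].
#' @param extra_ellipsoids List of `list(center_mm =, radii_mm =)` lesion
#'   components, clipped to the ipsilateral cerebral hemisphere.
#' @param hemisphere Which hemisphere is ipsilateral to the occlusion
#'   (`"right"` matches a right-sided MCAO).
#' @return A `lesion_spec` / `swelling_spec` list.
#' @export
lesion_spec <- function(target_coverage = numeric(),
                        extra_ellipsoids = list(),
                        hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  cov <- unlist(target_coverage)
  if (length(cov)) {
    if (is.null(names(cov)) || any(names(cov) == "")) {
      stop("`target_coverage` must be named by atlas label id", call. = FALSE)
    }
    if (any(cov < 0 | cov > 1)) {
      stop("coverage fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(target_coverage = cov, extra_ellipsoids = extra_ellipsoids,
                 hemisphere = hemisphere),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @param midline_shift_mm Signed displacement of the septum pellucidum
#'   landmark in mm; positive = toward the contralateral hemisphere
#'   (swelling), negative = toward the ipsilateral (atrophy).
#' @param volume_change_percent Signed percent change applied to the
#'   ipsilateral cerebral hemisphere volume relative to the contralateral.
#' @export
swelling_spec <- function(midline_shift_mm = 0, volume_change_percent = 0) {
  stopifnot(is.numeric(midline_shift_mm), is.numeric(volume_change_percent))
  if (volume_change_percent <= -100) {
    stop("`volume_change_percent` must be > -100", call. = FALSE)
  }
  structure(list(midline_shift_mm = midline_shift_mm,
                 volume_change_percent = volume_change_percent),
            class = "swelling_spec")
}

# shift a logical array one voxel along an axis, zero-padding the edge
shift_mask <- function(arr, axis, by) {
  out <- array(FALSE, dim(arr))
  n <- dim(arr)[axis]
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (axis == 1) out[dst, , ] <- arr[src, , ]
  else if (axis == 2) out[, dst, ] <- arr[, src, ]
  else out[, , dst] <- arr[, , src]
  out
}

# voxels 6-adjacent to a mask (excluding the mask itself)
mask_halo <- function(arr) {
  halo <- shift_mask(arr, 1, 1) | shift_mask(arr, 1, -1) |
    shift_mask(arr, 2, 1) | shift_mask(arr, 2, -1) |
    shift_mask(arr, 3, 1) | shift_mask(arr, 3, -1)
  halo & !arr
}

#' Generate one phantom subject
#'
#' Applies a [lesion_spec()] and [swelling_spec()] to a phantom atlas and
#' returns the full imaging bundle for one subject at one timepoint: lesion
#' mask, ipsi/contralateral hemisphere masks, per-side ventricle masks,
#' midline landmarks, and an exact ground-truth record.
#'
#' Lesion voxels inside each targeted structure are selected
#' deterministically, nearest-first from a lateral infarct focus, so the
#' achieved coverage equals `round(fraction * n_voxels)` voxels. Hemispheric
#' swelling (atrophy) is realised by adding (removing) exactly
#' `round(p/100 * contralateral_count)` voxels at the ipsilateral hemisphere
#' surface, so the measured ipsi/contra ratio is exact to within one voxel.
#' The septum landmark is displaced rigidly by `midline_shift_mm`.
#'
#' @param atlas A phantom [label_atlas()] from [generate_atlas()].
#' @param lesion A [lesion_spec()].
#' @param swelling A [swelling_spec()].
#' @param seed Integer seed (reserved for stochastic extensions; the current
#'   construction is deterministic given the specs).
#' @param subject_id,timepoint_day Identifiers carried into every result.
#' @return A `subject_imaging` object.
#' @export
generate_subject <- function(atlas, lesion = lesion_spec(),
                             swelling = swelling_spec(), seed = 1L,
                             subject_id = "subj01", timepoint_day = 1) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(lesion, "lesion_spec"),
            inherits(swelling, "swelling_spec"))
  sp <- atlas$grid$spacing
  shape <- dim(atlas$grid$data)
  axes <- phantom_axes(shape, sp)
  hemis <- atlas_hemisphere_arrays(atlas)
  ipsi_side <- lesion$hemisphere
  contra_side <- if (ipsi_side == "right") "left" else "right"
  sgn <- if (ipsi_side == "right") 1 else -1

  ipsi_base <- hemis[[ipsi_side]]
  contra <- hemis[[contra_side]]
  vent_ids <- atlas_labels(atlas, .data$is_ventricle)
  vlk <- atlas$lookup[atlas$lookup$is_ventricle, ]
  vent_ipsi <- array(atlas$grid$data %in%
                       vlk$label_id[vlk$hemisphere == ipsi_side], shape)
  vent_contra <- array(atlas$grid$data %in%
                         vlk$label_id[vlk$hemisphere == contra_side], shape)

  # ---- lesion mask -------------------------------------------------------
  lab <- atlas$grid$data
  focus <- c(sgn * 0.75 * atlas$brain_radii[1], 0, 0)
  lesion_arr <- array(FALSE, shape)
  cov <- lesion$target_coverage
  achieved <- tibble::tibble(structure_id = integer(), target = numeric(),
                             achieved = numeric())
  if (length(cov)) {
    sids <- as.integer(names(cov))
    if (!all(sids %in% atlas$lookup$label_id)) {
      stop("unknown structure ids in `target_coverage`: ",
           paste(setdiff(sids, atlas$lookup$label_id), collapse = ", "),
           call. = FALSE)
    }
    hemi_of <- atlas$lookup$hemisphere[match(sids, atlas$lookup$label_id)]
    if (!all(hemi_of == ipsi_side)) {
      stop("lesioned structures must lie in the ipsilateral (", ipsi_side,
           ") hemisphere", call. = FALSE)
    }
    for (k in seq_along(sids)) {
      vox <- which(lab == sids[k], arr.ind = TRUE)
      n_take <- round(cov[k] * nrow(vox))
      if (n_take > 0) {
        w <- cbind(axes[[1]][vox[, 1]], axes[[2]][vox[, 2]],
                   axes[[3]][vox[, 3]])
        d <- rowSums(sweep(w, 2, focus)^2)
        pick <- vox[order(d)[seq_len(n_take)], , drop = FALSE]
        lesion_arr[pick] <- TRUE
      }
      achieved <- dplyr::bind_rows(achieved, tibble::tibble(
        structure_id = sids[k], target = unname(cov[k]),
        achieved = n_take / max(nrow(vox), 1)))
    }
  }
  for (el in lesion$extra_ellipsoids) {
    lesion_arr <- lesion_arr |
      ((ellipsoid_field(axes, el$center_mm, el$radii_mm) <= 1) & ipsi_base)
  }

  # ---- swelling / atrophy ------------------------------------------------
  voxvol <- prod(sp)
  n_contra_net <- sum(contra) - sum(vent_contra)
  n_delta <- round(swelling$volume_change_percent / 100 * n_contra_net)
  ipsi <- ipsi_base
  x_arr <- array(axes[[1]], dim = shape)
  cereb_arr <- hemis$cerebellum
  if (n_delta > 0) {
    allowed <- !ipsi & !contra & !cereb_arr & (sgn * x_arr > 0)
    need <- n_delta
    while (need > 0) {
      cand <- which(mask_halo(ipsi) & allowed)
      if (!length(cand)) stop("grid too small to absorb requested swelling",
                              call. = FALSE)
      take <- cand[seq_len(min(need, length(cand)))]
      ipsi[take] <- TRUE
      need <- need - length(take)
    }
  } else if (n_delta < 0) {
    protected <- lesion_arr | vent_ipsi
    need <- -n_delta
    while (need > 0) {
      cand <- which(mask_halo(!ipsi) & ipsi & !protected)
      if (!length(cand)) stop("cannot erode hemisphere further",
                              call. = FALSE)
      take <- cand[seq_len(min(need, length(cand)))]
      ipsi[take] <- FALSE
      need <- need - length(take)
    }
  }
  n_ipsi_net <- sum(ipsi) - sum(vent_ipsi)

  # ---- midline landmarks -------------------------------------------------
  # ideal midline plane is x = 0 with unit normal pointing contralateral;
  # septum landmark displaced by the specified shift along that normal
  normal <- c(-sgn, 0, 0)
  septum <- c(0, -0.22 * atlas$brain_radii[2], 0) +
    swelling$midline_shift_mm * normal
  landmarks <- midline_landmarks(septum_xyz_mm = septum,
                                 plane_point_xyz_mm = c(0, 0, 0),
                                 plane_normal_xyz = normal)

  vg <- function(arr) volume_grid(arr, spacing = sp, affine = atlas$grid$affine)
  ground_truth <- list(
    lesion_voxels = sum(lesion_arr),
    lesion_volume_cm3 = sum(lesion_arr) * voxvol / 1000,
    coverage = achieved,
    ipsi_hemisphere_cm3 = n_ipsi_net * voxvol / 1000,
    contra_hemisphere_cm3 = n_contra_net * voxvol / 1000,
    hemispheric_change_percent = 100 * (n_ipsi_net / n_contra_net - 1),
    requested_change_percent = swelling$volume_change_percent,
    midline_shift_mm = swelling$midline_shift_mm,
    ipsilateral = ipsi_side
  )
  structure(
    list(subject_id = subject_id, timepoint_day = timepoint_day,
         ipsilateral = ipsi_side,
         lesion = vg(lesion_arr),
         hemi_ipsi = vg(ipsi), hemi_contra = vg(contra),
         vent_ipsi = vg(vent_ipsi), vent_contra = vg(vent_contra),
         cerebellum = vg(cereb_arr),
         landmarks = landmarks,
         fa = NULL, fa_rois = NULL,
         ground_truth = ground_truth),
    class = "subject_imaging"
  )
}

#' @export
print.subject_imaging <- function(x, ...) {
  cat("<subject_imaging> ", x$subject_id, " day ", x$timepoint_day,
      ": lesion ", format(x$ground_truth$lesion_volume_cm3, digits = 4),
      " cm^3, ipsilateral ", x$ipsilateral, "\n", sep = "")
  invisible(x)
}

#' Generate a phantom fractional-anisotropy map with paired tract ROIs
#'
#' Produces a scalar FA volume in which a mirrored pair of corpus-callosum
#' ROIs straddles the midline: the contralateral ROI carries the healthy
#' baseline FA and the ipsilateral ROI carries `baseline * (1 - decrement)`,
#' each plus i.i.d. Gaussian noise, clipped to \[0, 1\].
#'
#' @param atlas A phantom [label_atlas()].
#' @param tract_decrement Fractional FA reduction in \[0, 1\] applied to the
#'   ipsilateral ROI.
#' @param noise_sd Gaussian noise SD added voxelwise.
#' @param seed Integer RNG seed.
#' @param ipsilateral `"right"` or `"left"`.
#' @param contra_baseline Healthy mean FA of the tract (default 0.45, a
#'   typical corpus-callosum value).
#' @param background_fa Mean FA assigned to non-ROI brain tissue.
#' @return List with `fa` (a `volume_grid`), `roi_ipsi`, `roi_contra`
#'   (binary `volume_grid`s of equal voxel count) and `tract_name`.
#' @export
generate_fa_map <- function(atlas, tract_decrement = 0.3, noise_sd = 0.05,
                            seed = 1L, ipsilateral = c("right", "left"),
                            contra_baseline = 0.45, background_fa = 0.25) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (tract_decrement < 0 || tract_decrement > 1) {
    stop("`tract_decrement` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  ipsilateral <- match.arg(ipsilateral)
  sgn <- if (ipsilateral == "right") 1 else -1
  shape <- dim(atlas$grid$data)
  sp <- atlas$grid$spacing
  axes <- phantom_axes(shape, sp)
  hemis <- atlas_hemisphere_arrays(atlas)
  cerebrum <- hemis$left | hemis$right

  x_arr <- array(axes[[1]], dim = shape)
  y_arr <- array(rep(axes[[2]], each = shape[1]), dim = shape)
  z_arr <- array(rep(axes[[3]], each = shape[1] * shape[2]), dim = shape)
  box <- function(s) (s * x_arr >= 2 & s * x_arr <= 8) &
    (y_arr >= -12 & y_arr <= 8) & (abs(z_arr) <= 6) & cerebrum
  roi_ipsi <- box(sgn)
  roi_contra <- box(-sgn)

  fa <- withr::with_seed(seed, {
    arr <- array(0, shape)
    arr[cerebrum] <- background_fa
    arr[roi_contra] <- contra_baseline
    arr[roi_ipsi] <- contra_baseline * (1 - tract_decrement)
    if (noise_sd > 0) {
      arr[cerebrum] <- arr[cerebrum] +
        stats::rnorm(sum(cerebrum), 0, noise_sd)
    }
    pmin(pmax(arr, 0), 1)
  })
  dim(fa) <- shape
  vg <- function(a) volume_grid(a, spacing = sp, affine = atlas$grid$affine)
  list(fa = vg(fa), roi_ipsi = vg(roi_ipsi), roi_contra = vg(roi_contra),
       tract_name = "corpus_callosum")
}
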