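#' Per-structure lesion overlap: percent of structure and percent of lesion
#'
#' The core lesion-topology statistics. For each atlas structure X and a
#' binary lesion mask:
#'
#' * PoS (percent of structure) = 100 x (lesion voxels overlapping X) /
#'   (total voxels of X) — how much of the structure is infarcted.
#' * PoL (percent of lesion) = 100 x (lesion voxels overlapping X) /
#'   (total lesion voxels) — how much of the infarct falls inside the
#'   structure (0 when the lesion is empty).
#'
#' Counts are voxel counts ("pixels" in the radiological sense); physical
#' volumes are available by multiplying by the voxel volume. Because atlas
#' labels are mutually exclusive, the PoL values over all structures plus
#' the unlabeled lesion fraction sum to exactly 100%.
#'
#' @param atlas A [label_atlas()].
#' @param lesion A binary `volume_grid` on the same grid as the atlas.
#' @param merge_pairs If `TRUE`, bilateral partner labels are merged into a
#'   single structure (denominator = both hemispheres' voxels) before
#'   scoring; by default each unilateral label is scored on its own.
#' @param subject_id,timepoint_day Identifiers copied into the output.
#' @return A tibble (`lt_overlap`) with one row per structure:
#'   `structure_id`, `structure_name`, `n_lesion_overlap_voxels`,
#'   `n_structure_voxels`, `n_lesion_voxels`, `pos_percent`, `pol_percent`.
#'   Structures with zero voxels in the label volume are dropped with a
#'   warning. Ventricle and cerebellum labels are scored like any other
#'   (lesions never intersect them in the phantom).
#' @export
#' @examples
#' atlas <- generate_atlas(phantom_config(n_structures_per_hemisphere = 4))
#' subj <- generate_subject(atlas,
#'   lesion_spec(target_coverage = c(`5` = 0.5)))
#' structure_overlap(atlas, subj$lesion)
structure_overlap <- function(atlas, lesion, merge_pairs = FALSE,
                              subject_id = NA_character_,
                              timepoint_day = NA_real_) {
  stopifnot(inherits(atlas, "label_atlas"))
  assert_same_grid(atlas$grid, lesion, "atlas and lesion mask")
  assert_binary(lesion, "lesion mask")
  lab <- atlas$grid$data
  les <- mask_array(lesion)

  lookup <- atlas$lookup
  if (merge_pairs) {
    # collapse each bilateral pair onto the smaller label id of the pair
    canon <- pmin(lookup$label_id,
                  dplyr::coalesce(lookup$partner_id, lookup$label_id))
    remap <- stats::setNames(canon, lookup$label_id)
    lab <- array(unname(remap[as.character(lab)]), dim(lab))
    lab[is.na(lab)] <- 0L
    lookup <- lookup[lookup$label_id %in% canon, ]
    lookup$name <- sub("_(left|right)$", "", lookup$name)
    lookup$hemisphere <- ifelse(is.na(lookup$partner_id),
                                lookup$hemisphere, "bilateral")
  }

  max_id <- max(lookup$label_id)
  n_struct <- tabulate(lab, nbins = max_id)
  n_overlap <- tabulate(lab[les], nbins = max_id)
  n_lesion <- sum(les)

  ids <- lookup$label_id
  empty <- ids[n_struct[ids] == 0]
  if (length(empty)) {
    warning("omitting ", length(empty),
            " structure(s) with zero voxels in the label volume: ",
            paste(lookup$name[match(empty, ids)], collapse = ", "),
            call. = FALSE)
    ids <- setdiff(ids, empty)
  }
  out <- tibble::tibble(
    subject_id = subject_id,
    timepoint_day = timepoint_day,
    structure_id = ids,
    structure_name = lookup$name[match(ids, lookup$label_id)],
    n_lesion_overlap_voxels = n_overlap[ids],
    n_structure_voxels = n_struct[ids],
    n_lesion_voxels = n_lesion,
    pos_percent = 100 * n_overlap[ids] / n_struct[ids],
    pol_percent = if (n_lesion > 0) 100 * n_overlap[ids] / n_lesion else 0
  )
  class(out) <- c("lt_overlap", class(out))
  out
}

#' Lesion incidence per structure across a cohort
#'
#' A subject counts as lesioned in a structure when its lesion-overlap voxel
#' count reaches `threshold_voxels` (default 1: any lesioned voxel marks the
#' structure positive). Incidence is the percentage of subjects lesioned,
#' per structure and timepoint, rounded to one decimal for reporting.
#'
#' @param cohort_overlap Overlap rows for all subjects (row-bound output of
#'   [structure_overlap()] with `subject_id`/`timepoint_day` set).
#' @param threshold_voxels Minimum overlap voxels for presence.
#' @return Tibble with `structure_id`, `structure_name`, `timepoint_day`,
#'   `n_subjects_lesioned`, `n_subjects_total`, `incidence_percent`.
#' @export
lesion_incidence <- function(cohort_overlap, threshold_voxels = 1) {
  stopifnot(nrow(cohort_overlap) >= 1, threshold_voxels >= 1)
  cohort_overlap |>
    dplyr::group_by(.data$structure_id, .data$structure_name,
                    .data$timepoint_day) |>
    dplyr::summarise(
      n_subjects_lesioned =
        sum(.data$n_lesion_overlap_voxels >= threshold_voxels),
      n_subjects_total = dplyr::n_distinct(.data$subject_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(incidence_percent =
                    round(100 * .data$n_subjects_lesioned /
                            .data$n_subjects_total, 1))
}

#' Rank structures by cohort-mean lesion burden
#'
#' Orders structures by their cohort-mean PoS (or PoL) in descending order,
#' breaking ties alphabetically by structure name for determinism.
#'
#' @param overlap Overlap rows (one or many subjects).
#' @param by `"pos"` or `"pol"`.
#' @param top_n Number of structures to keep; `Inf` keeps all.
#' @param lesioned_only If `TRUE`, each structure's mean is taken over only
#'   the subjects with nonzero overlap in it; the default averages across
#'   all subjects, zeros included.
#' @return Tibble `structure_id`, `structure_name`, `mean_score`,
#'   `sd_score`, `n_subjects`, ordered by decreasing `mean_score`.
#' @export
rank_structures <- function(overlap, by = c("pos", "pol"), top_n = Inf,
                            lesioned_only = FALSE) {
  by <- match.arg(by)
  if (nrow(overlap) == 0) {
    return(tibble::tibble(structure_id = integer(),
                          structure_name = character(),
                          mean_score = numeric(), sd_score = numeric(),
                          n_subjects = integer()))
  }
  col <- if (by == "pos") "pos_percent" else "pol_percent"
  df <- overlap
  if (lesioned_only) df <- dplyr::filter(df, .data$n_lesion_overlap_voxels > 0)
  df |>
    dplyr::group_by(.data$structure_id, .data$structure_name) |>
    dplyr::summarise(mean_score = mean(.data[[col]]),
                     sd_score = stats::sd(.data[[col]]),
                     n_subjects = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$structure_name) |>
    utils::head(n = if (is.finite(top_n)) top_n else nrow(overlap))
}
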