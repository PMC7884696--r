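#' Build the acute imaging feature matrix
#'
#' One row per subject; columns are the top-`top_n_structures` PoS features
#' (selected by cohort-mean PoS at the imaging timepoint, ties broken
#' alphabetically) named `pos:<structure>`, plus the four canonical MRI
#' metrics (`lesion_volume_cm3`, `lesion_percent_of_ipsi`,
#' `midline_shift_mm`, `hemispheric_change_percent`) when volumetrics rows
#' are supplied.
#'
#' @param overlap Cohort overlap rows (see [structure_overlap()]), already
#'   restricted to — or carrying — a single imaging timepoint.
#' @param volumetrics Optional [cohort_volumetrics()] rows for the same
#'   subjects and timepoint; `NULL` for PoS-only features.
#' @param top_n_structures Number of PoS features to keep (0 = none).
#' @param imaging_timepoint_day Timepoint to slice from both inputs; `NULL`
#'   uses all rows as given.
#' @return A wide tibble (`lt_features`) with `subject_id` plus feature
#'   columns; the imaging timepoint is attached as attribute
#'   `imaging_timepoint_day`.
#' @export
build_feature_matrix <- function(overlap, volumetrics = NULL,
                                 top_n_structures = 10,
                                 imaging_timepoint_day = NULL) {
  ov <- tibble::as_tibble(overlap)
  if (!is.null(imaging_timepoint_day)) {
    ov <- dplyr::filter(ov, .data$timepoint_day == imaging_timepoint_day)
    if (!is.null(volumetrics)) {
      volumetrics <- dplyr::filter(volumetrics,
                                   .data$timepoint_day ==
                                     imaging_timepoint_day)
    }
  }
  if (nrow(ov) == 0) stop("no overlap rows at the requested timepoint",
                          call. = FALSE)
  feats <- dplyr::distinct(ov, .data$subject_id)
  if (top_n_structures > 0) {
    top <- rank_structures(ov, by = "pos", top_n = top_n_structures)
    pos_wide <- ov |>
      dplyr::filter(.data$structure_id %in% top$structure_id) |>
      dplyr::transmute(.data$subject_id,
                       feature = paste0("pos:", .data$structure_name),
                       .data$pos_percent) |>
      tidyr::pivot_wider(names_from = "feature",
                         values_from = "pos_percent")
    feats <- dplyr::left_join(feats, pos_wide, by = "subject_id")
  }
  if (!is.null(volumetrics)) {
    canon <- volumetrics[, c("subject_id", "lesion_volume_cm3",
                             "lesion_percent_of_ipsi", "midline_shift_mm",
                             "hemispheric_change_percent")]
    missing <- setdiff(feats$subject_id, canon$subject_id)
    if (length(missing)) {
      stop("volumetrics rows missing for subjects: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    feats <- dplyr::left_join(feats, canon, by = "subject_id")
  }
  attr(feats, "imaging_timepoint_day") <-
    imaging_timepoint_day %||% unique(ov$timepoint_day)[1]
  class(feats) <- c("lt_features", class(feats))
  feats
}

#' Correlate imaging features with functional outcomes
#'
#' Pearson correlation of each imaging feature against each functional
#' outcome at one outcome timepoint, within the stroked group only, with
#' two filters before Benjamini-Hochberg FDR adjustment:
#'
#' * minimum-lesioned filter: a `pos:` feature enters only if at least
#'   `min_lesioned` subjects have nonzero PoS in that structure;
#' * degeneracy filter: feature/outcome pairs with zero variance are
#'   flagged and excluded.
#'
#' Excluded cells never participate in the FDR family, so they cannot
#' alter the adjusted p-values of included cells. The FDR family is all
#' included cells of this call (one heatmap) by default.
#'
#' @param features An [build_feature_matrix()] tibble.
#' @param outcomes Tidy outcome rows (see [generate_outcomes()]).
#' @param outcome_timepoint_day Outcome timepoint to correlate against.
#' @param parameters Outcome parameters to use; default the six gait
#'   spatiotemporal parameters.
#' @param limb Limb to slice for limb-specific parameters (default `"LF"`,
#'   the forelimb contralateral to a right MCAO).
#' @param group Outcome group treated as stroked (default `"MCAO"`).
#' @param min_lesioned Minimum subjects with a lesion in a structure for
#'   its feature to be correlated (default 3).
#' @param fdr_family `"per_heatmap"` (adjust over all included cells of
#'   this call) or `"per_outcome"` (adjust within each outcome column).
#' @return Tibble (`lt_heatmap`) of heatmap cells: `feature`, `outcome`,
#'   `outcome_timepoint_day`, `r`, `n_used`, `p_raw`, `p_fdr`, `included`,
#'   `reason`.
#' @export
correlate_outcomes <- function(features, outcomes, outcome_timepoint_day,
                               parameters = c("velocity", "cadence",
                                              "stride_length", "step_length",
                                              "swing_percent",
                                              "stance_percent"),
                               limb = "LF", group = "MCAO",
                               min_lesioned = 3,
                               fdr_family = c("per_heatmap", "per_outcome")) {
  fdr_family <- match.arg(fdr_family)
  out <- outcomes |>
    dplyr::filter(.data$group == !!group,
                  .data$timepoint_day == outcome_timepoint_day,
                  .data$parameter %in% parameters,
                  is.na(.data$limb) | .data$limb == !!limb) |>
    dplyr::select("subject_id", "parameter", "value") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value")

  df <- dplyr::inner_join(tibble::as_tibble(features), out,
                          by = "subject_id")
  if (nrow(df) == 0) stop("no stroked subjects shared between features and ",
                          "outcomes", call. = FALSE)
  feature_cols <- setdiff(names(features), "subject_id")
  outcome_cols <- intersect(parameters, names(df))

  cells <- tidyr::expand_grid(feature = feature_cols,
                              outcome = outcome_cols) |>
    purrr::pmap_dfr(function(feature, outcome) {
      x <- df[[feature]]
      y <- df[[outcome]]
      keep <- !is.na(x) & !is.na(y)
      n_used <- sum(keep)
      lesioned <- if (startsWith(feature, "pos:")) sum(x[keep] > 0) else NA
      base <- tibble::tibble(feature = feature, outcome = outcome,
                             outcome_timepoint_day = outcome_timepoint_day,
                             r = NA_real_, n_used = n_used,
                             p_raw = NA_real_, p_fdr = NA_real_,
                             included = FALSE, reason = NA_character_)
      if (startsWith(feature, "pos:") && lesioned < min_lesioned) {
        base$reason <- sprintf("lesioned in %d < %d subjects", lesioned,
                               min_lesioned)
        return(base)
      }
      if (n_used < 3) {
        base$reason <- "fewer than 3 complete pairs"
        return(base)
      }
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        base$reason <- "zero variance"
        return(base)
      }
      ht <- pearson_r(x[keep], y[keep])
      base$r <- ht$estimate
      base$p_raw <- ht$p_value
      base$included <- TRUE
      base
    })

  if (any(cells$included)) {
    if (fdr_family == "per_heatmap") {
      cells$p_fdr[cells$included] <- bh_fdr(cells$p_raw[cells$included])
    } else {
      cells <- cells |>
        dplyr::group_by(.data$outcome) |>
        dplyr::mutate(p_fdr = ifelse(.data$included,
                                     bh_fdr(ifelse(.data$included,
                                                   .data$p_raw, NA)),
                                     NA_real_)) |>
        dplyr::ungroup()
    }
  } else {
    warning("no cells passed the inclusion filters; empty heatmap",
            call. = FALSE)
  }
  class(cells) <- c("lt_heatmap", class(cells))
  cells
}

#' Export heatmap cells to CSV
#'
#' Writes a wide CSV of r values (features as rows, outcomes as columns;
#' excluded cells empty) and a long CSV with the full per-cell record.
#' Reading the long CSV back with [read_heatmap()] reconstructs the cell
#' table exactly.
#'
#' @param cells An `lt_heatmap` tibble.
#' @param path_prefix Output path prefix; writes
#'   `<prefix>_r_wide.csv` and `<prefix>_cells_long.csv`.
#' @return Written paths, invisibly.
#' @export
export_heatmap <- function(cells, path_prefix) {
  if (nrow(cells) == 0) stop("empty heatmap table", call. = FALSE)
  wide <- cells |>
    dplyr::mutate(r_chr = ifelse(.data$included,
                                 formatC(.data$r, format = "g",
                                         digits = 15), "")) |>
    dplyr::select("feature", "outcome", "r_chr") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "r_chr")
  wide_path <- paste0(path_prefix, "_r_wide.csv")
  long_path <- paste0(path_prefix, "_cells_long.csv")
  readr::write_csv(wide, wide_path)
  readr::write_csv(tibble::as_tibble(cells), long_path)
  invisible(c(wide_path, long_path))
}

#' @rdname export_heatmap
#' @param path Path to a `<prefix>_cells_long.csv` file.
#' @export
read_heatmap <- function(path) {
  cells <- readr::read_csv(path, col_types = readr::cols(
    feature = readr::col_character(),
    outcome = readr::col_character(),
    outcome_timepoint_day = readr::col_double(),
    r = readr::col_double(),
    n_used = readr::col_integer(),
    p_raw = readr::col_double(),
    p_fdr = readr::col_double(),
    included = readr::col_logical(),
    reason = readr::col_character()
  ))
  class(cells) <- c("lt_heatmap", class(cells))
  cells
}
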