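#' Create a label atlas
#'
#' A `label_atlas` couples an integer parcellation volume (0 = background)
#' with a lookup table describing each label: its structure name, anatomical
#' region group, hemisphere, bilateral partner label, and whether it is a
#' ventricle or cerebellar label. This mirrors how parcellation atlases are
#' distributed for atlas-registered lesion analysis: one label image plus one
#' lookup CSV.
#'
#' @param grid A `volume_grid` whose data are integer labels (0 background).
#' @param lookup A data frame with columns `label_id`, `name`, `region_group`,
#'   `hemisphere` (`"left"`, `"right"` or `"midline"`), `partner_id`
#'   (`NA` for unpaired labels), `is_ventricle`, `is_cerebellum`.
#'
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(grid, lookup) {
  stopifnot(inherits(grid, "volume_grid"))
  lookup <- tibble::as_tibble(lookup)
  needed <- c("label_id", "name", "region_group", "hemisphere", "partner_id",
              "is_ventricle", "is_cerebellum")
  missing_cols <- setdiff(needed, names(lookup))
  if (length(missing_cols)) {
    stop("atlas lookup is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lookup$label_id)) {
    stop("atlas lookup has duplicated label ids", call. = FALSE)
  }
  labs <- sort(unique(as.vector(grid$data)))
  labs <- labs[labs != 0]
  if (!all(labs %in% lookup$label_id)) {
    stop("labels present in the volume but absent from the lookup: ",
         paste(setdiff(labs, lookup$label_id), collapse = ", "), call. = FALSE)
  }
  structure(list(grid = grid, lookup = lookup), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("<label_atlas> ", nrow(x$lookup), " labels on ",
      paste(dim(x$grid$data), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Write / read an atlas as NIfTI + lookup CSV
#'
#' @param atlas A `label_atlas`.
#' @param nii_path Path for the label volume (`.nii.gz`).
#' @param lookup_path Path for the lookup CSV.
#' @return Paths, invisibly.
#' @export
write_atlas <- function(atlas, nii_path, lookup_path) {
  stopifnot(inherits(atlas, "label_atlas"))
  write_volume(atlas$grid, nii_path)
  readr::write_csv(atlas$lookup, lookup_path)
  invisible(c(nii_path, lookup_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(nii_path, lookup_path) {
  grid <- read_volume(nii_path)
  grid$data <- array(as.integer(round(grid$data)), dim(grid$data))
  lookup <- readr::read_csv(lookup_path, show_col_types = FALSE)
  label_atlas(grid, lookup)
}

# label ids for a predicate on the lookup, e.g. ventricles of one hemisphere
atlas_labels <- function(atlas, ...) {
  dplyr::filter(atlas$lookup, ...)$label_id
}

# logical mask of a set of label ids
atlas_label_mask <- function(atlas, label_ids) {
  arr <- atlas$grid$data %in% label_ids
  dim(arr) <- dim(atlas$grid$data)
  volume_grid(arr, spacing = atlas$grid$spacing, affine = atlas$grid$affine)
}
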