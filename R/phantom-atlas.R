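#' Phantom cohort configuration
#'
#' Parameters of the synthetic brain phantom used throughout the package's
#' tests and examples. The phantom emulates the geometry the lesion-topology
#' pipeline consumes — a bilaterally symmetric parcellation with ventricles
#' and a cerebellum, MCA-territory-like lesions, hemispheric swelling with a
#' known midline shift — with exact, recorded ground truth. It makes no
#' attempt at MR contrast realism (no bias fields, no partial voluming).
#'
#' @param grid_shape Integer length-3 voxel counts; each >= 16 and the first
#'   (left-right) axis even, so the interhemispheric midline falls exactly
#'   between two voxel columns.
#' @param voxel_size_mm Numeric length-3 voxel spacing in mm. The default
#'   `c(1, 1, 3)` uses the 3.0 mm slice thickness typical of clinical T2W
#'   stroke protocols.
#' @param n_structures_per_hemisphere Number of paired grey-matter structures
#'   to pack into each hemisphere.
#' @param ventricle_fraction Fraction of each cerebral hemisphere occupied by
#'   its lateral ventricle, in (0, 0.2).
#' @param cerebellum_fraction Fraction of the whole brain assigned to the
#'   cerebellum, in (0, 0.3).
#' @param seed Integer RNG seed; a fixed seed makes every generated volume
#'   and table byte-identical across runs.
#'
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 24),
                           voxel_size_mm = c(1, 1, 3),
                           n_structures_per_hemisphere = 10,
                           ventricle_fraction = 0.08,
                           cerebellum_fraction = 0.12,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(voxel_size_mm) == 3)
  if (any(grid_shape < 16)) {
    stop("each `grid_shape` component must be >= 16", call. = FALSE)
  }
  if (grid_shape[1] %% 2 != 0) {
    stop("the left-right axis of `grid_shape` must be even so the midline ",
         "plane lies between voxels", call. = FALSE)
  }
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (ventricle_fraction <= 0 || ventricle_fraction >= 0.2) {
    stop("`ventricle_fraction` must lie in (0, 0.2)", call. = FALSE)
  }
  if (cerebellum_fraction <= 0 || cerebellum_fraction >= 0.3) {
    stop("`cerebellum_fraction` must lie in (0, 0.3)", call. = FALSE)
  }
  if (n_structures_per_hemisphere < 1) {
    stop("need at least one structure per hemisphere", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape,
         voxel_size_mm = as.numeric(voxel_size_mm),
         n_structures_per_hemisphere = as.integer(n_structures_per_hemisphere),
         ventricle_fraction = ventricle_fraction,
         cerebellum_fraction = cerebellum_fraction,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# world coordinates per axis, brain centred at the world origin; the midline
# plane is x = 0 and voxel mirroring i -> nx - 1 - i maps x -> -x exactly
phantom_axes <- function(shape, spacing) {
  lapply(1:3, function(a) {
    (seq_len(shape[a]) - 1 - (shape[a] - 1) / 2) * spacing[a]
  })
}

phantom_origin <- function(shape, spacing) -(shape - 1) * spacing / 2

# squared normalized ellipsoid coordinate field for centre/radii (mm)
ellipsoid_field <- function(axes, center, radii) {
  x2 <- ((axes[[1]] - center[1]) / radii[1])^2
  y2 <- ((axes[[2]] - center[2]) / radii[2])^2
  z2 <- ((axes[[3]] - center[3]) / radii[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

# mirror a 3D array across the midline (first axis)
mirror_x <- function(arr) arr[dim(arr)[1]:1, , , drop = FALSE]

# solve for the ellipsoid cap plane offset t (in units of the semi-axis)
# whose cap-beyond-t volume is `frac` of the full ellipsoid
cap_offset_for_fraction <- function(frac) {
  stats::uniroot(function(t) (2 - 3 * t + t^3) / 4 - frac,
                 interval = c(0, 1 - 1e-9))$root
}

phantom_structure_names <- function(n) {
  named <- c(
    claustrum = "striate_system", putamen = "striate_system",
    insular_cortex = "brodmann_area",
    inferior_temporal_gyrus = "brodmann_area",
    superior_temporal_gyrus = "brodmann_area",
    middle_temporal_gyrus = "brodmann_area",
    somatosensory_association_cortex = "brodmann_area",
    secondary_visual_cortex = "brodmann_area",
    globus_pallidus = "striate_system",
    primary_somatosensory_cortex = "brodmann_area",
    caudate_nucleus = "striate_system", hippocampus = "limbic_system",
    amygdala = "limbic_system", fornix = "limbic_system",
    subiculum = "limbic_system", pulvinar_nuclei = "thalamus",
    reticular_thalamic_nucleus = "thalamus",
    ventral_anterior_thalamic_nucleus = "thalamus",
    ventral_posterior_thalamic_nucleus = "thalamus",
    primary_motor_cortex = "brodmann_area",
    primary_visual_cortex = "brodmann_area",
    associative_visual_cortex = "brodmann_area",
    parahippocampal_cortex = "brodmann_area",
    fusiform_gyrus = "brodmann_area", prepiriform_area = "brodmann_area",
    anterior_entorhinal_cortex = "brodmann_area",
    dorsolateral_prefrontal_cortex = "brodmann_area",
    anterior_prefrontal_cortex = "brodmann_area",
    orbitofrontal_cortex = "brodmann_area",
    dorsal_anterior_cingulate_cortex = "brodmann_area"
  )
  nm <- names(named)
  grp <- unname(named)
  if (n > length(nm)) {
    extra <- sprintf("structure_%02d", seq(length(nm) + 1, n))
    nm <- c(nm, extra)
    grp <- c(grp, rep("other", length(extra)))
  }
  list(name = nm[seq_len(n)], region_group = grp[seq_len(n)])
}

#' Generate a synthetic parcellation atlas
#'
#' Builds a bilaterally mirror-symmetric label volume: paired grey-matter
#' structures are axis-aligned ellipsoids packed on a jittered lattice in the
#' left cerebral hemisphere and reflected across the midline plane into the
#' right; one lateral ventricle per hemisphere sits near the midline; a
#' posterior cap of the brain ellipsoid forms the (unpaired) cerebellum.
#' Every voxel carries at most one label, and the mirror image of each
#' left-hemisphere structure is exactly its right-hemisphere partner.
#'
#' @param config A [phantom_config()].
#' @return A [label_atlas()]. The attached lookup flags ventricle and
#'   cerebellar labels and records each label's bilateral `partner_id`.
#' @export
#' @examples
#' atlas <- generate_atlas(phantom_config(n_structures_per_hemisphere = 6))
#' atlas$lookup
generate_atlas <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_atlas_impl(config))
}

generate_atlas_impl <- function(config) {
  shape <- config$grid_shape
  sp <- config$voxel_size_mm
  n <- config$n_structures_per_hemisphere
  axes <- phantom_axes(shape, sp)
  half_extent <- shape * sp / 2
  brain_radii <- 0.94 * half_extent

  brain <- ellipsoid_field(axes, c(0, 0, 0), brain_radii) <= 1
  # posterior (+y) cap of the brain ellipsoid = cerebellum
  t_cap <- cap_offset_for_fraction(config$cerebellum_fraction)
  y_arr <- array(rep(axes[[2]], each = shape[1]), dim = shape)
  cerebellum <- brain & (y_arr > t_cap * brain_radii[2])
  cerebrum <- brain & !cerebellum

  x_arr <- array(axes[[1]], dim = shape)
  left_cerebrum <- cerebrum & (x_arr < 0)

  # left lateral ventricle sized to the requested hemisphere fraction
  voxvol <- prod(sp)
  n_hemi <- sum(left_cerebrum)
  target_vent_mm3 <- config$ventricle_fraction * n_hemi * voxvol
  vshape <- c(0.45, 1.5, 0.9)        # narrow, elongated anterior-posterior
  u <- (target_vent_mm3 / (4 / 3 * pi * prod(vshape)))^(1 / 3)
  vent_center <- c(-0.16 * brain_radii[1], -0.22 * brain_radii[2], 0)
  vent_left <- (ellipsoid_field(axes, vent_center, u * vshape) <= 1) &
    left_cerebrum

  labels <- array(0L, dim = shape)
  # pack structures on a jittered lattice inside the left cerebrum
  placeable <- left_cerebrum & !vent_left
  idx <- which(placeable, arr.ind = TRUE)
  box_lo <- c(min(axes[[1]][idx[, 1]]), min(axes[[2]][idx[, 2]]),
              min(axes[[3]][idx[, 3]]))
  box_hi <- c(max(axes[[1]][idx[, 1]]), max(axes[[2]][idx[, 2]]),
              max(axes[[3]][idx[, 3]]))
  extent <- box_hi - box_lo
  # lattice dimensions roughly proportional to box extents
  q <- pmax(1L, round((2 * n)^(1 / 3) * extent / prod(extent)^(1 / 3)))
  while (prod(q) < 2 * n) q[which.min(q * extent / max(extent))] <-
      q[which.min(q * extent / max(extent))] + 1L
  cell <- extent / q
  centers <- as.matrix(expand.grid(
    box_lo[1] + (seq_len(q[1]) - 0.5) * cell[1],
    box_lo[2] + (seq_len(q[2]) - 0.5) * cell[2],
    box_lo[3] + (seq_len(q[3]) - 0.5) * cell[3]
  ))
  centers <- centers + matrix(stats::runif(length(centers), -0.08, 0.08),
                              ncol = 3) * rep(cell, each = nrow(centers))
  # keep cells whose centre lies in placeable tissue, nearest-first
  ctr_vox <- round(sweep(sweep(centers, 2, phantom_origin(shape, sp)), 2, sp,
                         "/")) + 1
  ok <- ctr_vox[, 1] >= 1 & ctr_vox[, 1] <= shape[1] &
    ctr_vox[, 2] >= 1 & ctr_vox[, 2] <= shape[2] &
    ctr_vox[, 3] >= 1 & ctr_vox[, 3] <= shape[3]
  ok[ok] <- placeable[ctr_vox[ok, , drop = FALSE]]
  centers <- centers[ok, , drop = FALSE]
  centroid <- colMeans(as.matrix(idx))
  ctr_world <- c(axes[[1]][round(centroid[1])], axes[[2]][round(centroid[2])],
                 axes[[3]][round(centroid[3])])
  ord <- order(rowSums(sweep(centers, 2, ctr_world)^2))
  centers <- centers[ord, , drop = FALSE]
  if (nrow(centers) < n) {
    stop("grid too small to place ", n, " structures per hemisphere; ",
         "only ", nrow(centers), " lattice sites available", call. = FALSE)
  }
  placed <- 0L
  i <- 1L
  while (placed < n && i <= nrow(centers)) {
    radii <- 0.48 * cell * stats::runif(3, 0.8, 1.0)
    vox <- (ellipsoid_field(axes, centers[i, ], radii) <= 1) & placeable &
      labels == 0L
    if (sum(vox) >= 4) {
      placed <- placed + 1L
      labels[vox] <- placed
    }
    i <- i + 1L
  }
  if (placed < n) {
    stop("grid too small to place ", n, " structures per hemisphere",
         call. = FALSE)
  }

  # mirror left structures into the right hemisphere: partner of k is k + n
  right <- mirror_x(labels)
  labels[right > 0L] <- right[right > 0L] + n

  vent_l_id <- 2L * n + 1L
  vent_r_id <- 2L * n + 2L
  cereb_id <- 2L * n + 3L
  labels[vent_left] <- vent_l_id
  labels[mirror_x(vent_left)] <- vent_r_id
  labels[cerebellum] <- cereb_id

  nm <- phantom_structure_names(n)
  lookup <- tibble::tibble(
    label_id = c(seq_len(n), n + seq_len(n), vent_l_id, vent_r_id, cereb_id),
    name = c(paste0(nm$name, "_left"), paste0(nm$name, "_right"),
             "lateral_ventricle_left", "lateral_ventricle_right",
             "cerebellum"),
    region_group = c(nm$region_group, nm$region_group,
                     "ventricular_system", "ventricular_system",
                     "cerebellum"),
    hemisphere = c(rep("left", n), rep("right", n), "left", "right",
                   "midline"),
    partner_id = c(n + seq_len(n), seq_len(n), vent_r_id, vent_l_id,
                   NA_integer_),
    is_ventricle = c(rep(FALSE, 2 * n), TRUE, TRUE, FALSE),
    is_cerebellum = c(rep(FALSE, 2 * n), FALSE, FALSE, TRUE)
  )
  grid <- volume_grid(labels, spacing = sp,
                      origin = phantom_origin(shape, sp))
  out <- label_atlas(grid, lookup)
  out$brain_radii <- brain_radii
  out$config <- config
  out
}

# cerebral hemisphere masks implied by the atlas geometry (ventricles kept
# inside the hemisphere; cerebellum and background excluded)
atlas_hemisphere_arrays <- function(atlas) {
  shape <- dim(atlas$grid$data)
  sp <- atlas$grid$spacing
  axes <- phantom_axes(shape, sp)
  cereb_ids <- atlas_labels(atlas, .data$is_cerebellum)
  brain <- ellipsoid_field(axes, c(0, 0, 0), atlas$brain_radii) <= 1
  cereb <- array(atlas$grid$data %in% cereb_ids, shape)
  cerebrum <- brain & !cereb
  x_arr <- array(axes[[1]], dim = shape)
  list(left = cerebrum & (x_arr < 0), right = cerebrum & (x_arr > 0),
       cerebellum = cereb)
}
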