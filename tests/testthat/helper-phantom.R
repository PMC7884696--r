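# Shared fixtures, all generated in code.

# one small atlas reused across tests (generation is deterministic)
small_config <- function(seed = 42L) {
  phantom_config(grid_shape = c(32, 32, 16), voxel_size_mm = c(2, 2, 3),
                 n_structures_per_hemisphere = 4, seed = seed)
}

small_atlas_cache <- new.env()
small_atlas <- function() {
  if (is.null(small_atlas_cache$atlas)) {
    small_atlas_cache$atlas <- generate_atlas(small_config())
  }
  small_atlas_cache$atlas
}

# a random label volume + lesion mask on a tiny grid, as a label_atlas
random_label_phantom <- function(shape, n_labels, lesion_prob = 0.2,
                                 spacing = c(1, 1, 1)) {
  lab <- array(sample(0:n_labels, prod(shape), replace = TRUE), shape)
  lookup <- tibble::tibble(
    label_id = seq_len(n_labels),
    name = sprintf("s%02d", seq_len(n_labels)),
    region_group = "other", hemisphere = "left",
    partner_id = NA_integer_, is_ventricle = FALSE, is_cerebellum = FALSE)
  atlas <- label_atlas(volume_grid(lab, spacing = spacing), lookup)
  lesion <- volume_grid(array(stats::runif(prod(shape)) < lesion_prob,
                              shape), spacing = spacing)
  list(atlas = atlas, lesion = lesion)
}

# literal three-nested-loop voxel overlap counter (independent oracle)
triple_loop_overlap <- function(atlas, lesion, label) {
  lab <- atlas$grid$data
  les <- lesion$data
  d <- dim(lab)
  n_struct <- 0L; n_overlap <- 0L; n_lesion <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    in_lesion <- isTRUE(les[i, j, k]) || (is.numeric(les[i, j, k]) &&
                                            les[i, j, k] != 0)
    if (in_lesion) n_lesion <- n_lesion + 1L
    if (lab[i, j, k] == label) {
      n_struct <- n_struct + 1L
      if (in_lesion) n_overlap <- n_overlap + 1L
    }
  }
  list(n_struct = n_struct, n_overlap = n_overlap, n_lesion = n_lesion)
}

# single-pass variant: per-label structure and overlap counts for all labels
triple_loop_overlap_all <- function(atlas, lesion, n_labels) {
  lab <- atlas$grid$data
  les <- lesion$data
  d <- dim(lab)
  n_struct <- integer(n_labels); n_overlap <- integer(n_labels)
  n_lesion <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    in_lesion <- les[i, j, k]
    if (in_lesion) n_lesion <- n_lesion + 1L
    l <- lab[i, j, k]
    if (l > 0L) {
      n_struct[l] <- n_struct[l] + 1L
      if (in_lesion) n_overlap[l] <- n_overlap[l] + 1L
    }
  }
  list(n_struct = n_struct, n_overlap = n_overlap, n_lesion = n_lesion)
}

# overlap-like tibble straight from sampled PoS records (no volumes), for
# exercising the correlation pipeline at scale
pos_as_overlap <- function(cohort_pos, timepoint_day = 1) {
  out <- cohort_pos
  out$timepoint_day <- timepoint_day
  out$structure_name <- sprintf("s%02d", out$structure_id)
  out$n_lesion_overlap_voxels <- as.integer(round(out$pos_percent * 10))
  out$n_structure_voxels <- 1000L
  out$n_lesion_voxels <- 10000L
  out$pol_percent <- 0
  out
}
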