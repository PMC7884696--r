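test_that("PoS/PoL match a literal triple-loop count on random phantoms", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      shape <- sample(8:16, 3, replace = TRUE)
      ph <- random_label_phantom(shape, n_labels = 4)
      ov <- structure_overlap(ph$atlas, ph$lesion)
      for (lab in 1:4) {
        oracle <- triple_loop_overlap(ph$atlas, ph$lesion, lab)
        row <- ov[ov$structure_id == lab, ]
        if (oracle$n_struct == 0) {
          expect_equal(nrow(row), 0)
        } else {
          expect_equal(row$n_lesion_overlap_voxels, oracle$n_overlap)
          expect_equal(row$n_structure_voxels, oracle$n_struct)
          expect_equal(row$pos_percent,
                       100 * oracle$n_overlap / oracle$n_struct)
          expect_equal(row$pol_percent,
                       100 * oracle$n_overlap / oracle$n_lesion)
        }
      }
    }
  })
})

test_that("PoL over all labels plus the unlabeled fraction is exactly 100", {
  withr::with_seed(12, ph <- random_label_phantom(c(12, 12, 12), 5))
  ov <- structure_overlap(ph$atlas, ph$lesion)
  les <- ph$lesion$data
  n_unlabeled <- sum(les & ph$atlas$grid$data == 0)
  expect_identical(sum(ov$n_lesion_overlap_voxels) + n_unlabeled, sum(les))
  expect_equal(sum(ov$pol_percent) + 100 * n_unlabeled / sum(les), 100)
})

test_that("degenerate lesions behave: identical to structure, empty", {
  atlas <- small_atlas()
  sid <- atlas$lookup$label_id[atlas$lookup$hemisphere == "right"][1]
  lesion <- lesiontopo:::atlas_label_mask(atlas, sid)
  ov <- structure_overlap(atlas, lesion)
  row <- ov[ov$structure_id == sid, ]
  expect_equal(row$pos_percent, 100)
  expect_equal(row$pol_percent, 100)
  empty <- volume_grid(array(FALSE, dim(atlas$grid$data)),
                       spacing = atlas$grid$spacing,
                       affine = atlas$grid$affine)
  ov0 <- structure_overlap(atlas, empty)
  expect_true(all(ov0$pos_percent == 0) && all(ov0$pol_percent == 0))
})

test_that("adding a lesion voxel inside a structure never lowers its scores", {
  withr::with_seed(13, ph <- random_label_phantom(c(10, 10, 10), 3,
                                                  lesion_prob = 0.1))
  ov1 <- structure_overlap(ph$atlas, ph$lesion)
  inside <- which(ph$atlas$grid$data == 2 & !ph$lesion$data)
  skip_if(length(inside) == 0)
  les2 <- ph$lesion
  les2$data[inside[1]] <- TRUE
  ov2 <- structure_overlap(ph$atlas, les2)
  expect_gte(ov2$pos_percent[ov2$structure_id == 2],
             ov1$pos_percent[ov1$structure_id == 2])
})

test_that("grid mismatches are rejected", {
  atlas <- small_atlas()
  wrong <- volume_grid(array(FALSE, c(8, 8, 8)))
  expect_error(structure_overlap(atlas, wrong), "grid mismatch")
})

test_that("merging bilateral pairs pools both hemispheres' denominators", {
  atlas <- small_atlas()
  n <- atlas$config$n_structures_per_hemisphere
  sid_r <- n + 1L   # right partner of structure 1
  lesion <- lesiontopo:::atlas_label_mask(atlas, sid_r)
  ov_uni <- structure_overlap(atlas, lesion)
  ov_bi <- structure_overlap(atlas, lesion, merge_pairs = TRUE)
  uni <- ov_uni[ov_uni$structure_id == sid_r, ]
  bi <- ov_bi[ov_bi$structure_id == 1L, ]
  expect_equal(uni$pos_percent, 100)
  # the merged denominator includes the mirrored left copy: PoS halves
  expect_equal(bi$n_structure_voxels, 2L * uni$n_structure_voxels)
  expect_equal(bi$pos_percent, 50)
  expect_false(any(grepl("_right$", ov_bi$structure_name)))
})

test_that("incidence reproduces the k-of-n percentage lattice", {
  mk <- function(k, n = 7) {
    purrr::map_dfr(seq_len(n), function(s) tibble::tibble(
      subject_id = paste0("p", s), timepoint_day = 1,
      structure_id = 1L, structure_name = "claustrum",
      n_lesion_overlap_voxels = ifelse(s <= k, 5L, 0L),
      n_structure_voxels = 100L, n_lesion_voxels = 500L,
      pos_percent = 0, pol_percent = 0))
  }
  expect_equal(lesion_incidence(mk(7))$incidence_percent, 100)
  expect_equal(lesion_incidence(mk(2))$incidence_percent, 28.6)
  expect_equal(lesion_incidence(mk(0))$incidence_percent, 0)
  # presence threshold is configurable
  expect_equal(lesion_incidence(mk(3), threshold_voxels = 6)$incidence_percent,
               0)
})

test_that("structure ranking equals a brute-force sort with name tie-break", {
  withr::with_seed(14, {
    tbl <- tidyr::expand_grid(subject_id = paste0("s", 1:5),
                              structure_id = 1:6)
    tbl$structure_name <- c("b", "a", "c", "e", "d", "f")[tbl$structure_id]
    tbl$pos_percent <- runif(nrow(tbl), 0, 80)
    tbl$pol_percent <- 0
    tbl$n_lesion_overlap_voxels <- 1L
    tbl$timepoint_day <- 1
  })
  rk <- rank_structures(tbl, by = "pos", top_n = 3)
  means <- tapply(tbl$pos_percent, tbl$structure_name, mean)
  oracle <- names(sort(-means))  # sorted descending, names break ties
  expect_equal(rk$structure_name, oracle[1:3])
  # top_n beyond the table returns everything
  expect_equal(nrow(rank_structures(tbl, top_n = 100)), 6)
  expect_equal(nrow(rank_structures(tbl[0, ], top_n = 3)), 0)
  # exact ties break alphabetically by structure name
  tie <- tbl
  tie$pos_percent <- 50
  expect_equal(rank_structures(tie)$structure_name,
               sort(unique(tie$structure_name)))
})
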