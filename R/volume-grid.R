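#' Create a volume grid
#'
#' A `volume_grid` is the common substrate for every 3D image the package
#' touches: parcellation atlases, binary lesion/hemisphere/ventricle masks,
#' and scalar fractional-anisotropy maps. It wraps a 3D array together with
#' voxel spacing (mm) and a 4x4 voxel-to-world affine. Voxel indices are
#' 0-based in world-coordinate computations; world coordinates are mm.
#'
#' @param data A 3D numeric, integer, or logical array.
#' @param spacing Numeric length-3 voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3 world coordinate (mm) of voxel (0, 0, 0).
#'   Ignored when `affine` is supplied.
#' @param affine Optional 4x4 voxel-to-world affine. Defaults to a diagonal
#'   affine built from `spacing` and `origin`.
#'
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' vg <- volume_grid(array(0, c(16, 16, 8)), spacing = c(1, 1, 3))
#' voxel_volume_mm3(vg)
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel edge lengths (mm)", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- as.numeric(origin)
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  structure(
    list(data = data, spacing = spacing, affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm (",
      storage.mode(x$data), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Voxel volume in cubic millimetres
#' @param grid A `volume_grid`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$spacing)
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param grid A `volume_grid`.
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, ijk) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.vector(ijk)) ijk <- matrix(ijk, nrow = 1)
  h <- cbind(ijk, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @export
world_to_voxel <- function(grid, xyz) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(grid$affine))
  out[, 1:3, drop = FALSE]
}

# TRUE when two grids share shape, spacing and affine (to tolerance)
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

assert_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop("grid mismatch: ", what, " must share shape, spacing and affine",
         call. = FALSE)
  }
  invisible(TRUE)
}

assert_binary <- function(grid, what = "mask") {
  v <- grid$data
  if (is.logical(v)) return(invisible(TRUE))
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1))) {
    stop(what, " must be binary (0/1 or logical)", call. = FALSE)
  }
  invisible(TRUE)
}

# logical array view of a binary mask grid
mask_array <- function(grid) {
  if (is.logical(grid$data)) grid$data else grid$data != 0
}

#' Read a NIfTI volume into a `volume_grid`
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  arr <- array(as.vector(img), dim = dim(img))
  volume_grid(arr, spacing = RNifti::pixdim(img)[1:3], affine = aff)
}

#' Write a `volume_grid` to NIfTI
#'
#' @param grid A `volume_grid`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  arr <- grid$data
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
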