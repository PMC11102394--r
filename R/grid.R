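#' Define a voxel grid
#'
#' A voxel grid couples an array shape to a world (MNI mm) coordinate frame
#' through a 4x4 affine. Voxel indices are 0-based in the affine convention
#' (the first voxel maps to the affine's translation column); all world
#' coordinates throughout the package are signed MNI millimetres.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param spacing Voxel size in mm (scalar, isotropic, strictly positive).
#' @param origin World-mm coordinate of voxel (0,0,0).
#' @return An object of class \code{voxel_grid} with fields \code{shape},
#'   \code{spacing}, and \code{affine} (4x4 voxel-index to world-mm).
#' @export
voxel_grid <- function(shape, spacing = 2, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 1L, spacing > 0,
            length(origin) == 3L, all(is.finite(origin)))
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- origin
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %g mm, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$affine[1, 4], x$affine[2, 4], x$affine[3, 4]))
  invisible(x)
}

#' Default analysis grids
#'
#' \code{cerebellar_grid} covers the cerebellar bounding region implied by the
#' geometric mask (x in [-64, 64], y in [-104, -28], z in [-60, 12] mm);
#' \code{whole_brain_grid} covers a standard MNI extent. The default analysis
#' resolution is 2 mm isotropic; coarser grids are useful for fast runs.
#'
#' @param spacing Voxel size in mm.
#' @return A \code{voxel_grid}.
#' @export
cerebellar_grid <- function(spacing = 2) {
  lo <- c(-64, -104, -60)
  hi <- c(64, -28, 12)
  voxel_grid(shape = floor((hi - lo) / spacing) + 1L, spacing = spacing,
             origin = lo)
}

#' @rdname cerebellar_grid
#' @export
whole_brain_grid <- function(spacing = 2) {
  lo <- c(-90, -126, -72)
  hi <- c(90, 90, 108)
  voxel_grid(shape = floor((hi - lo) / spacing) + 1L, spacing = spacing,
             origin = lo)
}

#' Convert between world mm and voxel indices
#'
#' \code{world_to_voxel} maps world-mm coordinates to the nearest 0-based
#' voxel index under the inverse affine; \code{voxel_to_world} is its inverse
#' on indices. The roundtrip world -> voxel -> world lands within half a voxel.
#'
#' @param coords Numeric matrix (n x 3) or length-3 vector of world mm
#'   (or 0-based voxel indices for \code{voxel_to_world}).
#' @param grid A \code{voxel_grid}.
#' @return An n x 3 matrix (integer indices or world mm).
#' @export
world_to_voxel <- function(coords, grid) {
  coords <- coord_matrix(coords)
  inv <- solve(grid$affine)
  idx <- t(inv[1:3, 1:3] %*% t(coords) + inv[1:3, 4])
  idx <- round(idx)
  for (ax in 1:3) {
    bad <- which(idx[, ax] < 0 | idx[, ax] > grid$shape[ax] - 1L)
    if (length(bad)) {
      stop(sprintf(
        "coordinate out of grid on axis %s: value %.1f mm (row %d)",
        c("x", "y", "z")[ax], coords[bad[1], ax], bad[1]))
    }
  }
  storage.mode(idx) <- "integer"
  idx
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(coords, grid) {
  coords <- coord_matrix(coords)
  t(grid$affine[1:3, 1:3] %*% t(coords) + grid$affine[1:3, 4])
}

coord_matrix <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  coords
}

#' Linear (1-based) array index of voxel index triples
#' @noRd
voxel_linear_index <- function(idx, grid) {
  1L + idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3])
}

#' World coordinates of every voxel in a grid
#'
#' @param grid A \code{voxel_grid}.
#' @param mask Optional logical array over the grid; only masked voxels are
#'   returned.
#' @return Matrix (n x 3) of world mm, in array (column-major) order.
#' @export
grid_coordinates <- function(grid, mask = NULL) {
  idx <- as.matrix(expand.grid(x = 0:(grid$shape[1] - 1L),
                               y = 0:(grid$shape[2] - 1L),
                               z = 0:(grid$shape[3] - 1L)))
  if (!is.null(mask)) idx <- idx[as.vector(mask), , drop = FALSE]
  voxel_to_world(idx, grid)
}

#' Construct a volume (scalar field on a grid)
#'
#' @param grid A \code{voxel_grid}.
#' @param values Numeric array matching \code{grid$shape} (default all zero).
#' @param mask Optional logical array of the same shape.
#' @return An object of class \code{volume}.
#' @export
volume <- function(grid, values = NULL, mask = NULL) {
  if (is.null(values)) values <- array(0, dim = grid$shape)
  stopifnot(identical(dim(values), as.integer(grid$shape)))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), as.integer(grid$shape)), is.logical(mask))
    if (any(!is.finite(values[mask])))
      stop("non-finite values on masked voxels")
  }
  structure(list(grid = grid, values = values, mask = mask),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<volume> %d x %d x %d @ %g mm, range [%g, %g]%s\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing, rng[1], rng[2],
              if (is.null(x$mask)) "" else
                sprintf(", %d masked voxels", sum(x$mask))))
  invisible(x)
}

#' Rasterize the geometric cerebellar mask onto a grid
#'
#' @param grid A \code{voxel_grid}.
#' @param spec A \code{mask_spec} (defaults to the shipped geometry).
#' @return Logical array over the grid.
#' @export
grid_mask <- function(grid, spec = mask_spec()) {
  xyz <- grid_coordinates(grid)
  array(in_geometric_mask(xyz, spec), dim = grid$shape)
}

#' Read and write volumes as NIfTI-1
#'
#' Label volumes are written with an integer datatype and must contain small
#' non-negative integers; z-maps and other scalar fields are written float32.
#' The grid's affine is stored as both qform and sform and round-trips exactly.
#'
#' @param vol A \code{volume} (integer labels for \code{write_label_volume}).
#' @param path Output path (.nii or .nii.gz).
#' @return \code{read_volume} returns a \code{volume}; the writers return
#'   \code{path} invisibly.
#' @export
write_label_volume <- function(vol, path) {
  v <- vol$values
  if (any(v < 0)) stop("negative label in label volume")
  if (any(v != round(v))) stop("non-integer label in label volume")
  if (max(v) > 32767) stop("label overflow for int16 datatype")
  write_nifti_impl(vol, path, datatype = "int16", as_int = TRUE)
}

#' @rdname write_label_volume
#' @export
write_volume <- function(vol, path) {
  write_nifti_impl(vol, path, datatype = "float", as_int = FALSE)
}

write_nifti_impl <- function(vol, path, datatype, as_int) {
  v <- vol$values
  if (as_int) storage.mode(v) <- "integer"
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- rep(vol$grid$spacing, 3)
  aff <- structure(vol$grid$affine, code = 2L)
  RNifti::`qform<-`(img, value = aff) -> img
  RNifti::`sform<-`(img, value = aff) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_label_volume
#' @param path Path of an existing NIfTI file.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  spacing <- abs(aff[1, 1])
  grid <- structure(list(shape = as.integer(dim(img)), spacing = spacing,
                         affine = aff),
                    class = "voxel_grid")
  volume(grid, values = array(as.numeric(img), dim = dim(img)))
}
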