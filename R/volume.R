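#' Masked 4D volume time series
#'
#' The unit the pipeline transforms: a 4D array of BOLD-like samples
#' `(x, y, z, t)` together with a voxel-to-mm affine (RAS, MNI-style
#' coordinates), the repetition time, and a 3D logical brain mask.
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param affine 4x4 voxel-index-to-mm matrix (0-based voxel indices).
#' @param tr Repetition time in seconds.
#' @param mask 3D logical array matching the spatial dimensions; defaults to
#'   all-TRUE.
#' @return A `vol4d` object (list with elements `data`, `affine`, `tr`,
#'   `mask`).
#' @export
vol4d <- function(data, affine, tr, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  stopifnot(is.numeric(tr), length(tr) == 1, tr > 0)
  sdim <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sdim)
  stopifnot(is.logical(mask) || is.numeric(mask))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), sdim)) stop("mask shape must equal spatial shape")
  structure(list(data = data, affine = affine, tr = tr, mask = mask),
            class = "vol4d")
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol4d> %d x %d x %d grid, %d volumes, TR %.3g s, %d voxels in mask\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' @export
dim.vol4d <- function(x) dim(x$data)

n_vols <- function(vol) dim(vol$data)[4]

#' Build a diagonal RAS affine
#'
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param origin mm coordinate of voxel index (0, 0, 0).
#' @return 4x4 affine matrix.
#' @export
make_affine <- function(voxel_size = 3, origin = c(0, 0, 0)) {
  voxel_size <- rep_len(voxel_size, 3)
  if (any(voxel_size <= 0)) stop("voxel size must be positive")
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- origin
  a
}

#' Convert voxel indices to mm and back
#'
#' Voxel indices are 0-based (the affine convention); R arrays are indexed
#' from 1, so `vox_to_mm(a, ijk - 1)` maps array index `ijk`.
#'
#' @param affine 4x4 affine.
#' @param vox n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 matrix of coordinates.
#' @export
vox_to_mm <- function(affine, vox) {
  vox <- rbind_coords(vox)
  t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @export
mm_to_vox <- function(affine, mm) {
  mm <- rbind_coords(mm)
  t(solve(affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3)
  x
}

# mm coordinates of every voxel centre, as an n_voxel x 3 matrix in array order
grid_mm_coords <- function(affine, sdim) {
  memo(list("coords", affine, sdim), {
    ijk <- as.matrix(expand.grid(i = seq_len(sdim[1]) - 1,
                                 j = seq_len(sdim[2]) - 1,
                                 k = seq_len(sdim[3]) - 1))
    vox_to_mm(affine, ijk)
  })
}

#' Ellipsoidal brain-like mask
#'
#' An ellipsoid inscribed in the grid (semi-axes `shrink` times the grid
#' half-extents), a coarse stand-in for a brain mask that avoids treating
#' the whole rectangular field of view as brain.
#'
#' @param sdim Spatial grid dimensions (length 3).
#' @param shrink Semi-axis fraction of each half-extent.
#' @return 3D logical array.
#' @export
ellipsoid_mask <- function(sdim, shrink = 0.98) {
  c0 <- (sdim + 1) / 2
  i <- (seq_len(sdim[1]) - c0[1]) / (sdim[1] / 2 * shrink)
  j <- (seq_len(sdim[2]) - c0[2]) / (sdim[2] / 2 * shrink)
  k <- (seq_len(sdim[3]) - c0[3]) / (sdim[3] / 2 * shrink)
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(r2 <= 1, sdim)
}

#' Write / read a `vol4d` as NIfTI-1
#'
#' The affine is stored in the sform/qform and the TR in the temporal pixdim.
#' The mask travels in a companion file `<path>_mask.nii` when written via
#' [write_vol4d()] and is rebuilt from it (or taken as all-TRUE) on read.
#'
#' @param vol A `vol4d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param write_mask Also write the companion mask volume.
#' @return `read_vol4d` returns a `vol4d`.
#' @export
write_vol4d <- function(vol, path, write_mask = TRUE) {
  stopifnot(inherits(vol, "vol4d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(abs(diag(vol$affine)[1:3]), vol$tr)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  if (write_mask) {
    mpath <- mask_path_for(path)
    mimg <- RNifti::asNifti(array(as.integer(vol$mask), dim(vol$mask)))
    mimg <- RNifti::`sform<-`(mimg, structure(vol$affine, code = 2L))
    RNifti::writeNifti(mimg, mpath)
  }
  invisible(path)
}

#' @rdname write_vol4d
#' @export
read_vol4d <- function(path) {
  img <- RNifti::readNifti(path)
  a <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  dat <- array(as.numeric(img), dim(img))
  mpath <- mask_path_for(path)
  mask <- if (file.exists(mpath)) {
    m <- RNifti::readNifti(mpath)
    array(as.numeric(m) != 0, dim(m))
  } else NULL
  vol4d(dat, a, tr, mask)
}

mask_path_for <- function(path) {
  sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
}
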