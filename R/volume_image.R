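#' Construct a 3D volume image
#'
#' The universal image carrier of the pipeline: a 3D scalar grid together
#' with a 4x4 voxel-to-world affine (mm, RAS convention) and per-axis voxel
#' sizes. Voxel indices are 0-based in all user-facing coordinates.
#'
#' @param data numeric 3D array.
#' @param voxel_mm numeric length-3 vector of voxel sizes in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal affine
#'   built from `voxel_mm` with the origin at voxel (0,0,0).
#' @param space character label of the coordinate space (e.g. "flair", "t1").
#' @return An object of class `volume_image` with fields `data`, `affine`,
#'   `voxel_mm`, `space`.
#' @export
volume_image <- function(data, voxel_mm = c(1, 1, 1), affine = NULL,
                         space = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) == 0L)) stop("`data` must be non-empty", call. = FALSE)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be three positive numbers", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(affine[4, ] != c(0, 0, 0, 1)))
    stop("`affine` must be 4x4 homogeneous with last row (0,0,0,1)",
         call. = FALSE)
  structure(
    list(data = data, affine = affine, voxel_mm = voxel_mm,
         space = as.character(space)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %dx%dx%d voxels, %.2fx%.2fx%.2f mm, space '%s'\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              x$space))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Construct a 4D dynamic (time-series) image
#'
#' Carrier for dynamic susceptibility contrast (DSC) acquisitions: a 4D grid
#' (x, y, z, t) plus repetition time and echo time in seconds.
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param tr_s repetition time between volumes, seconds (> 0).
#' @param te_s echo time, seconds (> 0).
#' @inheritParams volume_image
#' @return An object of class `time_series_image`.
#' @export
time_series_image <- function(data, tr_s, te_s, voxel_mm = c(1, 1, 1),
                              affine = NULL, space = "dsc") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (!is.finite(tr_s) || tr_s <= 0) stop("`tr_s` must be > 0", call. = FALSE)
  if (!is.finite(te_s) || te_s <= 0) stop("`te_s` must be > 0", call. = FALSE)
  vol0 <- volume_image(array(0, dim(data)[1:3]), voxel_mm, affine, space)
  structure(
    list(data = data, tr_s = tr_s, te_s = te_s, affine = vol0$affine,
         voxel_mm = vol0$voxel_mm, space = vol0$space),
    class = "time_series_image"
  )
}

#' @export
print.time_series_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<time_series_image> %dx%dx%d voxels x %d timepoints, TR=%gs TE=%gs\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$te_s))
  invisible(x)
}

#' Extract one volume of a time series as a volume_image
#' @param x a `time_series_image`.
#' @param t 0-based volume index.
#' @return `volume_image` at timepoint `t`.
#' @export
ts_volume <- function(x, t) {
  stopifnot(inherits(x, "time_series_image"))
  nt <- dim(x$data)[4]
  if (t < 0 || t >= nt) stop("volume index out of range", call. = FALSE)
  volume_image(x$data[, , , t + 1, drop = FALSE][, , , 1],
               x$voxel_mm, x$affine, x$space)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data)[1:3] == dim(b$data)[1:3]) &&
    max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "images") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid/affine", what), call. = FALSE)
  invisible(TRUE)
}

#' Write a volume image to a NIfTI file
#'
#' The affine is stored in the sform; voxel sizes go to pixdim. The space
#' label is not stored in the file (NIfTI has no such field) and must be
#' supplied again on read.
#'
#' @param img a `volume_image` or `time_series_image`.
#' @param path output path (.nii or .nii.gz).
#' @param datatype passed to [RNifti::writeNifti()]; default "float".
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path, datatype = "float") {
  nim <- RNifti::asNifti(img$data)
  RNifti::pixdim(nim) <- img$voxel_mm
  RNifti::sform(nim) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nim, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI file as a volume_image or time_series_image
#'
#' @param path NIfTI file path.
#' @param space space label to attach.
#' @param tr_s,te_s timing metadata (seconds), required to interpret a 4D
#'   file as a DSC time series; ignored for 3D files.
#' @return `volume_image` (3D) or `time_series_image` (4D).
#' @export
read_volume <- function(path, space = "unknown", tr_s = NULL, te_s = NULL) {
  nim <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(nim, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- as.array(nim)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))  # column norms handle rotated affines
  if (length(dim(arr)) == 4L) {
    if (is.null(tr_s) || is.null(te_s))
      stop("4D file: supply tr_s and te_s", call. = FALSE)
    time_series_image(arr, tr_s, te_s, vox, aff, space)
  } else {
    volume_image(arr, vox, aff, space)
  }
}

#' Voxel volume in cubic millimetres
#' @param img a `volume_image`.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(img) prod(img$voxel_mm)
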