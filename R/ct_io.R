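# CT volume and mask containers and NIfTI I/O.
#
# HU are stored as doubles, clipped at -1024 on construction/load; no upper
# clip is applied (upper bounds are analysis parameters, not data
# properties).

#' Construct a CT volume in Hounsfield units
#'
#' @param voxels 3-D numeric array of attenuation values (HU). Values below
#'   -1024 are clipped to -1024.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @param axis_order orientation label for the three array axes; the third
#'   axis is the slice (z) axis, increasing towards the head (superior).
#' @return object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `origin`, `axis_order`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      axis_order = "LPS") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("`voxels` must be a 3-D array, got %s dimensions",
          length(dim(voxels)))
  if (any(dim(voxels) < 1L)) stopf("all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stopf("`origin` must have length 3")
  v <- voxels
  storage.mode(v) <- "double"
  v[v < -1024] <- -1024
  structure(list(voxels = v, spacing = spacing, origin = origin,
                 axis_order = axis_order),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %s mm, HU [%0.0f, %0.0f]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Volume of one voxel in millilitres
#' @param volume a [ct_volume].
#' @return scalar, mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(volume) {
  prod(volume$spacing) / 1000
}

#' Construct a segmentation mask congruent with a CT volume
#'
#' @param flags logical 3-D array (or 0/1 array), same shape as the parent
#'   volume grid.
#' @param volume optional parent [ct_volume] used to check congruence.
#' @return object of class `seg_mask` with fields `flags` and `voxel_count`.
#' @export
seg_mask <- function(flags, volume = NULL) {
  if (!is.array(flags) || length(dim(flags)) != 3L)
    stopf("`flags` must be a 3-D array")
  flags <- array(as.logical(flags), dim(flags))
  if (anyNA(flags)) stopf("mask flags must be TRUE/FALSE with no NA")
  if (!is.null(volume) && !identical(dim(flags), dim(volume$voxels)))
    stopf("mask shape (%s) does not match volume shape (%s)",
          paste(dim(flags), collapse = "x"),
          paste(dim(volume$voxels), collapse = "x"))
  structure(list(flags = flags, voxel_count = sum(flags)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("seg_mask: %s grid, %d voxels set\n",
              paste(dim(x$flags), collapse = " x "), x$voxel_count))
  invisible(x)
}

nifti_affine <- function(spacing, origin) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(spacing)
  m[1:3, 4] <- origin
  m
}

#' Read a CT volume from NIfTI
#'
#' Values are taken as already HU-calibrated (apply [hu_calibrate()] first
#' for raw stored values); anything below -1024 HU is clipped on load.
#' Spacing and origin are read from the NIfTI geometry.
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3-D scalar image.
#' @param format input format; only `"nifti"` is supported.
#' @return a [ct_volume].
#' @export
load_volume <- function(path, format = c("nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("volume file does not exist: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- dim(img)
  }
  if (length(d) != 3L)
    stopf("expected a 3-D scalar NIfTI, got %d dimensions", length(d))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("missing geometry metadata: non-positive pixdim (spacing) in %s", path)
  aff <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(aff, "try-error")) c(0, 0, 0) else as.numeric(aff[1:3, 4])
  ct_volume(array(as.numeric(img), d), spacing = sp, origin = orig)
}

#' Write a CT volume to NIfTI
#'
#' @param volume a [ct_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  aff <- structure(nifti_affine(volume$spacing, volume$origin), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a segmentation mask to NIfTI (uint8, 0/1)
#'
#' @param mask a [seg_mask].
#' @param geometry the parent [ct_volume] supplying spacing/origin.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, geometry, path) {
  if (!identical(dim(mask$flags), dim(geometry$voxels)))
    stopf("mask shape (%s) does not match volume shape (%s)",
          paste(dim(mask$flags), collapse = "x"),
          paste(dim(geometry$voxels), collapse = "x"))
  arr <- array(as.integer(mask$flags), dim(mask$flags))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry$spacing
  aff <- structure(nifti_affine(geometry$spacing, geometry$origin), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a 0/1 mask from NIfTI
#'
#' @param path mask file path.
#' @param volume optional [ct_volume] to check congruence against.
#' @return a [seg_mask].
#' @export
load_mask <- function(path, volume = NULL) {
  if (!file.exists(path)) stopf("mask file does not exist: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  arr <- array(as.numeric(img), d)
  if (!all(arr %in% c(0, 1)))
    stopf("mask file %s contains values other than 0/1", path)
  seg_mask(arr != 0, volume = volume)
}
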