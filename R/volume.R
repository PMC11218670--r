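#' Image volume
#'
#' A z-stack of square axial slices with voxel spacing and the intensity
#' window that maps Hounsfield units to the normalized \[0, 1\] range used by
#' every reconstruction routine.  The array layout is
#' `(rows, cols, slices)`; rows index the in-plane y axis, columns x.
#'
#' @param voxels numeric array `(n, n, n_slices)` (a matrix is promoted to a
#'   single slice); all values finite.
#' @param voxel_size voxel edge lengths in mm, length 1 (isotropic in-plane,
#'   reused for z) or 3 `(dx, dy, dz)`.
#' @param hu_window length-2 HU window mapped linearly to \[0, 1\];
#'   default `c(-1000, 1000)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, voxel_size = 4.13, hu_window = c(-1000, 1000)) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be a (rows, cols, slices) array")
  }
  if (dim(voxels)[1] != dim(voxels)[2]) stop("axial slices must be square")
  if (dim(voxels)[3] < 1L) stop("at least one slice required")
  if (!all(is.finite(voxels))) stop("voxel values must all be finite")
  if (length(voxel_size) == 1L) voxel_size <- rep(as.numeric(voxel_size), 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 1 or 3 positive lengths (mm)")
  }
  if (length(hu_window) != 2L || diff(hu_window) <= 0) {
    stop("hu_window must be an increasing length-2 window")
  }
  structure(
    list(voxels = voxels, voxel_size = voxel_size, hu_window = as.numeric(hu_window)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_volume> %d x %d x %d | voxel %g x %g x %g mm | HU window [%g, %g] | range [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$hu_window[1], x$hu_window[2], min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' HU windowing
#'
#' `normalize_hu()` clips a HU-valued array to the window and maps it linearly
#' to \[0, 1\]; `denormalize_hu()` inverts the map (exact for in-window
#' values).
#'
#' @param x numeric array of HU values (or normalized values for
#'   `denormalize_hu`).
#' @param hu_window length-2 increasing window.
#' @return Array of the same shape.
#' @export
normalize_hu <- function(x, hu_window = c(-1000, 1000)) {
  lo <- hu_window[1]; hi <- hu_window[2]
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(x, hu_window = c(-1000, 1000)) {
  hu_window[1] + x * diff(hu_window)
}

#' Read / write image volumes
#'
#' Volumes are written as NIfTI (`.nii` / `.nii.gz`) through RNifti or as
#' 32-bit float multi-page TIFF (`.tif` / `.tiff`); the format is chosen by
#' extension.  TIFF carries no spacing metadata, so `voxel_size` and
#' `hu_window` must be re-supplied on read.
#'
#' @param volume an [image_volume()].
#' @param path output file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `image_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$voxel_size
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    sl <- lapply(seq_len(dim(volume$voxels)[3]), function(k) volume$voxels[, , k])
    tiff::writeTIFF(sl, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    stop("unsupported volume format: ", ext)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param voxel_size,hu_window metadata for TIFF input (ignored for NIfTI
#'   spacing, which is read from the header).
#' @export
read_volume <- function(path, voxel_size = 4.13, hu_window = c(-1000, 1000)) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    vox <- array(as.numeric(img), dim = dim(img))
    if (length(dim(vox)) == 2L) vox <- array(vox, dim = c(dim(vox), 1L))
    pd <- RNifti::pixdim(img)
    if (length(pd) >= 3 && all(pd[1:3] > 0)) voxel_size <- pd[1:3]
    image_volume(vox, voxel_size = voxel_size, hu_window = hu_window)
  } else if (ext %in% c("tif", "tiff")) {
    sl <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (is.matrix(sl)) sl <- list(sl)
    vox <- array(0, dim = c(dim(sl[[1]]), length(sl)))
    for (k in seq_along(sl)) vox[, , k] <- sl[[k]]
    image_volume(vox, voxel_size = voxel_size, hu_window = hu_window)
  } else {
    stop("unsupported volume format: ", ext)
  }
}
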