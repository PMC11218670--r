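#' Sinogram container
#'
#' Projection measurements on an `(angles, detector, slices)` grid, together
#' with the geometry that produced them.  Values are line integrals in
#' (normalized intensity x mm) unless a noise model converted them through the
#' photon-count domain, which preserves the scale.
#'
#' @param values numeric array `(n_angles, detector_pixels, n_slices)`; a
#'   matrix is promoted to one slice.
#' @param geometry the [scan_geometry()] the measurements correspond to.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be an (angles, detector, slices) array")
  }
  if (dim(values)[1] != length(geometry$angles)) {
    stop("angle dimension must equal the geometry's angle count")
  }
  if (dim(values)[2] != geometry$detector_pixels) {
    stop("detector dimension must equal the geometry's detector_pixels")
  }
  if (!all(is.finite(values))) stop("sinogram values must all be finite")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sinogram> %d views x %d det x %d slices | range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Forward projection (the measurement operator A)
#'
#' Exact ray-grid intersection-length line integrals (Siddon traversal)
#' applied slice by slice.  The operator is linear in the volume; rays that
#' miss the grid contribute zero.  In fan mode each view's source sits at
#' SAD on the view direction and the detector line is centred on the opposite
#' side at SDD; in parallel mode rays are orthographic with the detector
#' pitch taken at the isocenter.
#'
#' @param volume an [image_volume()].
#' @param geometry a [scan_geometry()].
#' @return A [sinogram()], `y = A x`.
#' @export
forward_project <- function(volume, geometry) {
  stopifnot(inherits(volume, "image_volume"), inherits(geometry, "scan_geometry"))
  if (!all(is.finite(volume$voxels))) stop("non-finite voxel values")
  d <- dim(volume$voxels)
  fan <- geometry$beam_mode == "fan_per_slice"
  out <- array(0, dim = c(length(geometry$angles), geometry$detector_pixels, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- cpp_forward_project(
      volume$voxels[, , k], geometry$angles, geometry$detector_pixels,
      geometry$detector_pitch, volume$voxel_size[1],
      geometry$source_to_isocenter, geometry$source_to_detector, fan
    )
  }
  sinogram(out, geometry)
}

#' Back projection (the adjoint operator A^T)
#'
#' Transposes [forward_project()] with identical intersection-length weights,
#' so that `<A x, y> == <x, A^T y>` to floating precision for every geometry.
#'
#' @param sino a [sinogram()].
#' @param geometry the matching [scan_geometry()].
#' @param n image grid size (pixels per side).
#' @param voxel_size voxel edge length (mm), matching the forward projection.
#' @param hu_window carried through to the returned volume.
#' @return An [image_volume()], `A^T y` (values are unnormalized adjoint
#'   weights, not intensities).
#' @export
back_project <- function(sino, geometry, n, voxel_size = 4.13,
                         hu_window = c(-1000, 1000)) {
  stopifnot(inherits(sino, "sinogram"), inherits(geometry, "scan_geometry"))
  if (!identical(sino$geometry$angles, geometry$angles) ||
      sino$geometry$detector_pixels != geometry$detector_pixels) {
    stop("sinogram does not match geometry")
  }
  fan <- geometry$beam_mode == "fan_per_slice"
  ns <- dim(sino$values)[3]
  vox <- array(0, dim = c(n, n, ns))
  for (k in seq_len(ns)) {
    vox[, , k] <- cpp_back_project(
      slice_mat(sino$values, k), geometry$angles, as.integer(n),
      geometry$detector_pitch, voxel_size[1],
      geometry$source_to_isocenter, geometry$source_to_detector, fan
    )
  }
  # adjoint output is not intensity-bounded; bypass [0,1] conventions on purpose
  v <- image_volume(array(0, dim = dim(vox)), voxel_size = voxel_size, hu_window = hu_window)
  v$voxels <- vox
  v
}

#' Photon-count projection noise
#'
#' Converts line integrals to expected photon counts
#' `I = I0 * exp(-mu * y)`, draws Poisson counts plus zero-mean Gaussian
#' electronic noise, clamps counts at 1, and converts back with
#' `y' = log(I0 / count) / mu`.  Deterministic given `seed`.
#'
#' @param sino a [sinogram()] of noiseless line integrals.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return A [sinogram()] with noisy values (identical to the input when the
#'   model is disabled).
#' @export
add_projection_noise <- function(sino, noise, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"), inherits(noise, "noise_model"))
  if (!noise$enabled) return(sino)
  counts <- simulate_photon_counts(sino$values, noise, seed)
  mu <- noise$attenuation_per_unit
  vals <- log(noise$photons_per_pixel / counts) / mu
  sinogram(array(vals, dim = dim(sino$values)), sino$geometry)
}

#' Convert a sinogram between measurement domains
#'
#' Simulated projections can be kept as attenuation line integrals (the
#' operator's native output, and the default throughout) or as
#' log-converted intensities `mu^-1 log(I0 / I)` re-expressed from the
#' photon-count domain; with a shared noise model the two are related by
#' `I = I0 exp(-mu y)`.  This helper converts the stored values to the
#' requested domain (noiseless conversion; use [add_projection_noise()] for
#' the stochastic channel).
#'
#' @param sino a [sinogram()].
#' @param domain target domain, `"attenuation"` or `"intensity"`.
#' @param noise a [noise_model()] supplying `photons_per_pixel` and
#'   `attenuation_per_unit`.
#' @return A [sinogram()] with converted values and a `"domain"` attribute.
#' @export
convert_sinogram_domain <- function(sino, domain = c("attenuation", "intensity"),
                                    noise = noise_model()) {
  domain <- match.arg(domain)
  cur <- attr(sino, "domain") %||% "attenuation"
  if (cur == domain) return(sino)
  I0 <- noise$photons_per_pixel
  mu <- noise$attenuation_per_unit
  vals <- if (domain == "intensity") {
    I0 * exp(-mu * sino$values)
  } else {
    log(I0 / pmax(sino$values, 1e-12)) / mu
  }
  out <- sinogram(array(vals, dim = dim(sino$values)), sino$geometry)
  attr(out, "domain") <- domain
  out
}

#' Raw photon counts for a set of line integrals
#'
#' The count-domain half of [add_projection_noise()], exposed so the Poisson +
#' Gaussian moments can be checked directly.
#'
#' @param y numeric array of line integrals.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return Array of photon counts (clamped at 1), same shape as `y`.
#' @export
simulate_photon_counts <- function(y, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$photons_per_pixel <= 0) stop("photons_per_pixel must be positive")
  I0 <- noise$photons_per_pixel
  mu <- noise$attenuation_per_unit
  expected <- I0 * exp(-mu * y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  counts <- rpois(length(expected), lambda = as.numeric(expected))
  if (noise$electronic_variance > 0) {
    counts <- counts + rnorm(length(counts), sd = sqrt(noise$electronic_variance))
  }
  counts <- pmax(counts, 1)
  array(counts, dim = if (is.null(dim(y))) length(y) else dim(y))
}

# slice k of a 3D array as a matrix, robust to dropped dimensions
slice_mat <- function(arr, k) {
  m <- arr[, , k]
  dim(m) <- dim(arr)[1:2]
  m
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Dense system matrix (small grids)
#'
#' Assembles `A` column by column by forward-projecting unit basis images.
#' Intended for oracle comparisons on grids up to ~16 x 16; memory grows as
#' `(views * detectors) x n^2`.
#'
#' @param geometry a [scan_geometry()].
#' @param n grid size.
#' @param voxel_size voxel edge (mm).
#' @return A dense matrix with `length(angles) * detector_pixels` rows (angle
#'   index fastest) and `n^2` columns (R column-major pixel order).
#' @export
dense_system_matrix <- function(geometry, n, voxel_size = 4.13) {
  ncol <- n * n
  A <- matrix(0, nrow = length(geometry$angles) * geometry$detector_pixels, ncol = ncol)
  base <- array(0, dim = c(n, n, 1L))
  for (j in seq_len(ncol)) {
    e <- base
    e[[j]] <- 1
    v <- image_volume(e, voxel_size = voxel_size)
    A[, j] <- as.numeric(forward_project(v, geometry)$values[, , 1])
  }
  A
}

#' Read / write sinograms
#'
#' Stored as a 32-bit float multi-page TIFF (one page per slice) next to a
#' YAML sidecar (`<path>.yaml`) holding the geometry, the value scale used to
#' fit the TIFF's \[0, 1\] payload range, and the array dimensions.
#'
#' @param sino a [sinogram()].
#' @param path TIFF path.
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram` a
#'   [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  lo <- min(sino$values); hi <- max(sino$values)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(sino$values)[3]),
                  function(k) (sino$values[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(
    list(offset = lo, scale = scale, dim = dim(sino$values),
         geometry = unclass(sino$geometry)),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  g <- meta$geometry
  geometry <- scan_geometry(
    angles = unlist(g$angles), detector_pixels = g$detector_pixels,
    detector_pitch = g$detector_pitch,
    source_to_isocenter = g$source_to_isocenter,
    source_to_detector = g$source_to_detector, beam_mode = g$beam_mode
  )
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  vals <- array(0, dim = unlist(meta$dim))
  for (k in seq_along(pages)) vals[, , k] <- pages[[k]] * meta$scale + meta$offset
  sinogram(vals, geometry)
}
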