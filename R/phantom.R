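#' Phantom specification
#'
#' Describes a paired "prior CT" / "current CBCT" phantom: an ellipsoid
#' composite (Shepp-Logan-like) shared background, plus a set of small
#' lesion ellipsoids of which a configurable fraction differs between the
#' two volumes (inserted into or removed from the current volume), emulating
#' day-to-day anatomical change between a planning CT and a treatment-day
#' CBCT.  Closed-form ellipsoid rasterization keeps voxel counts exact for
#' testing.  Overlapping structures are painted in list order, so the
#' last-listed structure wins.
#'
#' @param n grid size (pixels per side).
#' @param n_slices axial slices.
#' @param n_structures random internal background ellipsoids (besides the
#'   body outline).
#' @param n_lesions small lesion ellipsoids.
#' @param mismatch_magnitude fraction of the lesions that differ between
#'   prior and current (0 = identical pair).
#' @param intensity_range normalized intensity range for internal structures.
#' @param texture_amplitude amplitude of the smooth intra-tissue intensity
#'   field shared by prior and current (0 disables); together with the
#'   per-structure intensity gradients this keeps the phantoms from being
#'   exactly piecewise constant, which real CT anatomy is not.
#' @param texture_scale correlation length of the texture field (pixels).
#' @param voxel_size voxel edge (mm).
#' @param hu_window HU window metadata of the produced volumes.
#' @param structures,lesions optional explicit structure lists (each element
#'   `list(center, axes, angle, value)` with an optional in-plane intensity
#'   `gradient`, in normalized \[-1, 1\] coordinates); when `NULL` they are
#'   drawn from `seed`.
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n = 64L, n_slices = 3L, n_structures = 14L,
                         n_lesions = 2L, mismatch_magnitude = 0.5,
                         intensity_range = c(0.15, 0.95),
                         texture_amplitude = 0.06, texture_scale = 1.5,
                         voxel_size = 4.13, hu_window = c(-1000, 1000),
                         structures = NULL, lesions = NULL, seed = 1L) {
  if (mismatch_magnitude < 0 || mismatch_magnitude > 1) {
    stop("mismatch_magnitude must lie in [0, 1]")
  }
  structure(
    list(n = as.integer(n), n_slices = as.integer(n_slices),
         n_structures = as.integer(n_structures), n_lesions = as.integer(n_lesions),
         mismatch_magnitude = mismatch_magnitude,
         intensity_range = as.numeric(intensity_range),
         texture_amplitude = texture_amplitude, texture_scale = texture_scale,
         voxel_size = voxel_size, hu_window = as.numeric(hu_window),
         structures = structures, lesions = lesions, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# slice z positions in normalized coordinates; kept close so neighbouring
# slices share most anatomy (what the z-TV term exploits)
slice_positions <- function(n_slices) {
  if (n_slices == 1L) 0 else seq(-0.3, 0.3, length.out = n_slices)
}

# paint one ellipsoid's cross-section onto a slice (last-listed precedence)
paint_ellipsoid <- function(img, st, zpos, n) {
  dz <- (zpos - st$center[3]) / st$axes[3]
  if (abs(dz) >= 1) return(img)
  f <- sqrt(1 - dz^2)
  a <- st$axes[1] * f; b <- st$axes[2] * f
  th <- st$angle * pi / 180
  co <- cos(th); si <- sin(th)
  xs <- (seq_len(n) - (n + 1) / 2) / (n / 2)   # pixel centres in [-1, 1]
  X <- matrix(xs, nrow = n, ncol = n, byrow = TRUE)  # columns = x
  Y <- matrix(xs, nrow = n, ncol = n)                # rows = y
  xr <- (X - st$center[1]) * co + (Y - st$center[2]) * si
  yr <- -(X - st$center[1]) * si + (Y - st$center[2]) * co
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  grad <- st$gradient
  if (is.null(grad) || all(grad == 0)) {
    img[inside] <- st$value
  } else {
    vals <- st$value + grad[1] * (X - st$center[1]) + grad[2] * (Y - st$center[2])
    img[inside] <- vals[inside]
  }
  img
}

# anatomy-like mix: organ-scale ellipsoids with intensity gradients, thin
# elongated high-contrast structures (vessel/septum-like) and small bright
# spots (bone-like); edge-dense content is what separates a learned prior
# from plain TV under a missing angular wedge
random_structures <- function(spec) {
  body <- list(center = c(0, 0, 0), axes = c(0.88, 0.78, 3), angle = 0,
               value = runif(1, 0.25, 0.45), gradient = runif(2, -0.05, 0.05))
  inner <- lapply(seq_len(spec$n_structures), function(j) {
    kind <- sample(c("organ", "vessel", "spot"), 1, prob = c(0.5, 0.25, 0.25))
    switch(kind,
      organ = list(center = c(runif(2, -0.45, 0.45), runif(1, -0.2, 0.2)),
                   axes = c(runif(1, 0.12, 0.4), runif(1, 0.12, 0.4),
                            runif(1, 0.5, 1.5)),
                   angle = runif(1, 0, 180),
                   value = runif(1, spec$intensity_range[1], spec$intensity_range[2]),
                   gradient = runif(2, -0.3, 0.3)),
      vessel = list(center = c(runif(2, -0.5, 0.5), runif(1, -0.2, 0.2)),
                    axes = c(runif(1, 0.2, 0.55), runif(1, 0.025, 0.06),
                             runif(1, 0.5, 1.5)),
                    angle = runif(1, 0, 180),
                    value = runif(1, 0.65, 1.0),
                    gradient = c(0, 0)),
      spot = list(center = c(runif(2, -0.55, 0.55), runif(1, -0.2, 0.2)),
                  axes = c(runif(1, 0.03, 0.08), runif(1, 0.03, 0.08),
                           runif(1, 0.3, 1.0)),
                  angle = runif(1, 0, 180),
                  value = runif(1, 0.75, 1.0),
                  gradient = c(0, 0))
    )
  })
  c(list(body), inner)
}

# smooth in-plane intensity field shared by prior and current: white noise
# blurred to the requested correlation length, scaled to unit max amplitude
texture_field <- function(n, scale) {
  z <- matrix(rnorm(n * n), n, n)
  size <- 2L * ceiling(2 * scale) + 1L
  g <- gaussian_kernel(size, scale)
  f <- cpp_conv2_same(z, g, 1L)
  f / max(abs(f))
}

random_lesions <- function(spec) {
  lapply(seq_len(spec$n_lesions), function(j) {
    list(center = c(runif(2, -0.4, 0.4), runif(1, -0.15, 0.15)),
         axes = c(runif(1, 0.08, 0.18), runif(1, 0.08, 0.18), runif(1, 0.3, 0.8)),
         angle = runif(1, 0, 180),
         value = runif(1, spec$intensity_range[1], spec$intensity_range[2]))
  })
}

#' Generate a paired prior/current phantom
#'
#' Deterministic given the spec's seed.  The returned mask marks exactly the
#' voxels where the two volumes differ; outside the mask they are
#' bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return `list(prior, current, mask)` with two [image_volume()]s and a
#'   logical array.
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  structures <- if (is.null(spec$structures)) random_structures(spec) else spec$structures
  lesions <- if (is.null(spec$lesions)) random_lesions(spec) else spec$lesions
  n_diff <- round(spec$mismatch_magnitude * length(lesions))
  differing <- if (length(lesions)) seq_along(lesions) <= n_diff else integer(0)
  # differing lesions are either inserted into or removed from `current`
  insert <- if (length(lesions)) runif(length(lesions)) < 0.5 else logical(0)
  tex <- if (spec$texture_amplitude > 0) {
    spec$texture_amplitude * texture_field(spec$n, spec$texture_scale)
  } else NULL

  zs <- slice_positions(spec$n_slices)
  n <- spec$n
  prior <- array(0, dim = c(n, n, spec$n_slices))
  current <- array(0, dim = c(n, n, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    base <- matrix(0, n, n)
    for (st in structures) base <- paint_ellipsoid(base, st, zs[k], n)
    p <- base; cu <- base
    for (j in seq_along(lesions)) {
      if (!differing[j]) {
        p <- paint_ellipsoid(p, lesions[[j]], zs[k], n)
        cu <- paint_ellipsoid(cu, lesions[[j]], zs[k], n)
      } else if (insert[j]) {
        cu <- paint_ellipsoid(cu, lesions[[j]], zs[k], n)
      } else {
        p <- paint_ellipsoid(p, lesions[[j]], zs[k], n)
      }
    }
    if (!is.null(tex)) {
      p <- p + tex * (p > 0)
      cu <- cu + tex * (cu > 0)
    }
    prior[, , k] <- pmin(pmax(p, 0), 1)
    current[, , k] <- pmin(pmax(cu, 0), 1)
  }
  list(
    prior = image_volume(prior, voxel_size = spec$voxel_size, hu_window = spec$hu_window),
    current = image_volume(current, voxel_size = spec$voxel_size, hu_window = spec$hu_window),
    mask = prior != current
  )
}

#' Build a training corpus of slices and their own Sobel edges
#'
#' Draws a randomized phantom population and pairs every axial slice with
#' the Sobel magnitude of that same slice - training conditions are
#' self-edges of the current-domain images; prior-CT edges enter only at
#' reconstruction time.
#'
#' @param n_volumes number of phantoms.
#' @param spec_template a [phantom_spec()] whose seed is re-derived per
#'   volume.
#' @param seed integer corpus seed.
#' @return An object of class `training_corpus` with an `items` list of
#'   `list(slice, magnitude)`.
#' @export
build_training_corpus <- function(n_volumes, spec_template = phantom_spec(),
                                  seed = 1L) {
  if (n_volumes < 1L) stop("n_volumes must be >= 1")
  items <- list()
  for (v in seq_len(n_volumes)) {
    sp <- spec_template
    sp$seed <- as.integer(seed * 10000L + v)
    pair <- generate_phantom_pair(sp)
    for (k in seq_len(dim(pair$current$voxels)[3])) {
      sl <- pair$current$voxels[, , k]
      items[[length(items) + 1L]] <- list(slice = sl,
                                          magnitude = sobel_magnitude(sl))
    }
  }
  structure(list(items = items, n_volumes = n_volumes, seed = seed,
                 spec = spec_template),
            class = "training_corpus")
}

#' @export
print.training_corpus <- function(x, ...) {
  d <- dim(x$items[[1]]$slice)
  cat(sprintf("<training_corpus> %d slices of %d x %d from %d phantoms\n",
              length(x$items), d[1], d[2], x$n_volumes))
  invisible(x)
}

#' Rigid in-plane misalignment of a volume
#'
#' Translates every slice by `magnitude` mm along one randomly chosen
#' in-plane axis (anterior-posterior or lateral), with linear interpolation
#' and nearest-edge padding; used to study the effect of imperfect
#' prior-to-target registration.
#'
#' @param volume an [image_volume()].
#' @param magnitude shift in mm (>= 0; must not exceed half the field of
#'   view).
#' @param axis_choice_seed seed for the random axis choice.
#' @return The shifted [image_volume()].
#' @export
misalign <- function(volume, magnitude, axis_choice_seed = 1L) {
  stopifnot(inherits(volume, "image_volume"))
  if (magnitude < 0) stop("magnitude must be non-negative")
  n <- dim(volume$voxels)[1]
  fov <- n * volume$voxel_size[1]
  if (magnitude > fov / 2) stop("shift exceeds half the field of view")
  if (magnitude == 0) return(volume)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(axis_choice_seed))
  axis <- sample(c("x", "y"), 1L)
  s <- magnitude / volume$voxel_size[1]
  out <- volume
  for (k in seq_len(dim(volume$voxels)[3])) {
    out$voxels[, , k] <- shift_slice(volume$voxels[, , k], s, axis)
  }
  out
}

# linear-interpolated shift by s voxels along "x" (columns) or "y" (rows),
# nearest-edge padding; an integer s reduces to an exact index roll
shift_slice <- function(m, s, axis) {
  n1 <- nrow(m); n2 <- ncol(m)
  s0 <- floor(s); f <- s - s0
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  if (axis == "x") {
    c0 <- idx(seq_len(n2) - s0, n2)
    c1 <- idx(seq_len(n2) - s0 - 1L, n2)
    (1 - f) * m[, c0, drop = FALSE] + f * m[, c1, drop = FALSE]
  } else {
    r0 <- idx(seq_len(n1) - s0, n1)
    r1 <- idx(seq_len(n1) - s0 - 1L, n1)
    (1 - f) * m[r0, , drop = FALSE] + f * m[r1, , drop = FALSE]
  }
}
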