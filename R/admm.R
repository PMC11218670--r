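#' ADMM configuration
#'
#' Parameters of the ADMM solver for the TV-regularized objective
#' `data_weight/2 * ||y - A x||^2 + tv_weight * ||D x||_1`, where `D` stacks
#' forward finite differences along the chosen axes (zero values assumed
#' beyond the boundary, which keeps `D^T D` banded and the adjoint exact).
#'
#' @param tv_weight TV regularization weight (>= 0).
#' @param penalty ADMM penalty parameter rho (> 0).
#' @param outer_iters number of outer ADMM iterations.
#' @param cg_iters conjugate-gradient iterations for each quadratic x-update.
#' @param tv_axes subset of `c("x", "y", "z")`; `"z"` alone gives the
#'   slice-coupling-only prior used inside the diffusion loop.
#' @param tolerance relative primal-residual stopping tolerance.
#' @param data_weight weight on the data-fidelity term; a large value turns
#'   the relaxed update into a near-hard projection onto data consistency.
#' @return An object of class `admm_config`.
#' @export
admm_config <- function(tv_weight = 1.0, penalty = 1.0, outer_iters = 50L,
                        cg_iters = 10L, tv_axes = c("x", "y", "z"),
                        tolerance = 1e-4, data_weight = 1.0) {
  tv_axes <- match.arg(tv_axes, c("x", "y", "z"), several.ok = TRUE)
  if (tv_weight < 0 || penalty < 0 || tolerance < 0 || data_weight < 0) {
    stop("all scalars must be non-negative")
  }
  if (outer_iters < 1L) stop("outer_iters must be >= 1")
  if (length(tv_axes) < 1L) stop("tv_axes must be non-empty")
  structure(
    list(tv_weight = tv_weight, penalty = penalty,
         outer_iters = as.integer(outer_iters), cg_iters = as.integer(cg_iters),
         tv_axes = tv_axes, tolerance = tolerance, data_weight = data_weight),
    class = "admm_config"
  )
}

#' Elementwise soft thresholding
#'
#' The proximal map of the scaled L1 norm: `sign(v) * max(|v| - threshold, 0)`.
#'
#' @param v numeric vector/array.
#' @param threshold non-negative scalar.
#' @return Same shape as `v`.
#' @export
soft_threshold <- function(v, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  sign(v) * pmax(abs(v) - threshold, 0)
}

# forward difference along an axis of a 3D array, zero beyond the boundary:
# (D x)_i = x_{i+1} - x_i, with x_{n+1} = 0
finite_diff <- function(x, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(x)
  out <- array(0, dim = d)
  switch(axis,
    y = { out[-d[1], , ] <- x[-1, , , drop = FALSE] - x[-d[1], , , drop = FALSE]
          out[d[1], , ] <- -x[d[1], , ] },
    x = { out[, -d[2], ] <- x[, -1, , drop = FALSE] - x[, -d[2], , drop = FALSE]
          out[, d[2], ] <- -x[, d[2], ] },
    z = { if (d[3] > 1L) {
            out[, , -d[3]] <- x[, , -1, drop = FALSE] - x[, , -d[3], drop = FALSE]
          }
          out[, , d[3]] <- out[, , d[3]] - x[, , d[3]] }
  )
  out
}

# adjoint of finite_diff: (D^T z)_i = z_{i-1} - z_i with z_0 = 0
finite_diff_adj <- function(z, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(z)
  out <- -z
  switch(axis,
    y = { out[-1, , ] <- out[-1, , , drop = FALSE] + z[-d[1], , , drop = FALSE] },
    x = { out[, -1, ] <- out[, -1, , drop = FALSE] + z[, -d[2], , drop = FALSE] },
    z = { if (d[3] > 1L) {
            out[, , -1] <- out[, , -1, drop = FALSE] + z[, , -d[3], drop = FALSE]
          } }
  )
  out
}

# conjugate gradient on a symmetric positive (semi)definite operator
cg_solve <- function(apply_fn, b, x0, iters, tol = 1e-10) {
  x <- x0
  r <- b - apply_fn(x)
  p <- r
  rs <- sum(r * r)
  b2 <- sum(b * b)
  if (b2 == 0) b2 <- 1
  for (i in seq_len(iters)) {
    if (sqrt(rs / b2) < tol) break
    Ap <- apply_fn(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

# shared ADMM engine on raw arrays; returns list(x, log)
admm_engine <- function(yvals, geometry, n, voxel_size, cfg, x0) {
  axes <- cfg$tv_axes
  lam <- cfg$tv_weight
  rho <- cfg$penalty
  dw <- cfg$data_weight
  fan <- geometry$beam_mode == "fan_per_slice"
  ns <- dim(yvals)[3]

  Afun <- function(x) {
    out <- array(0, dim = dim(yvals))
    for (k in seq_len(ns)) {
      out[, , k] <- cpp_forward_project(
        slice_mat(x, k), geometry$angles, geometry$detector_pixels,
        geometry$detector_pitch, voxel_size,
        geometry$source_to_isocenter, geometry$source_to_detector, fan)
    }
    out
  }
  Atfun <- function(y) {
    out <- array(0, dim = c(n, n, ns))
    for (k in seq_len(ns)) {
      out[, , k] <- cpp_back_project(
        slice_mat(y, k), geometry$angles, as.integer(n),
        geometry$detector_pitch, voxel_size,
        geometry$source_to_isocenter, geometry$source_to_detector, fan)
    }
    out
  }
  D <- function(x) lapply(axes, function(a) finite_diff(x, a))
  Dt <- function(zl) {
    out <- array(0, dim = c(n, n, ns))
    for (j in seq_along(axes)) out <- out + finite_diff_adj(zl[[j]], axes[j])
    out
  }

  x <- x0
  z <- D(x)
  u <- lapply(z, function(e) array(0, dim = dim(e)))
  Aty <- Atfun(yvals)
  normal_op <- function(v) {
    out <- dw * Atfun(Afun(v))
    if (rho > 0) out <- out + rho * Dt(D(v))
    out
  }
  log <- vector("list", cfg$outer_iters)
  prev_primal <- Inf
  growth <- 0L
  dx_norm <- function(l) sqrt(sum(vapply(l, function(e) sum(e^2), numeric(1))))
  for (it in seq_len(cfg$outer_iters)) {
    rhs <- dw * Aty + rho * Dt(Map(`-`, z, u))
    x <- cg_solve(normal_op, rhs, x, cfg$cg_iters)
    Dx <- D(x)
    z_old <- z
    thr <- if (rho > 0) lam / rho else 0
    z <- lapply(Map(`+`, Dx, u), soft_threshold, threshold = thr)
    u <- Map(`-`, Map(`+`, u, Dx), z)
    primal <- dx_norm(Map(`-`, Dx, z))
    dual <- rho * dx_norm(Map(`-`, z, z_old))
    obj <- dw / 2 * sum((yvals - Afun(x))^2) +
      lam * sum(vapply(Dx, function(e) sum(abs(e)), numeric(1)))
    log[[it]] <- c(iter = it, primal = primal, dual = dual, objective = obj)
    ref <- dx_norm(Dx)
    if (primal <= cfg$tolerance * max(ref, 1e-12)) { log <- log[seq_len(it)]; break }
    growth <- if (primal > prev_primal * 1.001) growth + 1L else 0L
    if (growth >= 10L) {
      stop(sprintf("ADMM diverging: primal residual grew over 10 consecutive iterations (iter %d, primal %.3g)",
                   it, primal))
    }
    prev_primal <- primal
  }
  list(x = x, log = tibble::as_tibble(do.call(rbind, log[!vapply(log, is.null, logical(1))])))
}

#' Iterative TV-regularized reconstruction via ADMM
#'
#' Approximately minimizes `1/2 ||y - A x||^2 + tv_weight ||D x||_1` with the
#' single-split ADMM (`z = D x`): conjugate-gradient solve of the quadratic
#' x-subproblem on `A^T A + rho D^T D`, soft-thresholding z-update, and dual
#' ascent.  Anisotropic TV (L1 of each stacked axis difference).  The
#' iteration log (primal/dual residuals and objective) is attached as the
#' `"admm_log"` attribute.
#'
#' @param sino a [sinogram()].
#' @param geometry the matching [scan_geometry()].
#' @param n output grid size.
#' @param cfg an [admm_config()]; the standalone baseline uses all three axes.
#' @param init optional [image_volume()] warm start (default zero).
#' @param voxel_size voxel edge (mm).
#' @param hu_window carried to the output.
#' @return An [image_volume()] with attribute `"admm_log"` (a tibble).
#' @export
admm_tv_reconstruct <- function(sino, geometry, n, cfg = admm_config(),
                                init = NULL, voxel_size = 4.13,
                                hu_window = c(-1000, 1000)) {
  stopifnot(inherits(sino, "sinogram"), inherits(cfg, "admm_config"))
  ns <- dim(sino$values)[3]
  x0 <- if (is.null(init)) array(0, dim = c(n, n, ns)) else init$voxels
  if (!all(dim(x0) == c(n, n, ns))) stop("init volume shape mismatch")
  res <- admm_engine(sino$values, geometry, n, voxel_size[1], cfg, x0)
  out <- image_volume(array(0, dim = dim(res$x)), voxel_size = voxel_size,
                      hu_window = hu_window)
  out$voxels <- res$x
  attr(out, "admm_log") <- res$log
  out
}

#' Data-fidelity update with z-only TV (diffusion-loop subproblem)
#'
#' One (by default) warm-started ADMM outer iteration of
#' `argmin 1/2 ||y - A x||^2 + tv_weight ||D_z x||_1`, the relaxed
#' data-consistency projection applied after each reverse-diffusion step.
#' Exact minimization can only lower the data residual relative to the warm
#' start, and the CG x-update preserves that monotonicity.
#'
#' @param x_prime [image_volume()] warm start (the denoised iterate).
#' @param sino a [sinogram()].
#' @param geometry the matching [scan_geometry()].
#' @param cfg an [admm_config()] with `tv_axes = "z"`.
#' @return An [image_volume()] with attribute `"admm_log"`.
#' @export
data_fidelity_update <- function(x_prime, sino, geometry,
                                 cfg = admm_config(tv_axes = "z", outer_iters = 1L)) {
  stopifnot(inherits(x_prime, "image_volume"), inherits(cfg, "admm_config"))
  if (!identical(cfg$tv_axes, "z")) stop("data_fidelity_update requires tv_axes = 'z'")
  n <- dim(x_prime$voxels)[1]
  res <- admm_engine(sino$values, geometry, n, x_prime$voxel_size[1], cfg,
                     x_prime$voxels)
  out <- x_prime
  out$voxels <- res$x
  attr(out, "admm_log") <- res$log
  out
}
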