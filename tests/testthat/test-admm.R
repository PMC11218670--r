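test_that("soft thresholding is the L1 proximal map", {
  expect_equal(soft_threshold(1.5, 1.0), 0.5)
  expect_equal(soft_threshold(-0.3, 1.0), 0)
  expect_equal(soft_threshold(c(-2, -0.5, 0, 0.5, 2), 1), c(-1, 0, 0, 0, 1))
  v <- matrix(rnorm(20), 4)
  expect_equal(soft_threshold(v, 0), v)
  expect_error(soft_threshold(v, -1), "non-negative")
})

test_that("finite differences and their adjoints pair exactly", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  z <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  for (ax in c("x", "y", "z")) {
    lhs <- sum(pfgdm:::finite_diff(x, ax) * z)
    rhs <- sum(x * pfgdm:::finite_diff_adj(z, ax))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # single-slice volumes have zero-boundary z-differences: D_z x = -x
  x1 <- array(rnorm(16), c(4, 4, 1))
  expect_equal(pfgdm:::finite_diff(x1, "z"), -x1)
})

test_that("with no TV weight the solver matches dense least squares", {
  set.seed(7)
  n <- 8
  g <- test_geometry(seq(0, 350, by = 4), ndet = 16L, pitch = 24.8)
  A <- dense_system_matrix(g, n, voxel_size = 24.8)
  xt <- runif(n * n)
  y <- as.numeric(A %*% xt)
  xls <- solve(crossprod(A), crossprod(A, y))
  sino <- sinogram(array(y, c(length(g$angles), 16, 1)), g)
  cfg <- admm_config(tv_weight = 0, penalty = 0, outer_iters = 2L,
                     cg_iters = 400L)
  rec <- admm_tv_reconstruct(sino, g, n, cfg, voxel_size = 24.8)
  rel <- sqrt(sum((as.numeric(rec$voxels) - xls)^2) / sum(xls^2))
  expect_lt(rel, 1e-4)
})

test_that("TV reconstruction beats FBP on a limited-angle scan", {
  spec <- phantom_spec(n_slices = 1L, seed = 31)
  target <- generate_phantom_pair(spec)$current
  g <- test_geometry(make_limited_angle_set("ortho", 90, 0.25))
  s <- forward_project(target, g)
  fdk <- clip01(fdk_reconstruct(s, g, 64))
  tv <- clip01(admm_tv_reconstruct(s, g, 64,
                                   admm_config(tv_weight = 3, penalty = 30,
                                               outer_iters = 25L, cg_iters = 8L)))
  expect_gt(evaluate_reconstruction(tv, target)$psnr,
            evaluate_reconstruction(fdk, target)$psnr)
  lg <- attr(tv, "admm_log")
  expect_true(all(c("iter", "primal", "dual", "objective") %in% names(lg)))
  # objective at the solution beats the fixed reference point A^T y
  ref <- back_project(s, g, 64)
  obj <- function(x) 0.5 * sum((s$values - forward_project(
    image_volume(x, voxel_size = 4.13), g)$values)^2) +
    3 * sum(abs(pfgdm:::finite_diff(x, "x"))) +
    3 * sum(abs(pfgdm:::finite_diff(x, "y"))) +
    3 * sum(abs(pfgdm:::finite_diff(x, "z")))
  expect_lt(obj(tv$voxels), obj(ref$voxels))
})

test_that("the data-fidelity update is a fixed point on consistent data", {
  spec <- phantom_spec(n_slices = 1L, seed = 41)
  target <- generate_phantom_pair(spec)$current
  g <- test_geometry(make_limited_angle_set("ortho", 60, 0.25))
  s <- forward_project(target, g)
  out <- data_fidelity_update(target, s, g)
  expect_lt(max(abs(out$voxels - target$voxels)), 1e-6)
})

test_that("the data-fidelity update never increases the data residual", {
  set.seed(8)
  spec <- phantom_spec(seed = 51)
  target <- generate_phantom_pair(spec)$current
  g <- test_geometry(make_limited_angle_set("ortho", 90, 0.25))
  s <- forward_project(target, g)
  resid <- function(v) sqrt(sum((s$values - forward_project(v, g)$values)^2))
  for (trial in 1:25) {
    x <- target
    x$voxels <- target$voxels + array(rnorm(length(target$voxels),
                                            sd = runif(1, 0.01, 2)),
                                      dim = dim(target$voxels))
    out <- data_fidelity_update(x, s, g)
    expect_lte(resid(out), resid(x) * (1 + 1e-10))
  }
})

test_that("the z-TV prior does not grow the slice difference of a consistent stack", {
  set.seed(9)
  spec <- phantom_spec(n_slices = 1L, seed = 61)
  sl <- generate_phantom_pair(spec)$current$voxels[, , 1]
  two <- image_volume(array(rep(sl, 2), c(64, 64, 2)))
  g <- test_geometry(make_limited_angle_set("ortho", 90, 0.25))
  s <- forward_project(two, g)
  zdiff <- function(v) sum(abs(v$voxels[, , 2] - v$voxels[, , 1]))
  out <- data_fidelity_update(two, s, g)
  expect_lte(zdiff(out), zdiff(two) + 1e-8)
})

test_that("ADMM requires z-only axes for the in-loop update and aborts on divergence", {
  spec <- phantom_spec(n_slices = 1L, seed = 71)
  target <- generate_phantom_pair(spec)$current
  g <- test_geometry(make_limited_angle_set("ortho", 30, 0.25))
  s <- forward_project(target, g)
  expect_error(data_fidelity_update(target, s, g, admm_config(tv_axes = c("x", "z"))),
               "tv_axes")
})
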