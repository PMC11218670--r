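test_that("Sobel magnitude matches hand-convolved cases", {
  expect_lt(max(sobel_magnitude(matrix(0.7, 9, 9))), 1e-12)
  # unit step across columns: correlation with the 3x3 kernels gives
  # magnitude 4 on the two columns adjacent to the edge, zero elsewhere
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  m <- sobel_magnitude(step)
  expect_equal(m[, 4], rep(4, 8))
  expect_equal(m[, 5], rep(4, 8))
  expect_true(all(m[, c(1:3, 6:8)] == 0))
})

test_that("Sobel magnitude is equivariant under 90-degree rotation", {
  set.seed(10)
  x <- matrix(rnorm(144), 12)
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(sobel_magnitude(rot(x)), rot(sobel_magnitude(x)),
               tolerance = 1e-12)
})

test_that("thresholding keeps-or-zeroes and tracks the kept count", {
  m <- matrix(c(1, 2, 3, 4), 2)
  h <- threshold_highfreq(m, 2.5)
  expect_equal(h$map, matrix(c(0, 0, 3, 4), 2))
  expect_equal(h$nonzero, 2L)
  expect_equal(threshold_highfreq(m, 0)$map, m)
  expect_true(all(threshold_highfreq(m, 5)$map == 0))
  expect_error(threshold_highfreq(m, -1), "non-negative")
})

test_that("thresholding sparsifies monotonically and is idempotent", {
  sl <- generate_phantom_pair(phantom_spec(n_slices = 1L, seed = 81))$current$voxels[, , 1]
  mag <- sobel_magnitude(sl)
  etas <- seq(0, max(mag) * 1.02, length.out = 50)
  counts <- vapply(etas, function(e) threshold_highfreq(mag, e)$nonzero, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[50], 0L)
  h <- threshold_highfreq(mag, etas[25])
  expect_equal(threshold_highfreq(h$map, etas[25])$map, h$map)
})

test_that("the reciprocal threshold rule telescopes as eta_m = (T/m) eta_T", {
  sch <- threshold_schedule(0.1, 100L, rule = "reciprocal")
  # single-step evaluation
  expect_equal(step_threshold(sch, 0.1, 2), 0.2)
  expect_equal(step_threshold(sch, 0, 57), 0)
  expect_identical(step_threshold(sch, 0.3, 1), Inf)
  # composed from T down to m for every m
  eta <- 0.1
  for (t in seq(100L, 2L)) {
    eta_next <- step_threshold(sch, eta, t)
    expect_equal(eta_next, schedule_threshold(sch, t - 1L), tolerance = 1e-12)
    eta <- eta_next
  }
  for (m in 1:100) {
    expect_equal(schedule_threshold(sch, m), 0.1 * 100 / m, tolerance = 1e-12)
  }
})

test_that("threshold schedules grow as the reverse process advances", {
  mag_max <- 3.7
  for (rule in c("geometric_span", "reciprocal", "constant_k")) {
    sch <- threshold_schedule(0.05, 60L, rule = rule, k = 1.08, eta_max = mag_max)
    etas <- vapply(seq(60L, 1L), function(t) schedule_threshold(sch, t), numeric(1))
    expect_true(all(diff(etas) >= 0))
  }
  sch <- threshold_schedule(0.05, 60L, rule = "geometric_span", eta_max = mag_max)
  expect_equal(schedule_threshold(sch, 1L), mag_max, tolerance = 1e-9)
  expect_equal(schedule_threshold(sch, 60L), 0.05)
  # below the final step the condition is empty
  expect_identical(schedule_threshold(sch, 0L), Inf)
})

test_that("the null condition is a constant -1 map", {
  nc <- null_condition(c(5, 7))
  expect_true(nc$null_flag)
  expect_equal(dim(nc$map), c(5L, 7L))
  expect_equal(mean(nc$map), -1)
  expect_equal(nc$nonzero, 0L)
})

test_that("the default starting threshold keeps nearly all edges", {
  sl <- generate_phantom_pair(phantom_spec(n_slices = 1L, seed = 91))$current$voxels[, , 1]
  mag <- sobel_magnitude(sl)
  eta0 <- default_eta_start(mag)
  h <- threshold_highfreq(mag, eta0)
  expect_gte(h$nonzero / sum(mag > 0), 0.85)
  expect_equal(default_eta_start(matrix(0, 4, 4)), 0)
})
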