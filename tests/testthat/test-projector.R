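test_that("parallel projection of a uniform disk matches the closed-form chord", {
  n <- 256
  r <- 50
  vol <- image_volume(array(raster_disk(n, r, sup = 8L), c(n, n, 1)),
                      voxel_size = 1)
  g <- test_geometry(c(0, 18.7, 45, 77.3), ndet = 201L, pitch = 1,
                     mode = "parallel_per_slice")
  sino <- forward_project(vol, g)
  u <- (seq_len(201) - 101)
  offsets <- abs(u) <= 0.8 * r          # away from the tangent rays
  expect_gte(sum(offsets), 20L)
  chord <- 2 * sqrt(pmax(r^2 - u^2, 0))
  for (a in seq_along(g$angles)) {
    expect_lt(max(abs(sino$values[a, offsets, 1] - chord[offsets])) / (2 * r),
              0.02)
  }
})

test_that("ray through a uniform square yields the side length", {
  # 20x20 unit-attenuation square of side 20 mm, axial ray through the centre
  n <- 20
  vol <- image_volume(array(1, c(n, n, 1)), voxel_size = 1)
  g <- test_geometry(0, ndet = 21L, pitch = 1, mode = "parallel_per_slice")
  sino <- forward_project(vol, g)
  expect_equal(sino$values[1, 11, 1], n, tolerance = 1e-9)
})

test_that("the projector is linear and maps zero to zero", {
  set.seed(1)
  g <- test_geometry(make_limited_angle_set("ortho", 40), ndet = 32L, pitch = 12.4)
  zero <- image_volume(array(0, c(16, 16, 2)), voxel_size = 16.5)
  expect_true(all(forward_project(zero, g)$values == 0))
  v1 <- zero; v1$voxels <- array(rnorm(512), c(16, 16, 2))
  v2 <- zero; v2$voxels <- array(rnorm(512), c(16, 16, 2))
  comb <- zero; comb$voxels <- 2.5 * v1$voxels - 1.3 * v2$voxels
  expect_equal(forward_project(comb, g)$values,
               2.5 * forward_project(v1, g)$values -
                 1.3 * forward_project(v2, g)$values,
               tolerance = 1e-12)
})

test_that("back projection is the exact adjoint across the geometry grid", {
  set.seed(2)
  for (mode in c("fan_per_slice", "parallel_per_slice")) {
    for (ndet in c(16L, 128L)) {
      g <- test_geometry(make_limited_angle_set("ortho", 60, 0.25),
                         ndet = ndet, pitch = 396.8 / ndet, mode = mode)
      n <- 24
      for (i in 1:13) {
        x <- array(rnorm(n * n), c(n, n, 1))
        y <- array(rnorm(length(g$angles) * ndet), c(length(g$angles), ndet, 1))
        vx <- image_volume(array(0, c(n, n, 1)), voxel_size = 11)
        vx$voxels <- x
        Ax <- forward_project(vx, g)$values
        Aty <- back_project(sinogram(y, g), g, n, voxel_size = 11)$voxels
        lhs <- sum(Ax * y); rhs <- sum(x * Aty)
        expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-6)
      }
    }
  }
  # zero sinogram maps to the zero volume
  g <- test_geometry(c(0, 10), ndet = 8L, pitch = 50)
  z <- sinogram(array(0, c(2, 8, 1)), g)
  expect_true(all(back_project(z, g, 8, voxel_size = 50)$voxels == 0))
})

test_that("dense matrix assembled from basis vectors reproduces the operator", {
  set.seed(3)
  g <- test_geometry(seq(0, 350, by = 22), ndet = 12L, pitch = 33)
  n <- 8
  A <- dense_system_matrix(g, n, voxel_size = 33)
  for (i in 1:5) {
    x <- matrix(rnorm(n * n), n)
    vx <- image_volume(array(x, c(n, n, 1)), voxel_size = 33)
    expect_equal(as.numeric(forward_project(vx, g)$values[, , 1]),
                 as.numeric(A %*% as.numeric(x)), tolerance = 1e-12)
  }
})

test_that("a single unit ray back-projects to its hand-traced footprint", {
  # 4x4 unit grid, parallel beam; the 45-degree central ray runs corner to
  # corner through the diagonal cells, length sqrt(2) in each
  g <- test_geometry(45, ndet = 3L, pitch = 1, mode = "parallel_per_slice")
  y <- array(0, c(1, 3, 1)); y[1, 2, 1] <- 1   # central detector, u = 0
  fp <- back_project(sinogram(y, g), g, 4, voxel_size = 1)$voxels[, , 1]
  expected <- diag(4) * sqrt(2)
  expect_equal(fp, expected, tolerance = 1e-9)
  # horizontal ray along row of cells: length 1 in each of the 4 cells
  g0 <- test_geometry(0, ndet = 4L, pitch = 1, mode = "parallel_per_slice")
  y0 <- array(0, c(1, 4, 1)); y0[1, 2, 1] <- 1  # u = -0.5, row y = -0.5
  fp0 <- back_project(sinogram(y0, g0), g0, 4, voxel_size = 1)$voxels[, , 1]
  expected0 <- matrix(0, 4, 4); expected0[2, ] <- 1
  expect_equal(fp0, expected0, tolerance = 1e-9)
})

test_that("rotating the phantom 90 degrees equals shifting the angle set", {
  set.seed(4)
  n <- 32
  img <- raster_disk(n, 9)
  img[8:12, 18:26] <- img[8:12, 18:26] + 0.7
  vol <- image_volume(array(img, c(n, n, 1)), voxel_size = 8)
  # rotate +90 deg CCW about the centre: (x, y) -> (-y, x)
  rot <- t(img)[, n:1]
  rvol <- image_volume(array(rot, c(n, n, 1)), voxel_size = 8)
  g1 <- test_geometry(c(0, 25, 50), ndet = 48L, pitch = 8, mode = "parallel_per_slice")
  g2 <- test_geometry(c(90, 115, 140), ndet = 48L, pitch = 8, mode = "parallel_per_slice")
  s1 <- forward_project(vol, g1)$values
  s2 <- forward_project(rvol, g2)$values
  expect_equal(s2, s1, tolerance = 1e-6)
})

test_that("sinogram domains convert consistently", {
  vol <- image_volume(array(raster_disk(24, 8) * 0.5, c(24, 24, 1)), voxel_size = 11)
  g <- test_geometry(make_limited_angle_set("single", 20), ndet = 24L, pitch = 16.5)
  s <- forward_project(vol, g)
  nm <- noise_model(1e5)
  si <- convert_sinogram_domain(s, "intensity", nm)
  expect_true(all(si$values <= 1e5 + 1e-6))
  back <- convert_sinogram_domain(si, "attenuation", nm)
  expect_equal(back$values, s$values, tolerance = 1e-10)
  # converting to the current domain is the identity
  expect_identical(convert_sinogram_domain(s, "attenuation", nm), s)
})

test_that("projection noise has the stated photon-count moments", {
  g <- test_geometry(rep_len(0, 1), ndet = 16L, pitch = 25)
  y <- array(0, c(100, 100))                   # zero attenuation everywhere
  nm <- noise_model(photons_per_pixel = 1e5, electronic_variance = 10)
  counts <- simulate_photon_counts(y, nm, seed = 11)
  expect_lt(abs(mean(counts) - 1e5), 3 * sqrt(1e5 / 1e4))
  expect_lt(abs(var(as.numeric(counts)) - (1e5 + 10)) / (1e5 + 10), 0.10)
})

test_that("projection noise is seed-deterministic and optional", {
  vol <- image_volume(array(raster_disk(24, 8) * 0.5, c(24, 24, 1)), voxel_size = 11)
  g <- test_geometry(make_limited_angle_set("single", 20), ndet = 24L, pitch = 16.5)
  s <- forward_project(vol, g)
  off <- add_projection_noise(s, noise_model(enabled = FALSE), seed = 1)
  expect_identical(off$values, s$values)
  n1 <- add_projection_noise(s, noise_model(1e5), seed = 42)
  n2 <- add_projection_noise(s, noise_model(1e5), seed = 42)
  n3 <- add_projection_noise(s, noise_model(1e5), seed = 43)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_false(identical(n1$values, s$values))
})
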