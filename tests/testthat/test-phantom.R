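test_that("phantom pairs are reproducible and differ only inside the mask", {
  spec <- phantom_spec(seed = 121)
  p1 <- generate_phantom_pair(spec)
  p2 <- generate_phantom_pair(spec)
  expect_identical(p1$prior$voxels, p2$prior$voxels)
  expect_identical(p1$current$voxels, p2$current$voxels)
  expect_true(any(p1$mask))
  expect_identical(p1$prior$voxels[!p1$mask], p1$current$voxels[!p1$mask])
  expect_true(all(p1$prior$voxels[p1$mask] != p1$current$voxels[p1$mask]))
  expect_true(all(p1$current$voxels >= 0 & p1$current$voxels <= 1))
})

test_that("a zero mismatch magnitude yields an identical pair", {
  spec <- phantom_spec(mismatch_magnitude = 0, seed = 131)
  p <- generate_phantom_pair(spec)
  expect_identical(p$prior$voxels, p$current$voxels)
  expect_false(any(p$mask))
})

test_that("an inserted disk lesion marks exactly its rasterized voxels", {
  # explicit geometry, no texture: the difference mask must equal the set of
  # pixel centres inside the lesion ellipse, counted independently here
  n <- 48
  body <- list(center = c(0, 0, 0), axes = c(0.9, 0.9, 3), angle = 0,
               value = 0.3)
  lesion <- list(center = c(0.25, -0.1, 0), axes = c(0.2, 0.2, 3), angle = 0,
                 value = 0.8)
  spec <- phantom_spec(n = n, n_slices = 1L, mismatch_magnitude = 1,
                       texture_amplitude = 0, structures = list(body),
                       lesions = list(lesion), seed = 141)
  p <- generate_phantom_pair(spec)
  xs <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  X <- outer(rep(1, n), xs); Y <- outer(xs, rep(1, n))
  inside <- ((X - 0.25) / 0.2)^2 + ((Y + 0.1) / 0.2)^2 <= 1
  expect_equal(sum(p$mask), sum(inside))
  expect_equal(unname(which(p$mask[, , 1])), unname(which(inside)))
})

test_that("the training corpus pairs every slice with its own edges", {
  spec <- phantom_spec(n = 32L, n_slices = 2L, voxel_size = 8.26, seed = 151)
  corpus <- build_training_corpus(4, spec, seed = 3)
  expect_length(corpus$items, 8L)
  for (it in corpus$items) {
    expect_equal(it$magnitude, sobel_magnitude(it$slice))
  }
  # reproducibility
  corpus2 <- build_training_corpus(4, spec, seed = 3)
  expect_identical(corpus$items[[5]]$slice, corpus2$items[[5]]$slice)
})

test_that("corpus intensities span nearly the whole normalized range", {
  corpus <- build_training_corpus(8, phantom_spec(seed = 161), seed = 5)
  vals <- unlist(lapply(corpus$items, function(it) as.numeric(it$slice)))
  occupied <- table(cut(vals, breaks = seq(0, 1, length.out = 21)))
  expect_gte(sum(occupied > 0) / 20, 0.9)
})

test_that("misalignment shifts rigidly with exact integer-voxel rolls", {
  spec <- phantom_spec(seed = 171)
  vol <- generate_phantom_pair(spec)$prior
  expect_identical(misalign(vol, 0)$voxels, vol$voxels)
  # integer-voxel shift equals an index roll with edge padding
  s <- 3
  m <- vol$voxels[, , 1]
  rolled_x <- cbind(m[, 1, drop = FALSE][, rep(1, s)], m[, 1:(64 - s)])
  rolled_y <- rbind(m[1, , drop = FALSE][rep(1, s), ], m[1:(64 - s), ])
  shifted <- misalign(vol, s * vol$voxel_size[1], axis_choice_seed = 1L)
  expect_true(identical(shifted$voxels[, , 1], rolled_x) ||
                identical(shifted$voxels[, , 1], rolled_y))
  # shifting forward then backward restores the interior exactly when the
  # support stays clear of the padded edge
  sl <- pfgdm:::shift_slice(m, 3, "x")
  back <- pfgdm:::shift_slice(sl, -3, "x")
  expect_lt(max(abs(back - m)), 1e-6)
  expect_error(misalign(vol, 64 * vol$voxel_size[1]), "half the field")
})
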