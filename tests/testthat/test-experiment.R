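tiny_config <- function(seed = 1L, out = NULL) {
  list(
    seed = seed, output_dir = out, methods = c("fdk", "admm_tv"),
    phantom = list(n = 32L, n_slices = 1L, n_structures = 6L, voxel_size = 8.26),
    geometry = list(mode = "ortho", total_angle = 60, sampling_density = 0.25,
                    detector_pixels = 32L, detector_pitch = 12.4),
    admm_tv = list(outer_iters = 10L)
  )
}

test_that("unknown configuration keys are rejected by name", {
  expect_error(experiment_config(list(sead = 1)), "sead")
  expect_error(experiment_config(list(phantom = list(nn = 3))), "phantom.nn")
  expect_error(experiment_config(list(methods = "dolce")), "dolce")
})

test_that("a small experiment runs end to end and writes its artifacts", {
  out <- withr::local_tempdir()
  res <- run_experiment(tiny_config(out = out))
  expect_equal(res$status, 0L)
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  expect_true(file.exists(file.path(out, "fdk.nii")))
  expect_setequal(res$metrics$method, c("FDK", "ADMM-TV"))
  expect_true(all(is.finite(res$metrics$psnr_mean)))
})

test_that("reruns of one configuration are identical in metrics and manifest", {
  r1 <- run_experiment(tiny_config(seed = 5L))
  r2 <- run_experiment(tiny_config(seed = 5L))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  r3 <- run_experiment(tiny_config(seed = 6L))
  expect_false(identical(r1$metrics, r3$metrics))
})

test_that("failures leave a marker and a nonzero status", {
  out <- withr::local_tempdir()
  cfg <- tiny_config(out = out)
  cfg$geometry$total_angle <- -10
  res <- run_experiment(cfg)
  expect_equal(res$status, 1L)
  expect_true(file.exists(file.path(out, "FAILED")))
})

test_that("compare_table aggregates reports with sample statistics", {
  mk <- function(method, psnr, ssim, ref = "r1") {
    structure(list(method = method, steps = tibble::tibble(),
                   psnr = psnr, ssim = ssim, reference_hash = ref),
              class = "recon_report")
  }
  single <- compare_table(list(mk("FDK", 20, 0.8)))
  expect_equal(nrow(single), 1L)
  expect_equal(single$psnr_sd, 0)
  dup <- compare_table(list(mk("FDK", 20, 0.8), mk("FDK", 20, 0.8)))
  expect_equal(dup$psnr_sd, 0)
  three <- compare_table(list(mk("X", 20, 0.7), mk("X", 22, 0.7), mk("X", 24, 0.7)))
  expect_equal(three$psnr_mean, 22)
  expect_equal(three$psnr_sd, 2)
  expect_error(compare_table(list(mk("A", 20, 0.8, "r1"), mk("B", 21, 0.8, "r2"))),
               "mixed references")
})
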