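test_that("noise schedules are geometric with positive variance increments", {
  sch <- diffusion_schedule(0.01, 10, 50L)
  expect_equal(sch$sigmas[1], 0.01)
  expect_equal(sch$sigmas[50], 10)
  expect_true(all(diff(sch$sigmas) > 0))
  dv <- sch$sigmas^2 - c(0, head(sch$sigmas, -1))^2
  expect_true(all(dv > 0))
  expect_error(diffusion_schedule(1, 0.5), "sigma_max")
})

test_that("the closed-form perturbation has the kernel's moments", {
  sch <- diffusion_schedule(0.01, 5, 40L)
  x0 <- matrix(0.5, 100, 100)
  p0 <- perturb(x0, sch, 0L, seed = 1)
  expect_identical(p0$x, x0)
  p <- perturb(x0, sch, 25L, seed = 2)
  s <- sch$sigmas[25]
  dev <- as.numeric(p$x - x0)
  expect_lt(abs(sd(dev) - s) / s, 3 / sqrt(2 * (1e4 - 1)))
  expect_lt(abs(mean(dev)), 3 * s / 100)
  # determinism and the returned draw
  p2 <- perturb(x0, sch, 25L, seed = 2)
  expect_identical(p$x, p2$x)
  expect_equal(p$x, x0 + s * p$z)
})

test_that("stepwise chain composition matches the closed-form kernel in law", {
  sch <- diffusion_schedule(0.05, 3, 12L)
  i <- 9L
  set.seed(12)
  n <- 1e4
  # compose the forward chain step by step with fresh standard draws
  x <- numeric(n)
  for (k in seq_len(i)) {
    dv <- sch$sigmas[k]^2 - (if (k == 1) 0 else sch$sigmas[k - 1]^2)
    x <- x + sqrt(dv) * rnorm(n)
  }
  ks <- stats::ks.test(x / sch$sigmas[i], pnorm)
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n))  # alpha = 0.01 critical value
})

test_that("the DSM loss is zero for the exact kernel score and ~pixel count for a null model", {
  sch <- diffusion_schedule(0.01, 5, 30L)
  x0 <- matrix(runif(256), 16)
  ds <- list(items = list(list(slice = x0, magnitude = NULL)))
  oracle <- score_model_fn(function(x, sigma, cond) -(x - x0) / sigma^2,
                           sigma_range = c(0.01, 5))
  cfg <- train_config("A", batch_size = 16L)
  expect_lt(dsm_loss(oracle, ds, sch, cfg, seed = 3), 1e-20)
  null_model <- score_model_fn(function(x, sigma, cond) x * 0,
                               sigma_range = c(0.01, 5))
  loss <- dsm_loss(null_model, ds, sch, cfg, seed = 4)
  expect_lt(abs(loss - 256) / 256, 0.15)
})

test_that("the DSM loss is invariant to batch order", {
  set.seed(13)
  m <- score_model_cnn(hidden = 4L, depth = 2L, sigma_range = c(0.01, 5), seed = 5)
  m$params[[2]]$W[] <- rnorm(length(m$params[[2]]$W), sd = 0.1)
  batch <- lapply(1:6, function(i) {
    list(x = matrix(rnorm(64), 8), z = matrix(rnorm(64), 8),
         sigma = runif(1, 0.1, 3), cond = matrix(runif(64), 8))
  })
  l1 <- pfgdm:::dsm_lossgrad(m, batch, want_grad = FALSE)$loss
  l2 <- pfgdm:::dsm_lossgrad(m, rev(batch), want_grad = FALSE)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("analytic gradients of the conv network match finite differences", {
  set.seed(14)
  m <- score_model_cnn(hidden = 4L, depth = 3L, sigma_range = c(0.01, 5), seed = 6)
  m$params[[3]]$W[] <- rnorm(length(m$params[[3]]$W), sd = 0.1)
  batch <- lapply(1:2, function(i) {
    list(x = matrix(runif(64), 8), z = matrix(rnorm(64), 8), sigma = 0.7,
         cond = matrix(runif(64), 8))
  })
  lg <- pfgdm:::dsm_lossgrad(m, batch, want_grad = TRUE)
  eps <- 1e-6
  for (l in 1:3) for (nm in c("W", "b")) {
    v <- m$params[[l]][[nm]]
    for (j in sample(length(v), min(4, length(v)))) {
      m2 <- m
      m2$params[[l]][[nm]][j] <- v[j] + eps
      lp <- pfgdm:::dsm_lossgrad(m2, batch, want_grad = FALSE)$loss
      m2$params[[l]][[nm]][j] <- v[j] - eps
      lm <- pfgdm:::dsm_lossgrad(m2, batch, want_grad = FALSE)$loss
      expect_equal(lg$grads[[l]][[nm]][j], (lp - lm) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("training reduces the loss and keeps the condition pathway live", {
  spec <- phantom_spec(n = 24L, n_slices = 1L, n_structures = 6L,
                       voxel_size = 11, seed = 101)
  corpus <- build_training_corpus(6, spec, seed = 7)
  sch <- diffusion_schedule(0.01, 6, 40L)
  cfg <- train_config("A", iterations = 400L, batch_size = 8L, seed = 9)
  m <- train_score_model(corpus, sch, cfg, hidden = 6L, depth = 3L)
  expect_lt(mean(tail(m$loss_curve, 100)), mean(head(m$loss_curve, 100)))
  expect_true(all(is.finite(m$loss_curve)))
  # conditional and null evaluations must differ somewhere
  sl <- corpus$items[[1]]$slice
  h <- threshold_highfreq(corpus$items[[1]]$magnitude, 0.05)
  s_cond <- score_eval(m, sl, 0.5, h)
  s_null <- score_eval(m, sl, 0.5, NULL)
  expect_gt(max(abs(s_cond - s_null)), 0)
})

test_that("training is bit-reproducible under a fixed seed", {
  spec <- phantom_spec(n = 16L, n_slices = 1L, n_structures = 4L,
                       voxel_size = 16.5, seed = 111)
  corpus <- build_training_corpus(3, spec, seed = 17)
  sch <- diffusion_schedule(0.01, 4, 20L)
  cfg <- train_config("B", iterations = 40L, batch_size = 2L, seed = 23)
  m1 <- train_score_model(corpus, sch, cfg, hidden = 4L, depth = 2L)
  m2 <- train_score_model(corpus, sch, cfg, hidden = 4L, depth = 2L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_curve, m2$loss_curve)
})

test_that("predictor-corrector steps are seeded and configurable", {
  sch <- diffusion_schedule(0.01, 4, 20L)
  m0 <- score_model_fn(function(x, sigma, cond) x * 0, sigma_range = c(0.01, 4))
  x <- matrix(rnorm(64), 8)
  a <- pc_sample_step(m0, x, sch, 10L, corrector_steps = 0L, seed = 31)
  b <- pc_sample_step(m0, x, sch, 10L, corrector_steps = 0L, seed = 31)
  expect_identical(a, b)
  # zero score + no corrector: pure noise with the chain's variance increment
  set.seed(41)
  dv <- sch$sigmas[10]^2 - sch$sigmas[9]^2
  devs <- replicate(200, {
    y <- pc_sample_step(m0, x, sch, 10L, corrector_steps = 0L)
    (y - x)[1, 1]
  })
  expect_lt(abs(sd(devs) - sqrt(dv)) / sqrt(dv), 0.25)
  expect_error(pc_sample_step(m0, x, sch, 0L), "1..N")
})

test_that("reversing the chain with a zero score reproduces the forward variance", {
  sch <- diffusion_schedule(0.05, 2, 25L)
  m0 <- score_model_fn(function(x, sigma, cond) x * 0, sigma_range = c(0.05, 2))
  set.seed(43)
  x <- matrix(0, 40, 40)
  for (i in seq(25L, 1L)) {
    x <- pc_sample_step(m0, x, sch, i, corrector_steps = 0L)
  }
  # total injected variance telescopes to sigma_N^2
  expect_lt(abs(sd(as.numeric(x)) - 2) / 2, 0.10)
})
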