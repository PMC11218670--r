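#' Variance-exploding noise schedule
#'
#' The geometric sequence of noise scales `sigma_1 < ... < sigma_N` of the
#' variance-exploding SDE, with `sigma_0 = 0` by convention.  The forward
#' Markov chain adds `sqrt(sigma_i^2 - sigma_(i-1)^2)` of fresh Gaussian
#' noise per step, so the state at step i is `x_0 + sigma_i * z` in closed
#' form.
#'
#' @param sigma_min smallest positive noise scale.
#' @param sigma_max largest noise scale; a good default is the diameter of
#'   the training data (maximum pairwise L2 distance), see
#'   [estimate_sigma_max()].
#' @param num_steps N, the number of discretization steps.
#' @return An object of class `diffusion_schedule` with the `sigmas` vector.
#' @export
diffusion_schedule <- function(sigma_min = 0.01, sigma_max = 10, num_steps = 150L) {
  if (!(sigma_max > sigma_min && sigma_min > 0)) {
    stop("require sigma_max > sigma_min > 0")
  }
  if (num_steps < 2L) stop("num_steps must be >= 2")
  sigmas <- exp(seq(log(sigma_min), log(sigma_max), length.out = num_steps))
  structure(
    list(sigma_min = sigma_min, sigma_max = sigma_max,
         num_steps = as.integer(num_steps), sigmas = sigmas),
    class = "diffusion_schedule"
  )
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf("<diffusion_schedule> N = %d, sigma in [%g, %g] (geometric)\n",
              x$num_steps, x$sigma_min, x$sigma_max))
  invisible(x)
}

# sigma_i with the sigma_0 = 0 convention
sigma_at <- function(schedule, i) {
  if (i <= 0) 0 else schedule$sigmas[i]
}

#' Data diameter estimate for sigma_max
#'
#' Maximum pairwise L2 distance over (a subsample of) the training slices;
#' the standard choice of `sigma_max` so the terminal distribution overwhelms
#' the data spread.
#'
#' @param slices list of matrices.
#' @param max_n cap on the number of slices scanned.
#' @return Scalar.
#' @export
estimate_sigma_max <- function(slices, max_n = 50L) {
  if (length(slices) > max_n) slices <- slices[seq_len(max_n)]
  X <- vapply(slices, as.numeric, numeric(length(slices[[1]])))
  dmax <- max(stats::dist(t(X)))
  max(dmax, 1)
}

#' Forward perturbation (closed form of the VE chain)
#'
#' Draws `z ~ N(0, I)` and returns `x0 + sigma_i * z`, the closed-form
#' composition of the stepwise variance-exploding chain up to step `i`,
#' together with the noise draw.  Deterministic given `seed`.
#'
#' @param x0 clean slice (matrix).
#' @param schedule a [diffusion_schedule()].
#' @param i step index in `0..N` (`i = 0` returns `x0` unchanged).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return `list(x = noisy slice, z = noise draw, sigma = sigma_i)`.
#' @export
perturb <- function(x0, schedule, i, seed = NULL) {
  stopifnot(inherits(schedule, "diffusion_schedule"))
  if (i < 0 || i > schedule$num_steps) stop("i must be in 0..N")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  s <- sigma_at(schedule, i)
  z <- matrix(rnorm(length(x0)), nrow = nrow(x0))
  list(x = x0 + s * z, z = z, sigma = s)
}

#' Training configuration for denoising score matching
#'
#' @param variant `"A"` (condition dropout to the null map, training for the
#'   hard condition-drop reconstruction) or `"B"` (condition always present
#'   but thresholded at a random level drawn uniformly between the slice's
#'   minimum and maximum nonzero Sobel magnitude).
#' @param condition_dropout_prob probability of replacing the condition with
#'   the -1 null map (variant A; forced to 0 for variant B).
#' @param lambda_rule weighting of the DSM objective; `"sigma2"`
#'   (`lambda(sigma) = sigma^2`) is the variance weighting that makes the
#'   zero-model loss equal the pixel count, stabilizing training across
#'   noise decades.
#' @param batch_size,learning_rate,iterations Adam SGD settings.
#' @param train_eta_quantile quantile of the nonzero Sobel magnitude used as
#'   the fixed extraction threshold for variant-A conditions.
#' @param ema_decay exponential-moving-average decay of the weights; the
#'   averaged weights are returned as the trained model (standard practice
#'   for score networks).
#' @param seed integer seed controlling the whole run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(variant = c("A", "B"), condition_dropout_prob = NULL,
                         lambda_rule = "sigma2", batch_size = 8L,
                         learning_rate = 1e-3, iterations = 2000L,
                         train_eta_quantile = 0.10, ema_decay = 0.999,
                         seed = 1L) {
  variant <- match.arg(variant)
  if (!identical(lambda_rule, "sigma2")) stop("only the sigma2 lambda rule is implemented")
  if (is.null(condition_dropout_prob)) {
    condition_dropout_prob <- if (variant == "A") 0.5 else 0
  }
  if (variant == "B" && condition_dropout_prob != 0) {
    stop("variant B trains without condition dropout")
  }
  if (condition_dropout_prob < 0 || condition_dropout_prob > 1) {
    stop("condition_dropout_prob must lie in [0, 1]")
  }
  structure(
    list(variant = variant, condition_dropout_prob = condition_dropout_prob,
         lambda_rule = lambda_rule, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, iterations = as.integer(iterations),
         train_eta_quantile = train_eta_quantile, ema_decay = ema_decay,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# condition map for one training example under the configured variant
training_condition <- function(item, cfg) {
  mag <- item$magnitude
  if (cfg$variant == "A") {
    if (runif(1) < cfg$condition_dropout_prob) {
      return(null_condition(dim(item$slice))$map)
    }
    nz <- mag[mag > 0]
    eta <- if (length(nz)) as.numeric(quantile(nz, cfg$train_eta_quantile)) else 0
    ifelse(mag >= eta, mag, 0)
  } else {
    nz <- mag[mag > 0]
    if (!length(nz)) return(mag * 0)
    eta <- runif(1, min(nz), max(nz))
    ifelse(mag >= eta, mag, 0)
  }
}

# DSM loss (and optionally gradients) for a prepared batch.
# Each element of `batch` is list(x = noisy slice, z = noise draw,
# sigma = noise level, cond = condition map).  With the sigma^2 weighting and
# the residual parameterization (raw = sigma * score), the per-sample loss is
# sum((raw + z)^2).
dsm_lossgrad <- function(model, batch, want_grad = TRUE) {
  B <- length(batch)
  loss <- 0
  grads <- if (want_grad) zero_like_params(model$params) else NULL
  if (model$kind %in% c("cnn", "unet")) {
    fwd <- if (model$kind == "cnn") cnn_forward else unet_forward
    bwd <- if (model$kind == "cnn") cnn_backward else unet_backward
    for (b in batch) {
      fw <- fwd(model, cnn_input(model, b$x, b$sigma, b$cond))
      co <- cnn_coefs(b$sigma)
      x0 <- b$x - b$sigma * b$z
      D <- co$c_skip * b$x + co$c_out * fw$raw
      r <- (D - x0) / b$sigma        # equals sigma * score_error + z
      loss <- loss + sum(r * r) / B
      if (want_grad) {
        grads <- bwd(model, fw, (2 * co$c_out / (b$sigma * B)) * r, grads)
      }
    }
  } else if (model$kind == "mlp") {
    p <- model$params
    X <- vapply(batch, function(b) mlp_input(model, b$x, b$sigma),
                numeric(model$input_dim + 1L))
    Z <- vapply(batch, function(b) as.numeric(b$z), numeric(model$input_dim))
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = model$input_dim)
    H <- tanh(p[[1]]$W %*% X + p[[1]]$b)
    raw <- p[[2]]$W %*% H + p[[2]]$b
    R <- raw + Z
    loss <- sum(R * R) / B
    if (want_grad) {
      draw <- 2 * R / B
      grads[[2]]$W <- draw %*% t(H)
      grads[[2]]$b <- rowSums(draw)
      dH <- t(p[[2]]$W) %*% draw
      dZ1 <- dH * (1 - H^2)
      grads[[1]]$W <- dZ1 %*% t(X)
      grads[[1]]$b <- rowSums(dZ1)
    }
  } else {
    for (b in batch) {
      s <- model$fn(b$x, b$sigma, b$cond)
      r <- b$sigma * s + b$z
      loss <- loss + sum(r * r) / B
    }
  }
  list(loss = loss, grads = grads)
}

# draw a training batch: indices, step levels, noise, conditions
draw_batch <- function(dataset, schedule, cfg) {
  idx <- sample.int(length(dataset$items), cfg$batch_size, replace = TRUE)
  lapply(idx, function(j) {
    item <- dataset$items[[j]]
    i <- sample.int(schedule$num_steps, 1L)
    s <- schedule$sigmas[i]
    z <- matrix(rnorm(length(item$slice)), nrow = nrow(item$slice))
    cond <- if (is.null(item$magnitude)) NULL else training_condition(item, cfg)
    list(x = item$slice + s * z, z = z, sigma = s, cond = cond)
  })
}

#' Denoising score matching loss
#'
#' Samples a step level uniformly per batch element, perturbs the clean
#' slices with the closed-form VE kernel, and evaluates
#' `lambda(sigma) * || s_theta(x0 + sigma z, sigma, H) + z / sigma ||^2`
#' averaged over the batch, where `-z / sigma` is the conditional score of
#' the perturbation kernel.  Conditions follow the training variant (dropout
#' to the null map for A, random threshold for B).  Deterministic given
#' `seed`.
#'
#' @param model a [score_model].
#' @param dataset a training corpus from [build_training_corpus()] (or any
#'   list with an `items` list of `slice`/`magnitude` pairs).
#' @param schedule a [diffusion_schedule()].
#' @param cfg a [train_config()].
#' @param seed integer seed.
#' @return Scalar loss.
#' @export
dsm_loss <- function(model, dataset, schedule, cfg, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  batch <- draw_batch(dataset, schedule, cfg)
  dsm_lossgrad(model, batch, want_grad = FALSE)$loss
}

#' Train a score model by denoising score matching
#'
#' Stochastic-gradient (Adam) minimization of the DSM objective over the
#' corpus.  The run is seeded end-to-end: weight initialization, batch
#' sampling, step levels, noise draws and condition dropout all derive from
#' `cfg$seed`.  Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param dataset corpus from [build_training_corpus()].
#' @param schedule a [diffusion_schedule()].
#' @param cfg a [train_config()].
#' @param model optional pre-built [score_model]; by default a small U-Net
#'   sized for the corpus slices.
#' @param arch architecture when `model` is `NULL`: `"unet"` (default) or
#'   the plain convolutional stack `"cnn"`.
#' @param hidden base channel width (U-Net) or hidden width (CNN).
#' @param depth layer count for the CNN backend.
#' @param checkpoint optional path; the trained model is saved there.
#' @return The trained `score_model`, with `loss_curve` (per-iteration
#'   losses), `schedule`, and `train_cfg` fields attached.
#' @export
train_score_model <- function(dataset, schedule, cfg, model = NULL,
                              arch = c("unet", "cnn"), hidden = 12L,
                              depth = 4L, checkpoint = NULL) {
  stopifnot(length(dataset$items) >= 1L)
  if (is.null(model)) {
    arch <- match.arg(arch)
    sr <- c(schedule$sigma_min, schedule$sigma_max)
    model <- if (arch == "unet") {
      score_model_unet(width = hidden, sigma_range = sr, seed = cfg$seed)
    } else {
      score_model_cnn(hidden = hidden, depth = depth, sigma_range = sr,
                      seed = cfg$seed)
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  state <- adam_init(model$params)
  ema <- model$params
  dec <- cfg$ema_decay
  losses <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    batch <- draw_batch(dataset, schedule, cfg)
    lg <- dsm_lossgrad(model, batch, want_grad = TRUE)
    if (!is.finite(lg$loss)) {
      stop(sprintf("training diverged: non-finite loss at iteration %d", it))
    }
    losses[it] <- lg$loss
    upd <- adam_step(model$params, lg$grads, state, cfg$learning_rate)
    model$params <- upd$params
    state <- upd$state
    if (dec > 0) {
      for (l in seq_along(ema)) for (nm in names(ema[[l]])) {
        ema[[l]][[nm]] <- dec * ema[[l]][[nm]] + (1 - dec) * model$params[[l]][[nm]]
      }
    }
  }
  if (dec > 0) model$params <- ema
  model$loss_curve <- losses
  model$schedule <- schedule
  model$train_cfg <- cfg
  if (!is.null(checkpoint)) save_score_model(model, checkpoint)
  model
}

#' One predictor-corrector reverse step
#'
#' The reverse-diffusion "Solve" step at level i: the predictor applies the
#' discretized reverse SDE
#' `x <- x + (sigma_i^2 - sigma_(i-1)^2) * s_theta(x, sigma_i, H)
#'  + sqrt(sigma_i^2 - sigma_(i-1)^2) * z`,
#' followed by `corrector_steps` annealed-Langevin corrections at the new
#' level with step size `eps = 2 * (snr * ||z|| / ||s||)^2`.  With
#' `corrector_steps = 0` this is the plain reverse-diffusion sampler.
#' Deterministic given the RNG state (or `seed`).
#'
#' @param model a [score_model].
#' @param x_t current state (matrix) at level i.
#' @param schedule a [diffusion_schedule()].
#' @param i step index in `1..N`.
#' @param condition optional condition (see [score_eval()]).
#' @param corrector_steps number of Langevin corrector steps (default 1).
#' @param snr signal-to-noise ratio of the corrector (default 0.16).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return The state at level i - 1.
#' @export
pc_sample_step <- function(model, x_t, schedule, i, condition = NULL,
                           corrector_steps = 1L, snr = 0.16, seed = NULL) {
  stopifnot(inherits(schedule, "diffusion_schedule"))
  if (i < 1 || i > schedule$num_steps) stop("i must be in 1..N")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  s_i <- sigma_at(schedule, i)
  s_im1 <- sigma_at(schedule, i - 1L)
  dv <- s_i^2 - s_im1^2
  s <- score_eval(model, x_t, s_i, condition)
  z <- matrix(rnorm(length(x_t)), nrow = nrow(x_t))
  x <- x_t + dv * s + sqrt(dv) * z
  if (!all(is.finite(x))) stop("non-finite state in predictor step")
  if (corrector_steps > 0L) {
    s_corr <- max(s_im1, schedule$sigma_min)
    for (k in seq_len(corrector_steps)) {
      g <- score_eval(model, x, s_corr, condition)
      z <- matrix(rnorm(length(x)), nrow = nrow(x))
      gn <- sqrt(sum(g * g))
      if (gn <= 0) next
      eps <- 2 * (snr * sqrt(sum(z * z)) / gn)^2
      x <- x + eps * g + sqrt(2 * eps) * z
      if (!all(is.finite(x))) stop("non-finite state in corrector step")
    }
  }
  x
}
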