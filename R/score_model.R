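#' Score-model backends
#'
#' A score model maps a noisy image `x`, a noise level `sigma`, and an
#' optional high-frequency condition map `H` to an estimate of the score
#' `grad_x log p(x; sigma)`, with the same shape as `x`.  Three backends
#' share this contract:
#'
#' * `score_model_cnn()` - a small shape-preserving convolutional network
#'   (3x3 kernels, ReLU, zero padding) with the condition injected by channel
#'   concatenation and the noise level by a normalized log-sigma channel.
#'   The network predicts the scaled residual `sigma * score`, so its output
#'   is divided by `sigma`; the noisy input channel is whitened by
#'   `1/sqrt(1 + sigma^2)` to keep activations bounded across noise decades.
#' * `score_model_mlp()` - a one-hidden-layer tanh network on flattened
#'   inputs, for low-dimensional analytic oracles (e.g. two-pixel Gaussian
#'   toys); it ignores the condition.
#' * `score_model_fn()` - wraps an analytic score function, used as an exact
#'   oracle in sampler tests.
#'
#' All evaluations are deterministic given fixed parameters and inputs.
#'
#' @param hidden hidden channel width (CNN) or hidden unit count (MLP).
#' @param depth number of convolution layers including the output layer
#'   (CNN); receptive field is `2 * depth + 1` pixels.
#' @param sigma_range `c(sigma_min, sigma_max)` used to normalize the noise
#'   channel.
#' @param seed integer seed for weight initialization.
#' @return An object of class `score_model`.
#' @name score_model
NULL

#' @rdname score_model
#' @export
score_model_cnn <- function(hidden = 12L, depth = 4L, sigma_range = c(0.01, 10),
                            seed = 1L) {
  if (depth < 2L) stop("depth must be >= 2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  chans <- c(3L, rep(as.integer(hidden), depth - 1L), 1L)
  params <- vector("list", depth)
  for (l in seq_len(depth)) {
    cin <- chans[l]; cout <- chans[l + 1L]
    W <- matrix(rnorm(cout * cin * 9L, sd = sqrt(2 / (cin * 9L))),
                nrow = cout, ncol = cin * 9L)
    if (l == depth) W[] <- 0  # zero-initialized head: initial score is 0
    params[[l]] <- list(W = W, b = numeric(cout))
  }
  structure(
    list(kind = "cnn", hidden = as.integer(hidden), depth = as.integer(depth),
         chans = chans, sigma_range = as.numeric(sigma_range),
         conditioning_mode = "channel_concat", params = params),
    class = "score_model"
  )
}

#' @rdname score_model
#' @param width base channel width F of the U-Net backend; the encoder runs
#'   F / 2F / 2F channels over two 2x mean-pool downsamplings, and the
#'   decoder mirrors it with skip concatenations, so the receptive field
#'   spans several organ diameters at 64 x 64.
#' @export
score_model_unet <- function(width = 12L, sigma_range = c(0.01, 10), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  f <- as.integer(width)
  shapes <- list(
    enc0 = c(f, 3L), enc1 = c(2L * f, f), mid1 = c(2L * f, 2L * f),
    mid2 = c(2L * f, 2L * f), dec1 = c(f, 4L * f), dec0 = c(f, 2L * f),
    head = c(1L, f)
  )
  params <- lapply(names(shapes), function(nm) {
    cout <- shapes[[nm]][1]; cin <- shapes[[nm]][2]
    W <- matrix(rnorm(cout * cin * 9L, sd = sqrt(2 / (cin * 9L))),
                nrow = cout, ncol = cin * 9L)
    if (nm == "head") W[] <- 0
    list(W = W, b = numeric(cout))
  })
  structure(
    list(kind = "unet", width = f, sigma_range = as.numeric(sigma_range),
         conditioning_mode = "channel_concat", params = params),
    class = "score_model"
  )
}

#' @rdname score_model
#' @param input_dim flattened input length for the MLP backend.
#' @export
score_model_mlp <- function(input_dim, hidden = 64L, sigma_range = c(0.01, 10),
                            seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  d_in <- input_dim + 1L  # + sigma feature
  params <- list(
    list(W = matrix(rnorm(hidden * d_in, sd = 1 / sqrt(d_in)), nrow = hidden),
         b = numeric(hidden)),
    list(W = matrix(0, nrow = input_dim, ncol = hidden),
         b = numeric(input_dim))
  )
  structure(
    list(kind = "mlp", input_dim = as.integer(input_dim),
         hidden = as.integer(hidden), sigma_range = as.numeric(sigma_range),
         params = params),
    class = "score_model"
  )
}

#' @rdname score_model
#' @param fn function `(x, sigma, cond_map) -> score matrix`.
#' @export
score_model_fn <- function(fn, sigma_range = c(0.01, 10)) {
  stopifnot(is.function(fn))
  structure(list(kind = "fn", fn = fn, sigma_range = as.numeric(sigma_range)),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  nparam <- function(p) sum(vapply(p, function(e) length(e$W) + length(e$b),
                                   numeric(1)))
  desc <- switch(x$kind,
    cnn = sprintf("cnn (hidden %d, depth %d, %d params)", x$hidden, x$depth,
                  nparam(x$params)),
    unet = sprintf("unet (width %d, %d params)", x$width, nparam(x$params)),
    mlp = sprintf("mlp (%d -> %d -> %d)", x$input_dim, x$hidden, x$input_dim),
    fn = "analytic function")
  cat(sprintf("<score_model> %s | sigma in [%g, %g]\n", desc,
              x$sigma_range[1], x$sigma_range[2]))
  invisible(x)
}

sigma_feature <- function(model, sigma) {
  sr <- model$sigma_range
  log(sigma / sr[1]) / log(sr[2] / sr[1])
}

cond_map_of <- function(cond, shape) {
  if (is.null(cond)) return(matrix(-1, nrow = shape[1], ncol = shape[2]))
  if (inherits(cond, "highfreq_condition")) return(cond$map)
  if (is.matrix(cond)) return(cond)
  stop("condition must be NULL, a matrix, or a highfreq_condition")
}

# variance-preserving preconditioning coefficients: the network regresses a
# unit-variance residual F at every noise level, and the denoised estimate is
# D = c_skip * x + c_out * F(c_in * x, ...); the score is (D - x) / sigma^2
cnn_coefs <- function(sigma, sigma_data = 0.3) {
  s2 <- sigma^2 + sigma_data^2
  list(c_in = 1 / sqrt(s2),
       c_skip = sigma_data^2 / s2,
       c_out = sigma * sigma_data / sqrt(s2))
}

# assemble the (H, W, 3) input stack for the CNN backend
cnn_input <- function(model, x, sigma, cond) {
  h <- nrow(x); w <- ncol(x)
  co <- cnn_coefs(sigma)
  inp <- array(0, dim = c(h, w, 3L))
  inp[, , 1] <- x * co$c_in
  inp[, , 2] <- cond_map_of(cond, c(h, w))
  inp[, , 3] <- sigma_feature(model, sigma)
  inp
}

# forward pass keeping the per-layer caches needed for backprop
cnn_forward <- function(model, inp) {
  L <- model$depth
  acts <- vector("list", L)   # input to each layer
  masks <- vector("list", L)  # ReLU masks of hidden layers
  a <- inp
  for (l in seq_len(L)) {
    acts[[l]] <- a
    z <- cpp_conv3_fwd(a, dim(a), model$params[[l]]$W, model$params[[l]]$b)
    if (l < L) {
      masks[[l]] <- z > 0
      a <- z * masks[[l]]
    } else {
      a <- z
    }
  }
  list(raw = matrix(a, nrow = dim(inp)[1]), acts = acts, masks = masks)
}

# backprop of dL/draw through the conv stack; accumulates into grads
cnn_backward <- function(model, cache, draw, grads) {
  L <- model$depth
  delta <- array(draw, dim = c(nrow(draw), ncol(draw), 1L))
  for (l in rev(seq_len(L))) {
    a <- cache$acts[[l]]
    cpp_conv3_bwd_weights(a, dim(a), delta, nrow(model$params[[l]]$W),
                          grads[[l]]$W, grads[[l]]$b)
    if (l > 1L) {
      delta <- cpp_conv3_bwd_input(delta, dim(delta), model$params[[l]]$W,
                                   dim(a)[3])
      delta <- delta * cache$masks[[l - 1L]]
    }
  }
  grads
}

# 2x2 mean pooling and nearest-neighbour upsampling with their adjoints
pool2 <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], by = 2L); co <- seq(1L, d[2], by = 2L)
  (x[ro, co, , drop = FALSE] + x[ro + 1L, co, , drop = FALSE] +
     x[ro, co + 1L, , drop = FALSE] + x[ro + 1L, co + 1L, , drop = FALSE]) / 4
}
unpool2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}
pool2_bwd <- function(delta_small) unpool2(delta_small) / 4
unpool2_bwd <- function(delta_big) pool2(delta_big) * 4

conv_relu <- function(a, p) {
  z <- cpp_conv3_fwd(a, dim(a), p$W, p$b)
  mask <- z > 0
  list(a = z * mask, mask = mask)
}

# U-Net forward keeping every cache needed for backprop
unet_forward <- function(model, inp) {
  d <- dim(inp)
  if (any(d[1:2] %% 4L != 0L)) {
    stop("U-Net backend needs slice sides divisible by 4")
  }
  p <- model$params
  e0 <- conv_relu(inp, p[[1]])
  p1 <- pool2(e0$a)
  e1 <- conv_relu(p1, p[[2]])
  p2 <- pool2(e1$a)
  m1 <- conv_relu(p2, p[[3]])
  m2 <- conv_relu(m1$a, p[[4]])
  u1 <- unpool2(m2$a)
  c1 <- array(c(u1, e1$a), dim = c(dim(u1)[1:2], dim(u1)[3] + dim(e1$a)[3]))
  d1 <- conv_relu(c1, p[[5]])
  u0 <- unpool2(d1$a)
  c0 <- array(c(u0, e0$a), dim = c(dim(u0)[1:2], dim(u0)[3] + dim(e0$a)[3]))
  d0 <- conv_relu(c0, p[[6]])
  raw <- cpp_conv3_fwd(d0$a, dim(d0$a), p[[7]]$W, p[[7]]$b)
  list(raw = matrix(raw, nrow = d[1]),
       inp = inp, e0 = e0, p1 = p1, e1 = e1, p2 = p2, m1 = m1, m2 = m2,
       c1 = c1, d1 = d1, c0 = c0, d0 = d0)
}

unet_backward <- function(model, cache, draw, grads) {
  p <- model$params
  f <- model$width
  bwd_conv <- function(idx, a_in, delta) {
    cpp_conv3_bwd_weights(a_in, dim(a_in), delta, nrow(p[[idx]]$W),
                          grads[[idx]]$W, grads[[idx]]$b)
    cpp_conv3_bwd_input(delta, dim(delta), p[[idx]]$W, dim(a_in)[3])
  }
  delta <- array(draw, dim = c(nrow(draw), ncol(draw), 1L))
  g_d0 <- bwd_conv(7L, cache$d0$a, delta) * cache$d0$mask
  g_c0 <- bwd_conv(6L, cache$c0, g_d0)
  g_u0 <- g_c0[, , seq_len(f), drop = FALSE]
  g_e0_skip <- g_c0[, , f + seq_len(f), drop = FALSE]
  g_d1 <- unpool2_bwd(g_u0) * cache$d1$mask
  g_c1 <- bwd_conv(5L, cache$c1, g_d1)
  g_u1 <- g_c1[, , seq_len(2L * f), drop = FALSE]
  g_e1_skip <- g_c1[, , 2L * f + seq_len(2L * f), drop = FALSE]
  g_m2 <- unpool2_bwd(g_u1) * cache$m2$mask
  g_m1 <- bwd_conv(4L, cache$m1$a, g_m2) * cache$m1$mask
  g_p2 <- bwd_conv(3L, cache$p2, g_m1)
  g_e1 <- (pool2_bwd(g_p2) + g_e1_skip) * cache$e1$mask
  g_p1 <- bwd_conv(2L, cache$p1, g_e1)
  g_e0 <- (pool2_bwd(g_p1) + g_e0_skip) * cache$e0$mask
  invisible(bwd_conv(1L, cache$inp, g_e0))
  grads
}

mlp_input <- function(model, x, sigma) {
  c(as.numeric(x) / sqrt(1 + sigma^2), sigma_feature(model, sigma))
}

#' Evaluate a score model
#'
#' @param model a [score_model].
#' @param x noisy image (matrix).
#' @param sigma positive noise level.
#' @param cond optional condition: a [threshold_highfreq()] /
#'   [null_condition()] object or a raw matrix; `NULL` means the null (-1)
#'   condition.
#' @return Score estimate, same shape as `x`.
#' @export
score_eval <- function(model, x, sigma, cond = NULL) {
  stopifnot(inherits(model, "score_model"), sigma > 0)
  switch(model$kind,
    fn = model$fn(x, sigma, cond_map_of(cond, dim(x))),
    cnn = ,
    unet = {
      fwd <- if (model$kind == "cnn") cnn_forward else unet_forward
      fw <- fwd(model, cnn_input(model, x, sigma, cond))
      co <- cnn_coefs(sigma)
      D <- co$c_skip * x + co$c_out * fw$raw
      (D - x) / sigma^2
    },
    mlp = {
      p <- model$params
      h <- tanh(p[[1]]$W %*% mlp_input(model, x, sigma) + p[[1]]$b)
      raw <- as.numeric(p[[2]]$W %*% h + p[[2]]$b)
      matrix(raw / sigma, nrow = nrow(x), ncol = ncol(x))
    }
  )
}

zero_like_params <- function(params) {
  lapply(params, function(p) lapply(p, function(v) { v[] <- 0; v }))
}

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      g <- grads[[l]][[nm]]
      state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[nm]] / bc1
      vhat <- state$v[[l]][[nm]] / bc2
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Save / load a trained score model
#'
#' Checkpoints are self-describing: the serialized object carries the
#' architecture, the noise-level range, parameters, and (after training) the
#' schedule, training configuration, and loss curve.
#'
#' @param model a [score_model].
#' @param path file path (`.rds`).
#' @return `save_score_model` returns `path` invisibly; `load_score_model`
#'   the model.
#' @export
save_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_score_model
#' @export
load_score_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "score_model"))
  model
}
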