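#' Reconstruction quality metrics
#'
#' PSNR is `10 * log10(MAX^2 / MSE)` with `MAX` the data range of the
#' normalization window (1 for windowed-HU volumes); identical volumes are
#' reported as the capped sentinel 100 dB.  SSIM uses the standard constants
#' (`K1 = 0.01`, `K2 = 0.03`, 11x11 Gaussian window with sd 1.5) computed
#' per axial slice and averaged; it is symmetric in its arguments.
#'
#' @param x,reference [image_volume()]s of identical shape and normalization
#'   window.
#' @return `evaluate_reconstruction` returns `list(psnr, ssim)`.
#' @export
evaluate_reconstruction <- function(x, reference) {
  stopifnot(inherits(x, "image_volume"), inherits(reference, "image_volume"))
  if (!all(dim(x$voxels) == dim(reference$voxels))) stop("shape mismatch")
  list(psnr = psnr(x$voxels, reference$voxels, data_range = 1),
       ssim = ssim(x$voxels, reference$voxels, data_range = 1))
}

#' @rdname evaluate_reconstruction
#' @param a,b numeric arrays of identical shape.
#' @param data_range dynamic range MAX of the data.
#' @param cap sentinel value reported when the arrays are identical.
#' @export
psnr <- function(a, b, data_range = 1, cap = 100) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(10 * log10(data_range^2 / mse), cap)
}

#' @rdname evaluate_reconstruction
#' @export
ssim <- function(a, b, data_range = 1) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (is.matrix(a)) { a <- array(a, dim = c(dim(a), 1)); b <- array(b, dim = c(dim(b), 1)) }
  vals <- vapply(seq_len(dim(a)[3]),
                 function(k) ssim_slice(a[, , k], b[, , k], data_range),
                 numeric(1))
  mean(vals)
}

ssim_slice <- function(a, b, data_range) {
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  g <- gaussian_kernel(11L, 1.5)
  mu_a <- cpp_conv2_same(a, g, 1L)
  mu_b <- cpp_conv2_same(b, g, 1L)
  sa <- cpp_conv2_same(a * a, g, 1L) - mu_a^2
  sb <- cpp_conv2_same(b * b, g, 1L) - mu_b^2
  sab <- cpp_conv2_same(a * b, g, 1L) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * sab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (sa + sb + C2)
  mean(num / den)
}

gaussian_kernel <- function(size, sd) {
  r <- (size - 1) / 2
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sd^2))
  k2 <- outer(k, k)
  k2 / sum(k2)
}
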