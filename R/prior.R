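#' Sobel gradient magnitude of an axial slice
#'
#' Correlates the slice with the standard 3x3 Sobel kernels
#' `Kx = [[-1,0,1],[-2,0,2],[-1,0,1]]` (and its transpose for `Ky`) under
#' reflective boundary handling, and returns `sqrt(Gx^2 + Gy^2)`.  A constant
#' slice maps to all zeros; a unit step across columns produces magnitude 4
#' on the two interior columns adjacent to the edge.
#'
#' @param slice numeric matrix (one axial slice).
#' @return Matrix of gradient magnitudes, same shape.
#' @export
sobel_magnitude <- function(slice) {
  if (!is.matrix(slice) || !all(is.finite(slice))) {
    stop("slice must be a finite numeric matrix")
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), nrow = 3)  # columns -1,0,1
  ky <- t(kx)
  gx <- cpp_conv2_same(slice, kx, 1L)
  gy <- cpp_conv2_same(slice, ky, 1L)
  sqrt(gx^2 + gy^2)
}

#' High-frequency condition map
#'
#' The thresholded Sobel magnitude that conditions the score model: values of
#' `magnitude` at or above `eta` are kept, all others set to zero.  The
#' number of surviving pixels is non-increasing in `eta`, and thresholding an
#' already-thresholded map at the same `eta` is the identity.
#'
#' @param magnitude numeric matrix of Sobel magnitudes (`i_mag`).
#' @param eta non-negative threshold.
#' @return An object of class `highfreq_condition` with fields `magnitude`,
#'   `threshold`, `map`, `nonzero` (kept-pixel count) and `null_flag`.
#' @export
threshold_highfreq <- function(magnitude, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) || eta < 0) {
    stop("eta must be a non-negative scalar")
  }
  if (!is.matrix(magnitude)) stop("magnitude must be a matrix")
  map <- ifelse(magnitude >= eta, magnitude, 0)
  structure(
    list(magnitude = magnitude, threshold = eta, map = map,
         nonzero = sum(map != 0), null_flag = FALSE),
    class = "highfreq_condition"
  )
}

#' Null (dropped) condition
#'
#' The conditioning input used when the prior is withheld: a constant -1 map
#' of the requested shape, matching the null tensors the model sees during
#' condition-dropout training.
#'
#' @param shape integer vector `c(rows, cols)`.
#' @return A `highfreq_condition` with `null_flag = TRUE`.
#' @export
null_condition <- function(shape) {
  map <- matrix(-1, nrow = shape[1], ncol = shape[2])
  structure(
    list(magnitude = NULL, threshold = Inf, map = map, nonzero = 0L,
         null_flag = TRUE),
    class = "highfreq_condition"
  )
}

#' @export
print.highfreq_condition <- function(x, ...) {
  if (x$null_flag) {
    cat(sprintf("<highfreq_condition> null (-1) map %d x %d\n",
                nrow(x$map), ncol(x$map)))
  } else {
    cat(sprintf("<highfreq_condition> eta = %.4g | %d nonzero of %d\n",
                x$threshold, x$nonzero, length(x$map)))
  }
  invisible(x)
}

#' Decaying-threshold schedule (variant B)
#'
#' Governs how the high-pass threshold grows as the reverse process advances
#' (t descending from `steps` to 1), progressively emptying the condition
#' map.  Three multiplier rules are built in:
#' \describe{
#'   \item{`"geometric_span"`}{(default) a geometric ladder from `eta_start`
#'     to `eta_max` that reaches `eta_max` exactly at the final reverse step,
#'     so the last steps run unconditioned.}
#'   \item{`"reciprocal"`}{the literal per-step rule
#'     `eta_(t-1) = t/(t-1) * eta_t`, which telescopes to
#'     `eta_m = (T/m) * eta_T` and diverges at t = 1 (empty condition).}
#'   \item{`"constant_k"`}{`eta_(t-1) = k * eta_t` with a fixed factor `k`.}
#' }
#'
#' @param eta_start threshold at the first reverse step (t = `steps`); the
#'   default used by the pipeline is the 10th percentile of the nonzero Sobel
#'   magnitude, which keeps nearly all edges initially.
#' @param steps total reverse-diffusion steps T.
#' @param rule multiplier rule, see above.
#' @param k factor for `"constant_k"`.
#' @param eta_max ceiling for `"geometric_span"` (typically `max(i_mag)`).
#' @return An object of class `threshold_schedule`.
#' @export
threshold_schedule <- function(eta_start, steps,
                               rule = c("geometric_span", "reciprocal", "constant_k"),
                               k = 1.05, eta_max = NULL) {
  rule <- match.arg(rule)
  if (eta_start < 0) stop("eta_start must be non-negative")
  if (steps < 1L) stop("steps must be >= 1")
  if (rule == "geometric_span" && (is.null(eta_max) || eta_max <= 0)) {
    stop("geometric_span rule needs a positive eta_max")
  }
  if (rule == "constant_k" && k < 1) stop("k must be >= 1 (threshold grows)")
  structure(
    list(eta_start = eta_start, steps = as.integer(steps), rule = rule,
         k = k, eta_max = eta_max),
    class = "threshold_schedule"
  )
}

#' Threshold for a given reverse step
#'
#' Returns the high-pass threshold `eta_t` to use at reverse step `t`
#' (t = `steps` is the first, noisiest step; t = 1 the last).  Thresholds are
#' non-decreasing as t descends.  Under the literal `"reciprocal"` rule the
#' value at t is `eta_start * steps / t`, which is `+Inf` at t <= 0; for
#' `"geometric_span"` the ladder spans `[eta_start, eta_max]`
#' geometrically.
#'
#' @param schedule a [threshold_schedule()].
#' @param t reverse step index, `1 <= t <= steps` (values below 1 map to an
#'   infinite threshold, i.e. an empty condition).
#' @return Scalar threshold.
#' @export
schedule_threshold <- function(schedule, t) {
  stopifnot(inherits(schedule, "threshold_schedule"))
  T <- schedule$steps
  if (t > T) stop("t must not exceed the schedule's step count")
  if (t < 1) return(Inf)
  switch(schedule$rule,
    reciprocal = schedule$eta_start * T / t,
    constant_k = schedule$eta_start * schedule$k^(T - t),
    geometric_span = {
      if (T == 1L) return(schedule$eta_max)
      lo <- max(schedule$eta_start, 1e-12)
      lo * (schedule$eta_max / lo)^((T - t) / (T - 1))
    }
  )
}

#' One-step threshold update
#'
#' Maps the threshold at reverse step `t` to the threshold at step `t - 1`
#' under the schedule's multiplier rule; the per-step form of
#' [schedule_threshold()].  Under the literal `"reciprocal"` rule this is
#' `eta_(t-1) = t/(t-1) * eta_t`, which is `+Inf` at `t <= 1` (the condition
#' map empties).
#'
#' @param schedule a [threshold_schedule()].
#' @param eta_t threshold at step t.
#' @param t current reverse step.
#' @return Threshold at step `t - 1`.
#' @export
step_threshold <- function(schedule, eta_t, t) {
  stopifnot(inherits(schedule, "threshold_schedule"))
  switch(schedule$rule,
    reciprocal = if (t <= 1) Inf else eta_t * t / (t - 1),
    constant_k = eta_t * schedule$k,
    geometric_span = {
      T <- schedule$steps
      if (T == 1L) return(schedule$eta_max)
      lo <- max(schedule$eta_start, 1e-12)
      eta_t * (schedule$eta_max / lo)^(1 / (T - 1))
    }
  )
}

#' Default starting threshold from a magnitude map
#'
#' The 10th percentile of the nonzero Sobel magnitudes: keeps nearly all
#' edges at the start of the reverse process.
#'
#' @param magnitude Sobel magnitude matrix (or stack).
#' @return Scalar threshold.
#' @export
default_eta_start <- function(magnitude) {
  nz <- magnitude[magnitude > 0]
  if (length(nz) == 0) return(0)
  as.numeric(quantile(nz, 0.10))
}
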