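# shared oracle helpers: built from first principles, independent of the
# implementation paths they check

# supersampled rasterization of a centred disk (partial pixel coverage)
raster_disk <- function(n, radius, sup = 4L) {
  xs <- seq_len(n) - (n + 1) / 2
  off <- (seq_len(sup) - (sup + 1) / 2) / sup
  img <- matrix(0, n, n)
  for (dr in off) {
    for (dc in off) {
      X <- outer(rep(1, n), xs + dc)
      Y <- outer(xs + dr, rep(1, n))
      img <- img + (X^2 + Y^2 <= radius^2) / sup^2
    }
  }
  img
}

# binary disk from pixel-centre membership (exact voxel counts)
binary_disk <- function(n, radius, cx = 0, cy = 0) {
  xs <- seq_len(n) - (n + 1) / 2
  X <- outer(rep(1, n), xs)
  Y <- outer(xs, rep(1, n))
  (X - cx)^2 + (Y - cy)^2 <= radius^2
}

# small default-scale geometry helpers used across tests
test_geometry <- function(angles, ndet = 64L, pitch = 6.2,
                          mode = "fan_per_slice") {
  scan_geometry(angles, detector_pixels = ndet, detector_pitch = pitch,
                beam_mode = mode)
}

clip01 <- function(vol) {
  vol$voxels <- pmin(pmax(vol$voxels, 0), 1)
  vol
}
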