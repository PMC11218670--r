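#' Cone-beam acquisition geometry
#'
#' Describes the measurement operator's parameters for a circular-trajectory
#' acquisition, reduced to an independent divergent (fan-beam) or parallel-beam
#' problem per axial slice.  Distances are in millimetres; angles are view
#' angles in degrees, measured counter-clockwise from the +x axis, each in
#' \[0, 360).  The default numbers scale a clinical head geometry
#' (SAD 1000 mm, SDD 1500 mm, 256 detector pixels at 1.552 mm) down to desk
#' scale while keeping the magnification SDD/SAD = 1.5 and the detector
#' coverage of the field of view unchanged.
#'
#' @param angles numeric vector of view angles (degrees), strictly increasing
#'   within each arc.
#' @param detector_pixels number of detector elements per row.
#' @param detector_pitch detector element spacing (mm).
#' @param source_to_isocenter source-to-axis distance SAD (mm).
#' @param source_to_detector source-to-detector distance SDD (mm).
#' @param beam_mode `"fan_per_slice"` (divergent, the default) or
#'   `"parallel_per_slice"` (used by analytic oracle tests).
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(make_limited_angle_set("ortho", 90))
#' g$angles[1:5]
#' @export
scan_geometry <- function(angles,
                          detector_pixels = 64L,
                          detector_pitch = 6.2,
                          source_to_isocenter = 1000,
                          source_to_detector = 1500,
                          beam_mode = c("fan_per_slice", "parallel_per_slice")) {
  beam_mode <- match.arg(beam_mode)
  angles <- as.numeric(angles)
  if (length(angles) < 1L || anyNA(angles)) stop("angles must be a non-empty numeric vector")
  if (any(angles < 0 | angles >= 360)) stop("every angle must lie in [0, 360)")
  if (!(source_to_detector > source_to_isocenter && source_to_isocenter > 0)) {
    stop("require source_to_detector > source_to_isocenter > 0")
  }
  if (detector_pitch <= 0) stop("detector_pitch must be positive")
  # strictly increasing within each arc (an arc break is a downward jump)
  d <- diff(angles)
  if (any(d == 0) || any(d < 0 & abs(d) < 1e-9)) stop("angles must be strictly increasing within each arc")
  structure(
    list(
      source_to_isocenter = as.numeric(source_to_isocenter),
      source_to_detector = as.numeric(source_to_detector),
      detector_pixels = as.integer(detector_pixels),
      detector_pitch = as.numeric(detector_pitch),
      angles = angles,
      beam_mode = beam_mode
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %s | %d views in [%g, %g] deg | %d det px @ %g mm | SAD %g / SDD %g mm\n",
    x$beam_mode, length(x$angles), min(x$angles), max(x$angles),
    x$detector_pixels, x$detector_pitch,
    x$source_to_isocenter, x$source_to_detector
  ))
  invisible(x)
}

#' Limited-angle view sets
#'
#' Builds the view-angle list for a limited-angle scan.  `"single"` covers one
#' contiguous arc starting at 0 degrees; `"ortho"` splits the total angle
#' equally between two arcs starting at 0 and 90 degrees, the orthogonal-view
#' layout with better sampling efficiency at equal total angle.  For a total
#' angle of 30 degrees the orthogonal layout is \[0, 15\] and \[90, 105\].
#'
#' @param mode `"single"` or `"ortho"`.
#' @param total_angle total covered angle in degrees, in (0, 360\].
#' @param sampling_density views per degree (default 1).
#' @return Numeric vector of view angles in degrees (endpoints included).
#' @examples
#' make_limited_angle_set("ortho", 30)
#' @export
make_limited_angle_set <- function(mode = c("single", "ortho"),
                                   total_angle, sampling_density = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(total_angle) || total_angle <= 0 || total_angle > 360) {
    stop("total_angle must lie in (0, 360]")
  }
  if (sampling_density <= 0) stop("sampling_density must be positive")
  step <- 1 / sampling_density
  if (mode == "single") {
    seq(0, total_angle, by = step)
  } else {
    half <- total_angle / 2
    c(seq(0, half, by = step), seq(90, 90 + half, by = step))
  }
}

#' Projection noise model
#'
#' Transmission-domain photon statistics: incident photons per detector pixel
#' follow a Poisson law, with additive zero-mean Gaussian electronic noise.
#' `attenuation_per_unit` converts the operator's line integrals (unit
#' normalized intensity x mm) into attenuation, using the water-like
#' 0.02 per mm at unit intensity.
#'
#' @param photons_per_pixel mean incident photon count I0 (e.g. 1e5 or 1e6).
#' @param electronic_variance variance of the additive electronic noise,
#'   in photon-count units (default 10).
#' @param attenuation_per_unit attenuation coefficient per unit normalized
#'   intensity (mm^-1); default 0.02.
#' @param enabled logical; when `FALSE` the sinogram passes through unchanged.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photons_per_pixel = 1e5, electronic_variance = 10,
                        attenuation_per_unit = 0.02, enabled = TRUE) {
  if (photons_per_pixel <= 0) stop("photons_per_pixel must be positive")
  if (electronic_variance < 0) stop("electronic_variance must be non-negative")
  if (attenuation_per_unit <= 0) stop("attenuation_per_unit must be positive")
  structure(
    list(
      photons_per_pixel = photons_per_pixel,
      electronic_variance = electronic_variance,
      attenuation_per_unit = attenuation_per_unit,
      enabled = isTRUE(enabled)
    ),
    class = "noise_model"
  )
}

#' Serialize / read a scan geometry as YAML
#'
#' @param geometry a [scan_geometry()].
#' @param path file path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry` returns
#'   a `scan_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "scan_geometry"))
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- yaml::read_yaml(path)
  scan_geometry(
    angles = unlist(g$angles),
    detector_pixels = g$detector_pixels,
    detector_pitch = g$detector_pitch,
    source_to_isocenter = g$source_to_isocenter,
    source_to_detector = g$source_to_detector,
    beam_mode = g$beam_mode
  )
}
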