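#' Detector geometry
#'
#' Flat detector normal to the incident beam.  Pixel coordinates are
#' 1-based `(slow, fast)` with pixel centers at integer coordinates; the
#' beam center may be fractional.  The laboratory frame has the beam along
#' +z, the detector fast axis along +x and the slow axis along +y, with the
#' detector plane at `z = distance` (mm).
#'
#' @param n_slow,n_fast raster dimensions in pixels.
#' @param pixel_size pixel edge in mm.
#' @param distance sample-to-detector distance in mm.
#' @param beam_center numeric(2) `(slow, fast)` in pixels (fractional allowed).
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(n_slow, n_fast, pixel_size, distance, beam_center) {
  stopifnot(n_slow >= 1, n_fast >= 1, pixel_size > 0, distance > 0,
            length(beam_center) == 2)
  if (beam_center[1] < 1 || beam_center[1] > n_slow ||
      beam_center[2] < 1 || beam_center[2] > n_fast)
    stop("beam_center (", beam_center[1], ", ", beam_center[2],
         ") must lie inside the raster")
  structure(list(n_slow = as.integer(n_slow), n_fast = as.integer(n_fast),
                 pixel_size = pixel_size, distance = distance,
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("detector: %d x %d px, %.4g mm/px, distance %.4g mm, beam (%.2f, %.2f) px\n",
              x$n_slow, x$n_fast, x$pixel_size, x$distance,
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Map detector pixels to reciprocal-space vectors
#'
#' Each pixel `(slow, fast)` defines a scattered-beam direction; assuming
#' the scatterer lies on the Ewald sphere, the reciprocal vector is
#' `q = s1 - s0` with `|s1| = |s0| = 1/lambda` and `s0` along +z.
#'
#' @param slow,fast pixel coordinates (vectors, fractional allowed).
#' @param geom `detector_geometry`.
#' @param wavelength X-ray wavelength in angstrom.
#' @return n x 3 matrix of reciprocal vectors (1/angstrom).
#' @export
pixel_to_q <- function(slow, fast, geom, wavelength) {
  x <- (fast - geom$beam_center[2]) * geom$pixel_size
  y <- (slow - geom$beam_center[1]) * geom$pixel_size
  L <- geom$distance
  nrm <- sqrt(x^2 + y^2 + L^2)
  s1 <- cbind(x, y, L) / (nrm * wavelength)
  s1[, 3] <- s1[, 3] - 1 / wavelength
  colnames(s1) <- c("qx", "qy", "qz")
  s1
}

#' Map reciprocal vectors to detector pixels
#'
#' Projects `s1 = q + s0` onto the detector plane.  Vectors scattering
#' backwards (`s1_z <= 0`) are returned as NA.
#'
#' @param q n x 3 matrix of reciprocal vectors (1/angstrom).
#' @param geom `detector_geometry`.
#' @param wavelength angstrom.
#' @return data.frame with columns `slow`, `fast` (pixels) and
#'   `on_detector` (logical).
#' @export
q_to_pixel <- function(q, geom, wavelength) {
  q <- matrix(q, ncol = 3)
  s1z <- q[, 3] + 1 / wavelength
  ok <- s1z > 1e-12
  L <- geom$distance
  x <- ifelse(ok, L * q[, 1] / s1z, NA_real_)
  y <- ifelse(ok, L * q[, 2] / s1z, NA_real_)
  slow <- geom$beam_center[1] + y / geom$pixel_size
  fast <- geom$beam_center[2] + x / geom$pixel_size
  on <- ok & slow >= 1 & slow <= geom$n_slow & fast >= 1 & fast <= geom$n_fast
  data.frame(slow = slow, fast = fast, on_detector = on & !is.na(slow))
}

#' Resolution of a detector position
#'
#' Bragg d-spacing of the scattering vector through a pixel:
#' `tan(2 theta) = r_mm / distance`, `d = lambda / (2 sin(theta))`.
#'
#' @param slow,fast pixel coordinates.
#' @param geom `detector_geometry`.
#' @param wavelength angstrom.
#' @return d-spacing in angstrom (Inf at the beam center).
#' @export
pixel_to_d <- function(slow, fast, geom, wavelength) {
  r_mm <- sqrt(((slow - geom$beam_center[1]) * geom$pixel_size)^2 +
               ((fast - geom$beam_center[2]) * geom$pixel_size)^2)
  tth <- atan2(r_mm, geom$distance)
  d <- wavelength / (2 * sin(tth / 2))
  d[r_mm == 0] <- Inf
  d
}
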