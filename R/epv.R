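#' Reciprocal-lattice spot width
#'
#' Full-width diameter of a reciprocal-lattice point under the two-parameter
#' mosaic model: the mosaic block size D sets a resolution-independent base
#' width (the diameter of the origin reflection is approximately 2/D), and
#' the mosaic rotational spread eta makes the width grow with distance from
#' the reciprocal origin (distance 1/d):
#'
#'   w(d) = 2/D + eta/d
#'
#' @param d resolution (d-spacing) in angstrom; vectorized.
#' @param D effective mosaic block size in angstrom.
#' @param eta effective full-width mosaic rotational spread in radians.
#' @return spot full width w in 1/angstrom.
#' @examples
#' spot_width(3.5, D = 500, eta = 0.002)
#' @export
spot_width <- function(d, D, eta) {
  if (any(d <= 0)) stop("resolution d must be positive")
  if (D <= 0) stop("mosaic block size D must be positive")
  if (eta < 0) stop("mosaic spread eta must be non-negative")
  2 / D + eta / d
}

#' Ewald proximal volume
#'
#' Volume of reciprocal space within which a reciprocal-lattice point
#' satisfies the diffraction condition, i.e. lies within half a spot width
#' w(d)/2 of the Ewald sphere, out to the outer resolution limit `d_L`.
#' In spherical coordinates about the Ewald sphere center (r = distance
#' from the center, tau = angle from the incident beam = 2 theta, kappa =
#' azimuth about the beam) the volume element is r^2 sin(tau) dr dtau
#' dkappa with limits r in \[1/lambda - w/2, 1/lambda + w/2\], tau in
#' \[0, 2 asin(lambda / (2 d_L))\] and kappa over the full circle.  The
#' kappa and r integrals have closed forms (a 2 pi factor and a difference
#' of cubes); the tau integral is evaluated by Gauss-Legendre quadrature,
#' with w taken at the resolution d = lambda / (2 sin(tau/2)) of each node.
#'
#' The EPV shrinks to zero as eta -> 0 and D -> infinity (a perfect
#' crystal intersects the sphere in a set of measure zero), grows with
#' eta, and shrinks with D.
#'
#' @param D mosaic block size, angstrom.
#' @param eta mosaic rotational spread, radians (full width).
#' @param lambda wavelength, angstrom.
#' @param d_L outer resolution limit, angstrom; must satisfy `d_L >= lambda/2`.
#' @param quadrature_points number of Gauss-Legendre nodes (default 128;
#'   at the default the result is converged to well below 1e-6 relative).
#' @return EPV in 1/angstrom^3.
#' @examples
#' compute_epv(D = 500, eta = 0.002, lambda = 1.3, d_L = 3.5)
#' @export
compute_epv <- function(D, eta, lambda, d_L, quadrature_points = 128L) {
  if (lambda <= 0) stop("wavelength must be positive")
  if (d_L < lambda / 2)
    stop("resolution unreachable: d_L = ", d_L, " < lambda/2 = ", lambda / 2)
  if (D <= 0) stop("mosaic block size D must be positive")
  if (eta < 0) stop("mosaic spread eta must be non-negative")
  if (quadrature_points < 16) stop("quadrature_points must be at least 16")
  tau_max <- 2 * asin(lambda / (2 * d_L))
  gl <- gauss_legendre_cached(as.integer(quadrature_points), tau_max)
  # w at the resolution hit by scattering angle tau; eta/d = eta*2*sin(tau/2)/lambda
  w <- 2 / D + eta * 2 * sin(gl$x / 2) / lambda
  r0 <- 1 / lambda
  shell <- ((r0 + w / 2)^3 - (r0 - w / 2)^3) / 3
  2 * pi * sum(gl$w * sin(gl$x) * shell)
}

# Gauss-Legendre nodes are reused heavily during mosaic scans; cache by
# (n, upper limit)
gauss_legendre_cached <- function(n, b) {
  key <- paste0("gl_", n, "_", signif(b, 12))
  hit <- .stillgrid_cache[[key]]
  if (is.null(hit)) {
    hit <- pracma::gaussLegendre(n, 0, b)
    .stillgrid_cache[[key]] <- hit
  }
  hit
}

#' Expected number of Bragg spots
#'
#' Number of reflections an ideal noise-free detector would record for one
#' still: the Ewald proximal volume times the primitive-setting unit-cell
#' volume (the reciprocal lattice carries one node per reciprocal-cell
#' volume 1/V_cell).
#'
#' @param epv Ewald proximal volume, 1/angstrom^3.
#' @param cell numeric(6) primitive unit cell.
#' @return expected spot count (real).
#' @export
expected_spot_count <- function(epv, cell) {
  if (epv < 0) stop("epv must be non-negative")
  epv * cell_volume(cell)
}
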