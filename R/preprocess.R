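#' Recenter the direct beam to the image center
#'
#' Downstream indexing assumes the direct-beam position coincides with the
#' geometric center of the raster.  The frame is recentered by symmetric
#' zero-padding (data pixels are never cropped): whole pixels are added
#' along the low or high edge of each axis until the beam center lies
#' within half a pixel of `((n_slow + 1)/2, (n_fast + 1)/2)` (1-based
#' coordinates).  Added pixels are zero-valued and masked, so they can
#' never contribute spots.  Original pixel values are preserved at shifted
#' coordinates; the operation is idempotent.
#'
#' @param frame an [image_frame()] with the beam center inside the raster.
#' @return a recentered `image_frame`.
#' @export
recenter_frame <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  g <- frame$geometry
  pads <- function(n, bc) {
    delta <- round(n + 1 - 2 * bc)    # pl - ph
    if (delta >= 0) c(delta, 0) else c(0, -delta)
  }
  ps <- pads(g$n_slow, g$beam_center[1])
  pf <- pads(g$n_fast, g$beam_center[2])
  if (all(c(ps, pf) == 0)) return(frame)
  ns <- g$n_slow + sum(ps); nf <- g$n_fast + sum(pf)
  raster <- matrix(0L, ns, nf)
  rows <- ps[1] + seq_len(g$n_slow); cols <- pf[1] + seq_len(g$n_fast)
  raster[rows, cols] <- frame$raster
  mask <- matrix(TRUE, ns, nf)
  mask[rows, cols] <- if (is.null(frame$mask)) FALSE else frame$mask
  geom <- detector_geometry(ns, nf, g$pixel_size, g$distance,
                            g$beam_center + c(ps[1], pf[1]))
  image_frame(raster, geom, frame$wavelength, mask = mask,
              source_id = frame$source_id)
}

#' Beam-stop shadow mask
#'
#' Circular disc of `radius_px` around the beam center plus a rectangular
#' arm of width `arm_width_px` running from the beam center to the detector
#' edge, flagged as excluded (TRUE).  Covers the shadow cast by a mounted
#' beam stop and its support arm.
#'
#' @param geometry a [detector_geometry()].
#' @param radius_px disc radius in pixels (>= 0; 0 with zero arm width
#'   gives an empty mask).
#' @param arm_width_px full width of the arm in pixels.
#' @param arm_direction which edge the arm runs to: `"up"` (decreasing
#'   slow), `"down"`, `"left"` (decreasing fast) or `"right"`.
#' @return logical matrix (slow x fast), TRUE = excluded.
#' @export
make_beamstop_mask <- function(geometry, radius_px, arm_width_px = 0,
                               arm_direction = c("down", "up", "left", "right")) {
  stopifnot(inherits(geometry, "detector_geometry"), radius_px >= 0,
            arm_width_px >= 0)
  arm_direction <- match.arg(arm_direction)
  bc <- geometry$beam_center
  s <- matrix(seq_len(geometry$n_slow), geometry$n_slow, geometry$n_fast)
  f <- matrix(seq_len(geometry$n_fast), geometry$n_slow, geometry$n_fast,
              byrow = TRUE)
  mask <- (s - bc[1])^2 + (f - bc[2])^2 <= radius_px^2
  if (arm_width_px > 0) {
    half <- arm_width_px / 2
    arm <- switch(arm_direction,
      up    = abs(f - bc[2]) <= half & s <= bc[1],
      down  = abs(f - bc[2]) <= half & s >= bc[1],
      left  = abs(s - bc[1]) <= half & f <= bc[2],
      right = abs(s - bc[1]) <= half & f >= bc[2])
    mask <- mask | arm
  }
  mask
}

#' Triage a frame by candidate Bragg-spot count
#'
#' Cheap pre-screen that discards blank or poorly diffracting images: the
#' spot finder is run once at the supplied parameters and the frame is kept
#' iff at least `min_spots` candidate spots are found.  `min_spots = 0`
#' bypasses triage (every frame kept).
#'
#' @param frame an [image_frame()].
#' @param spot_params numeric(2) `(min_height, min_area)` for the spot
#'   finder; defaults to the grid-search median point used elsewhere.
#' @param min_spots minimum candidate Bragg spots to keep the frame
#'   (default 10).
#' @param background optional precomputed [estimate_background()] result.
#' @return object of class `triage_decision`: list with `keep`,
#'   `n_bragg_candidates`, `reason`.
#' @export
triage_frame <- function(frame, spot_params = c(4, 5), min_spots = 10,
                         background = NULL) {
  stopifnot(min_spots >= 0, length(spot_params) == 2)
  spots <- find_spots(frame, spot_find_params(spot_params[1], spot_params[2]),
                      background = background)
  n <- nrow(spots)
  keep <- n >= min_spots
  structure(list(keep = keep, n_bragg_candidates = n,
                 reason = if (keep) sprintf("%d candidate spots >= %d", n, min_spots)
                          else sprintf("only %d candidate spots < %d", n, min_spots)),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("triage: %s (%s)\n", if (x$keep) "keep" else "discard", x$reason))
  invisible(x)
}
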