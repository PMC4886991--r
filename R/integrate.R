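#' Predict observable reflections for a lattice model
#'
#' Enumerates Miller indices with d-spacing at least `d_L` whose
#' reciprocal-lattice node lies within half a mosaic spot width w(d)/2 of
#' the Ewald sphere ([spot_width()] with the model's D and eta), i.e. the
#' nodes inside the Ewald proximal volume, and projects them onto the
#' detector.
#'
#' @param model a `lattice_model` with mosaic parameters set.
#' @param geom detector geometry (the model's refined beam center is used).
#' @param wavelength angstrom.
#' @param d_L outer resolution limit, angstrom.
#' @return data.frame: `h, k, l, d, delta_r, slow, fast, on_detector`.
#' @export
predict_reflections <- function(model, geom, wavelength, d_L) {
  stopifnot(inherits(model, "lattice_model"))
  if (is.na(model$mosaic_block_size_D) || is.na(model$mosaic_angle_eta))
    stop("model has no mosaic parameters; run estimate_mosaic() first")
  g2 <- geom
  g2$beam_center <- model$beam_center_refined
  nodes <- enumerate_nodes(model$cell, model$orientation, d_L)
  empty <- data.frame(h = integer(), k = integer(), l = integer(),
                      d = numeric(), delta_r = numeric(), slow = numeric(),
                      fast = numeric(), on_detector = logical())
  if (nrow(nodes$q) == 0) return(empty)
  delta_r <- sqrt(nodes$q[, 1]^2 + nodes$q[, 2]^2 +
                  (nodes$q[, 3] + 1 / wavelength)^2) - 1 / wavelength
  w <- spot_width(nodes$d, model$mosaic_block_size_D, model$mosaic_angle_eta)
  sel <- abs(delta_r) <= w / 2
  if (!any(sel)) return(empty)
  pos <- q_to_pixel(nodes$q[sel, , drop = FALSE], g2, wavelength)
  data.frame(h = nodes$hkl[sel, 1], k = nodes$hkl[sel, 2],
             l = nodes$hkl[sel, 3], d = nodes$d[sel],
             delta_r = delta_r[sel], slow = pos$slow, fast = pos$fast,
             on_detector = pos$on_detector)
}

#' Integrate predicted reflections
#'
#' Summation integration: for each predicted reflection a fixed circular
#' mask of radius `radius_px` around the predicted position is summed,
#' background subtracted (per-pixel background level from
#' [estimate_background()]); sigma comes from counting statistics,
#' `sqrt(sum counts + n_px * background variance)`.  Predictions falling
#' off the detector, or whose mask overlaps excluded (e.g. beam-stop)
#' pixels, are dropped and tallied.
#'
#' @param frame an [image_frame()].
#' @param predictions data.frame from [predict_reflections()].
#' @param background an [estimate_background()] result for `frame`
#'   (computed if NULL).
#' @param radius_px integration mask radius, pixels (default 3).
#' @return list with `reflections` (data.frame `h, k, l, I, sigI, d`),
#'   `n_dropped` (off-detector or masked), `n_integrated`.
#' @export
integrate_reflections <- function(frame, predictions, background = NULL,
                                  radius_px = 3) {
  stopifnot(inherits(frame, "image_frame"))
  if (is.null(background)) background <- estimate_background(frame)
  v <- frame$raster
  ns <- nrow(v); nf <- ncol(v)
  r <- ceiling(radius_px)
  disc <- expand.grid(ds = -r:r, df = -r:r)
  disc <- disc[disc$ds^2 + disc$df^2 <= radius_px^2, ]
  np <- nrow(predictions)
  Ivec <- sigvec <- numeric(np)
  kept <- logical(np)
  for (i in seq_len(np)) {
    s0 <- round(predictions$slow[i]); f0 <- round(predictions$fast[i])
    ss <- s0 + disc$ds; ff <- f0 + disc$df
    if (!isTRUE(predictions$on_detector[i]) ||
        any(ss < 1 | ss > ns | ff < 1 | ff > nf)) next
    idx <- cbind(ss, ff)
    if (!is.null(frame$mask) && any(frame$mask[idx])) next
    counts <- v[idx]
    bg <- background$level[idx]
    sig2 <- background$sigma[idx]^2
    kept[i] <- TRUE
    Ivec[i] <- sum(counts - bg)
    sigvec[i] <- sqrt(max(sum(counts), 0) + sum(sig2))
  }
  refl <- data.frame(h = predictions$h[kept], k = predictions$k[kept],
                     l = predictions$l[kept], I = Ivec[kept],
                     sigI = sigvec[kept], d = predictions$d[kept])
  list(reflections = refl, n_dropped = np - sum(kept),
       n_integrated = nrow(refl))
}

#' Per-image integration result
#'
#' Bundle of the reflection table integrated at one grid point together
#' with its lattice model, EPV and provenance.
#'
#' @param reflections data.frame `h, k, l, I, sigI, d`.
#' @param lattice a `lattice_model`.
#' @param epv Ewald proximal volume of the model (1/angstrom^3).
#' @param grid_point numeric(2) `(min_height, min_area)`.
#' @param grid_index position of the grid point in the canonical grid
#'   (used for deterministic tie-breaks).
#' @param image_id frame identifier.
#' @param strong_threshold I/sigma(I) threshold for the strong count.
#' @param n_dropped predictions dropped during integration.
#' @return object of class `integration_result`.
#' @export
integration_result <- function(reflections, lattice, epv, grid_point,
                               grid_index, image_id = "",
                               strong_threshold = 5, n_dropped = 0L) {
  n_strong <- sum(reflections$I / reflections$sigI > strong_threshold)
  structure(list(reflections = reflections, lattice = lattice, epv = epv,
                 n_strong = n_strong, strong_threshold = strong_threshold,
                 grid_point = as.numeric(grid_point),
                 grid_index = as.integer(grid_index),
                 n_dropped = as.integer(n_dropped), image_id = image_id),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "integration result [%s] at grid point (height %g, area %g):\n  %d reflections (%d strong at I/sigI > %g), EPV %.4g A^-3\n",
    x$image_id, x$grid_point[1], x$grid_point[2], nrow(x$reflections),
    x$n_strong, x$strong_threshold, x$epv))
  invisible(x)
}
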