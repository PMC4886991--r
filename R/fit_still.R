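#' Fit a crystal model to one still image by spot-finding grid search
#'
#' The central fitting routine.  For every grid point (minimum spot
#' height, minimum spot area) a full pipeline is run: spot finding
#' ([find_spots()], with one shared background estimate), target-cell
#' indexing ([fit_orientation()]), least-squares lattice refinement
#' ([refine_lattice()]), mosaic parameter estimation
#' ([estimate_mosaic()]), reflection prediction
#' ([predict_reflections()]) and summation integration
#' ([integrate_reflections()]).  Unless a step fails, the grid point
#' yields an [integration_result()] carrying the Ewald proximal volume of
#' its crystal model; per-point failures are recorded with stage and
#' reason, not raised.  Optional Bravais-lattice / target-cell filtering
#' is applied to the result pool, and the best result is selected by the
#' two-step smallest-EPV / most-strong-reflections heuristic
#' ([select_best()]).  The image fails only if no grid point survives.
#'
#' @param frame an [image_frame()] (triaged; see [triage_frame()]).
#' @param target_cell numeric(6) known unit cell.
#' @param grid parameter grid from [build_grid()]; default the single
#'   median point of an 8 +/- 7 sigma x 12 +/- 10 px grid is NOT assumed —
#'   supply the grid you want searched.
#' @param d_L outer resolution limit (angstrom) used for mosaic ranking,
#'   prediction and EPV (default 3.5).
#' @param strong_threshold I/sigma(I) threshold defining strong
#'   reflections (default 5, strict).
#' @param epv_fraction smallest-EPV fraction kept before the strong-count
#'   selection (default 0.25).
#' @param bravais optional required Bravais lattice symbol (e.g. "oP");
#'   results failing [bravais_filter()] are excluded before selection.
#' @param cell_tolerance relative edge tolerance for the cell filter.
#' @param radius_px integration mask radius (default 3).
#' @param index_opts list of overrides passed to [fit_orientation()]
#'   (`n_min`, `f_idx`, `t_idx`, `n_coarse`, `n_score`, `n_refine`,
#'   `max_spots`).
#' @param background optional precomputed [estimate_background()] result.
#' @return object of class `still_fit` with fields `best` (the selected
#'   [integration_result()], or NULL on image-level failure), `results`
#'   (all surviving results), `log` (per-grid-point status data.frame),
#'   `n_filtered` (results removed by the Bravais/cell filter), `grid`,
#'   `target_cell`, `d_L`, `frame_id`, and `failure_histogram` (reasons by
#'   stage when the image failed).
#' @seealso [summary.still_fit()], [coef.still_fit()],
#'   [predict.still_fit()], [residuals.still_fit()], [plot.still_fit()]
#' @export
fit_still <- function(frame, target_cell, grid, d_L = 3.5,
                      strong_threshold = 5, epv_fraction = 0.25,
                      bravais = NULL, cell_tolerance = 0.05,
                      radius_px = 3, index_opts = list(),
                      background = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  validate_cell(target_cell)
  if (nrow(grid) == 0) stop("empty parameter grid")
  if (is.null(background)) background <- estimate_background(frame)
  lambda <- frame$wavelength
  geom <- frame$geometry

  results <- list()
  log_rows <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    mh <- grid$min_height[gi]; ma <- grid$min_area[gi]
    rec <- list(grid_index = gi, min_height = mh, min_area = ma,
                stage_reached = "spotfind", reason = "", n_spots = NA_integer_,
                n_indexed = NA_integer_, epv = NA_real_,
                n_strong = NA_integer_, selected = FALSE)
    step <- function(rec) { log_rows[[gi]] <<- as.data.frame(rec); NULL }

    spots <- find_spots(frame, spot_find_params(mh, ma), background = background)
    rec$n_spots <- nrow(spots)
    model <- do.call(fit_orientation,
                     c(list(spots = spots, target_cell = target_cell,
                            geom = geom, wavelength = lambda), index_opts))
    if (inherits(model, "lattice_failure")) {
      rec$stage_reached <- "index"; rec$reason <- model$reason
      step(rec); next
    }
    rec$stage_reached <- "refine"
    model <- refine_lattice(model, spots, geom, lambda)
    rec$n_indexed <- model$n_indexed

    rec$stage_reached <- "mosaic"
    model <- estimate_mosaic(model, spots, geom, lambda, d_L = d_L,
                             strong_height = 2 * mh)

    rec$stage_reached <- "predict"
    preds <- predict_reflections(model, geom, lambda, d_L)
    if (nrow(preds) == 0) { rec$reason <- "no predictions"; step(rec); next }

    rec$stage_reached <- "integrate"
    intg <- integrate_reflections(frame, preds, background = background,
                                  radius_px = radius_px)
    if (intg$n_integrated == 0) { rec$reason <- "no reflections integrated"; step(rec); next }

    epv <- compute_epv(model$mosaic_block_size_D, model$mosaic_angle_eta,
                       lambda, d_L)
    res <- integration_result(intg$reflections, model, epv,
                              grid_point = c(mh, ma), grid_index = gi,
                              image_id = frame$source_id,
                              strong_threshold = strong_threshold,
                              n_dropped = intg$n_dropped)
    res$spots <- spots
    rec$stage_reached <- "complete"
    rec$epv <- epv
    rec$n_strong <- res$n_strong
    results[[length(results) + 1]] <- res
    step(rec)
  }
  log <- do.call(rbind, log_rows)

  n_filtered <- 0L
  if (!is.null(bravais) && length(results) > 0) {
    keep <- vapply(results, function(r)
      bravais_filter(r$lattice$cell, bravais, target_cell = target_cell,
                     length_tol = cell_tolerance), TRUE)
    n_filtered <- sum(!keep)
    results <- results[keep]
  }

  best <- NULL
  failure_histogram <- NULL
  if (length(results) > 0) {
    best <- select_best(results, epv_fraction = epv_fraction,
                        strong_threshold = strong_threshold)
    log$selected <- log$grid_index == best$grid_index
  } else {
    failure_histogram <- table(paste(log$stage_reached, log$reason, sep = ": "))
  }
  structure(list(best = best, results = results, log = log,
                 n_filtered = n_filtered, grid = grid,
                 target_cell = target_cell, d_L = d_L,
                 strong_threshold = strong_threshold,
                 frame_id = frame$source_id, frame = frame,
                 failure_histogram = failure_histogram),
            class = "still_fit")
}

#' @export
print.still_fit <- function(x, ...) {
  cat(sprintf("still grid-search fit [%s]: %d/%d grid points completed\n",
              x$frame_id, length(x$results), nrow(x$grid)))
  if (is.null(x$best)) {
    cat("  image-level failure; reasons:\n")
    print(x$failure_histogram)
  } else {
    cat(sprintf("  best point: height %g sigma, area %g px; %d reflections, %d strong, EPV %.4g\n",
                x$best$grid_point[1], x$best$grid_point[2],
                nrow(x$best$reflections), x$best$n_strong, x$best$epv))
  }
  invisible(x)
}

#' Summarize a still grid-search fit
#' @param object a `still_fit`.
#' @param ... unused.
#' @return the per-grid-point log, invisibly, after printing a stage
#'   summary and the selected model.
#' @export
summary.still_fit <- function(object, ...) {
  print(object)
  cat("stages reached:\n")
  print(table(object$log$stage_reached))
  if (!is.null(object$best)) {
    cat("selected crystal model:\n")
    print(object$best$lattice)
  }
  invisible(object$log)
}

#' Coefficients of the selected crystal model
#' @param object a `still_fit`.
#' @param ... unused.
#' @return named vector: cell (a..gamma), mosaic D and eta, refined beam
#'   center.
#' @export
coef.still_fit <- function(object, ...) {
  if (is.null(object$best)) return(NULL)
  m <- object$best$lattice
  c(a = m$cell[1], b = m$cell[2], c = m$cell[3],
    alpha = m$cell[4], beta = m$cell[5], gamma = m$cell[6],
    D = m$mosaic_block_size_D, eta = m$mosaic_angle_eta,
    beam_slow = m$beam_center_refined[1], beam_fast = m$beam_center_refined[2])
}

#' Predicted reflections of the selected model
#' @param object a `still_fit`.
#' @param d_L resolution limit (defaults to the fit's).
#' @param ... unused.
#' @return prediction table from [predict_reflections()].
#' @export
predict.still_fit <- function(object, d_L = object$d_L, ...) {
  if (is.null(object$best)) stop("no successful integration result to predict from")
  predict_reflections(object$best$lattice, object$frame$geometry,
                      object$frame$wavelength, d_L)
}

#' Observed-minus-predicted spot residuals (pixels)
#' @param object a `still_fit`.
#' @param ... unused.
#' @return data.frame `slow`, `fast` residuals for the indexed spots of
#'   the selected grid point.
#' @export
residuals.still_fit <- function(object, ...) {
  if (is.null(object$best)) stop("no successful integration result")
  m <- object$best$lattice
  spots <- model_spots(m, object$best$spots)
  ok <- m$indexed
  g2 <- object$frame$geometry
  g2$beam_center <- m$beam_center_refined
  B <- reciprocal_matrix(m$cell)
  qpred <- t(m$orientation %*% B %*% t(m$hkl[ok, , drop = FALSE]))
  pp <- q_to_pixel(qpred, g2, object$frame$wavelength)
  data.frame(slow = spots$slow[ok] - pp$slow, fast = spots$fast[ok] - pp$fast)
}

#' Simulate still images from the fitted crystal model
#'
#' Renders synthetic frames from the selected crystal model (cell,
#' orientation, mosaic parameters) under the fitted frame's geometry —
#' useful for eyeballing whether the model reproduces the observed
#' diffraction pattern.
#'
#' @param object a `still_fit`.
#' @param nsim number of frames (default 1).
#' @param seed integer seed for the renderer.
#' @param background_mean,intensity_mean renderer settings (see
#'   [render_still()]).
#' @param ... unused.
#' @return list of `nsim` [image_frame()] objects.
#' @export
simulate.still_fit <- function(object, nsim = 1, seed = 1,
                               background_mean = 20, intensity_mean = 4000,
                               ...) {
  if (is.null(object$best)) stop("no successful integration result to simulate from")
  m <- object$best$lattice
  truth <- structure(list(cell = m$cell, orientation = m$orientation,
                          mosaic_block_size_D = m$mosaic_block_size_D,
                          mosaic_angle_eta = m$mosaic_angle_eta,
                          wavelength = object$frame$wavelength,
                          is_blank = FALSE, seed = as.integer(seed)),
                     class = "ground_truth")
  lapply(seq_len(nsim), function(i)
    render_still(truth, object$frame$geometry,
                 background_mean = background_mean, d_min = object$d_L,
                 rng_seed = seed + i - 1,
                 intensity_mean = intensity_mean)$frame)
}

#' Plot a still fit: image, found spots and predictions
#' @param x a `still_fit`.
#' @param ... passed to [graphics::image()].
#' @return x, invisibly.
#' @export
plot.still_fit <- function(x, ...) {
  v <- x$frame$raster
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "fast (px)", ylab = "slow (px)",
                  main = x$frame_id, useRaster = TRUE, ...)
  if (!is.null(x$best)) {
    sp <- x$best$spots
    graphics::points(sp$fast, sp$slow, pch = 5, col = "blue", cex = 0.8)
    pr <- predict(x)
    pr <- pr[pr$on_detector, ]
    graphics::points(pr$fast, pr$slow, pch = 1, col = "red", cex = 1.2)
    graphics::legend("topright", legend = c("found spots", "predictions"),
                     pch = c(5, 1), col = c("blue", "red"), bty = "n")
  }
  invisible(x)
}

#' Process a set of still images: triage then grid-search fitting
#'
#' Dataset-level driver: each frame is read (if given as a path), triaged
#' by candidate-spot count, and — if kept — fitted with [fit_still()].
#' Images are independent work units processed in a deterministic order.
#'
#' @param frames list of [image_frame()] objects or character vector of
#'   SMV paths.
#' @param target_cell numeric(6).
#' @param grid parameter grid from [build_grid()].
#' @param min_spots triage threshold (default 10; 0 bypasses triage).
#' @param triage_params numeric(2) spot-finder parameters used by triage
#'   (default: the grid's median point).
#' @param ... passed on to [fit_still()].
#' @return object of class `still_run`: list with `ids`, `triage` (list of
#'   [triage_frame()] decisions), `fits` (list, NULL for discarded
#'   frames), `grid`, `target_cell`.
#' @export
process_dataset <- function(frames, target_cell, grid, min_spots = 10,
                            triage_params = NULL, ...) {
  if (is.character(frames)) {
    ids <- basename(frames)
    loader <- function(i) read_frame(frames[i])
    n <- length(frames)
  } else {
    ids <- vapply(frames, function(f) f$source_id, "")
    loader <- function(i) frames[[i]]
    n <- length(frames)
  }
  if (is.null(triage_params)) {
    mp <- grid_median_point(grid)
    triage_params <- c(mp$min_height, mp$min_area)
  }
  triage <- vector("list", n); fits <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- loader(i)
    bg <- estimate_background(fr)
    tri <- triage_frame(fr, spot_params = triage_params,
                        min_spots = min_spots, background = bg)
    triage[[i]] <- tri
    if (tri$keep)
      fits[[i]] <- fit_still(fr, target_cell, grid, background = bg, ...)
  }
  structure(list(ids = ids, triage = triage, fits = fits, grid = grid,
                 target_cell = target_cell),
            class = "still_run")
}

#' @export
print.still_run <- function(x, ...) {
  kept <- vapply(x$triage, function(t) t$keep, TRUE)
  ok <- vapply(x$fits, function(f) !is.null(f) && !is.null(f$best), TRUE)
  cat(sprintf("still run: %d images, %d kept by triage, %d integrated\n",
              length(x$ids), sum(kept), sum(ok)))
  invisible(x)
}
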