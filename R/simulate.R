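#' Random crystal ground truth
#'
#' Draws one synthetic crystal: a uniformly random orientation (Shoemake
#' quaternion method), and mosaic block size D / mosaic rotational spread
#' eta uniform over the supplied ranges.  Deterministic given the seed.
#'
#' @param cell numeric(6) unit cell (validated; invalid cells are rejected
#'   with a diagnostic naming the offending parameter).
#' @param D_range interval (angstrom) for the mosaic block size.
#' @param eta_range interval (radians, full width) for the mosaic spread.
#' @param rng_seed integer seed.
#' @param wavelength X-ray wavelength in angstrom (default 1.3).
#' @return object of class `ground_truth` with fields `cell`,
#'   `orientation` (3x3 proper rotation), `mosaic_block_size_D`,
#'   `mosaic_angle_eta`, `wavelength`, `is_blank`, `seed`.
#' @export
random_crystal <- function(cell, D_range, eta_range, rng_seed,
                           wavelength = 1.3) {
  validate_cell(cell)
  stopifnot(length(D_range) == 2, length(eta_range) == 2,
            D_range[1] <= D_range[2], eta_range[1] <= eta_range[2],
            D_range[1] > 0, eta_range[1] >= 0, wavelength > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  R <- random_rotation()
  D <- stats::runif(1, D_range[1], D_range[2])
  eta <- stats::runif(1, eta_range[1], eta_range[2])
  structure(list(cell = as.numeric(cell), orientation = R,
                 mosaic_block_size_D = D, mosaic_angle_eta = eta,
                 wavelength = wavelength, is_blank = FALSE,
                 seed = as.integer(rng_seed)),
            class = "ground_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("crystal: cell (%s), D = %.0f A, eta = %.4g rad, lambda = %.3g A%s\n",
              paste(signif(x$cell, 5), collapse = ", "),
              x$mosaic_block_size_D, x$mosaic_angle_eta, x$wavelength,
              if (isTRUE(x$is_blank)) " [blank]" else ""))
  invisible(x)
}

# enumerate reciprocal nodes with d >= d_min for orientation R
enumerate_nodes <- function(cell, R, d_min) {
  A <- direct_matrix(cell)
  B <- reciprocal_matrix(cell)
  hmax <- floor(sqrt(colSums(A^2)) / d_min)   # |h_i| <= |a_i| * |q| <= a_i/d_min
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                               k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  q <- t(R %*% B %*% t(hkl))
  d <- 1 / sqrt(rowSums(q^2))
  keep <- d >= d_min
  list(hkl = hkl[keep, , drop = FALSE], q = q[keep, , drop = FALSE],
       d = d[keep])
}

#' Render one synthetic still diffraction image
#'
#' Reflections are the reciprocal-lattice nodes whose distance from the
#' Ewald sphere is at most half the mosaic spot width w(d) (see
#' [spot_width()]).  Each is drawn on the detector as an isotropic 2-D
#' Gaussian of footprint `sigma_px`; its integrated intensity is the full
#' reflection intensity scaled by a Gaussian partiality factor
#' `exp(-dr^2 / (2 sigma_r^2))` with `sigma_r = w/2.355`, so the falloff
#' has full width at half maximum w and equals 1/2 at the rendering cutoff
#' `|dr| = w/2`.  Poisson noise is applied to background + signal when
#' `noise = TRUE`.  Blank truths render background only.
#'
#' @param truth a `ground_truth`.
#' @param det a `detector_geometry`.
#' @param background_mean flat background level in counts (>= 0).
#' @param d_min outer resolution limit for rendering, angstrom
#'   (must be >= wavelength/2).
#' @param rng_seed integer seed (intensities and noise).
#' @param sigma_px detector-plane Gaussian footprint of a spot, pixels.
#' @param intensity_mean mean full-reflection intensity, counts (lognormal
#'   heterogeneity with `intensity_sdlog`).
#' @param intensity_sdlog lognormal sdlog of reflection intensities.
#' @param noise apply Poisson noise (default TRUE).
#' @return list with `frame` (an [image_frame()]) and `manifest`, a
#'   data.frame with one row per rendered reflection: h, k, l, d, delta_r,
#'   partiality, intensity (expected recorded counts after partiality),
#'   slow, fast, on_detector.
#' @export
render_still <- function(truth, det, background_mean = 20, d_min = 3.5,
                         rng_seed = 1, sigma_px = 1.0,
                         intensity_mean = 4000, intensity_sdlog = 0.6,
                         noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(det, "detector_geometry"))
  lambda <- truth$wavelength
  if (d_min < lambda / 2)
    stop("d_min = ", d_min, " unreachable at wavelength ", lambda)
  if (background_mean < 0) stop("background_mean must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)

  empty_manifest <- data.frame(h = integer(), k = integer(), l = integer(),
                               d = numeric(), delta_r = numeric(),
                               partiality = numeric(), intensity = numeric(),
                               slow = numeric(), fast = numeric(),
                               on_detector = logical())
  raster <- matrix(background_mean, det$n_slow, det$n_fast)
  manifest <- empty_manifest

  if (!isTRUE(truth$is_blank)) {
    nodes <- enumerate_nodes(truth$cell, truth$orientation, d_min)
    if (nrow(nodes$q) > 0) {
      delta_r <- sqrt(nodes$q[, 1]^2 + nodes$q[, 2]^2 +
                      (nodes$q[, 3] + 1 / lambda)^2) - 1 / lambda
      w <- spot_width(nodes$d, truth$mosaic_block_size_D, truth$mosaic_angle_eta)
      sel <- abs(delta_r) <= w / 2
      if (any(sel)) {
        hkl <- nodes$hkl[sel, , drop = FALSE]
        q <- nodes$q[sel, , drop = FALSE]
        d <- nodes$d[sel]; delta_r <- delta_r[sel]; w <- w[sel]
        sigma_r <- w / 2.355
        part <- exp(-delta_r^2 / (2 * sigma_r^2))
        i_full <- stats::rlnorm(length(d),
                                log(intensity_mean) - intensity_sdlog^2 / 2,
                                intensity_sdlog)
        inten <- i_full * part
        pos <- q_to_pixel(q, det, lambda)
        manifest <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                               d = d, delta_r = delta_r, partiality = part,
                               intensity = inten,
                               slow = pos$slow, fast = pos$fast,
                               on_detector = pos$on_detector)
        for (i in which(pos$on_detector)) {
          raster <- add_gaussian_spot(raster, pos$slow[i], pos$fast[i],
                                      inten[i], sigma_px)
        }
      }
    }
  }
  if (noise) {
    v <- stats::rpois(length(raster), lambda = pmax(raster, 0))
    raster <- matrix(v, nrow(raster), ncol(raster))
  }
  raster <- matrix(pmin(pmax(round(raster), 0), 65535), nrow(raster), ncol(raster))
  storage.mode(raster) <- "integer"
  frame <- image_frame(raster, det, lambda,
                       source_id = sprintf("sim_seed%d", truth$seed))
  list(frame = frame, manifest = manifest)
}

# add one 2-D Gaussian of integrated intensity `total` at fractional
# position (s0, f0); density evaluated at pixel centers over a +-4 sigma patch
add_gaussian_spot <- function(raster, s0, f0, total, sigma_px) {
  r <- ceiling(4 * sigma_px)
  ss <- max(1, floor(s0) - r):min(nrow(raster), ceiling(s0) + r)
  ff <- max(1, floor(f0) - r):min(ncol(raster), ceiling(f0) + r)
  if (length(ss) == 0 || length(ff) == 0) return(raster)
  gs <- exp(-(ss - s0)^2 / (2 * sigma_px^2))
  gf <- exp(-(ff - f0)^2 / (2 * sigma_px^2))
  patch <- (total / (2 * pi * sigma_px^2)) * outer(gs, gf)
  raster[ss, ff] <- raster[ss, ff] + patch
  raster
}

#' Generate a synthetic still-image dataset with ground truth
#'
#' Writes `n_images` SMV frames plus a tab-separated ground-truth manifest
#' (`manifest.tsv`: filename, is_blank, cell a..gamma, quaternion w x y z,
#' D, eta, n_reflections).  Approximately `blank_fraction` of the frames
#' are background-only.  Unit cells are drawn from weighted populations;
#' mosaic parameters, spot footprint and intensity scale are drawn per
#' image from the heterogeneity ranges.  One master seed; per-image seeds
#' are drawn up front from the master-seeded RNG, so output is independent
#' of processing order and byte-identical on re-run.
#'
#' @param n_images number of frames (>= 1).
#' @param blank_fraction fraction of blank frames in `[0, 1]`.
#' @param populations list of `list(cell = numeric(6), weight = w)`;
#'   weights must sum to 1.
#' @param out_dir output directory (created; must be writable).
#' @param rng_seed master seed.
#' @param det detector geometry (default 400 x 400 px, 0.1 mm pixels,
#'   50 mm distance, centered beam).
#' @param heterogeneity list of per-image ranges: `D_range` (angstrom),
#'   `eta_range` (radians), `sigma_px_range`, `intensity_range` (mean
#'   counts).  Defaults emulate a moderately heterogeneous serial set.
#' @param wavelength angstrom (default 1.3).
#' @param background_mean counts (default 20).
#' @param d_min rendering resolution limit, angstrom (default 3.5).
#' @param noise apply Poisson noise (default TRUE).
#' @return invisibly, the manifest data.frame (also written to
#'   `out_dir/manifest.tsv`).
#' @export
generate_dataset <- function(n_images, blank_fraction, populations, out_dir,
                             rng_seed,
                             det = detector_geometry(400, 400, 0.1, 50,
                                                     c(200.5, 200.5)),
                             heterogeneity = list(),
                             wavelength = 1.3, background_mean = 20,
                             d_min = 3.5, noise = TRUE) {
  stopifnot(n_images >= 1, blank_fraction >= 0, blank_fraction <= 1)
  wts <- vapply(populations, function(p) p$weight, 0)
  if (abs(sum(wts) - 1) > 1e-8) stop("population weights must sum to 1")
  for (p in populations) validate_cell(p$cell)
  het <- utils::modifyList(list(D_range = c(300, 800),
                                eta_range = c(0.001, 0.004),
                                sigma_px_range = c(0.8, 2.2),
                                intensity_range = c(800, 8000)),
                           heterogeneity)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  blank <- stats::runif(n_images) < blank_fraction
  pop <- sample.int(length(populations), n_images, replace = TRUE, prob = wts)
  sig <- stats::runif(n_images, het$sigma_px_range[1], het$sigma_px_range[2])
  imean <- exp(stats::runif(n_images, log(het$intensity_range[1]),
                            log(het$intensity_range[2])))

  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    truth <- random_crystal(populations[[pop[i]]]$cell, het$D_range,
                            het$eta_range, seeds[i], wavelength = wavelength)
    truth$is_blank <- blank[i]
    rs <- render_still(truth, det, background_mean = background_mean,
                       d_min = d_min, rng_seed = seeds[i],
                       sigma_px = sig[i], intensity_mean = imean[i],
                       noise = noise)
    fn <- sprintf("img_%04d.img", i)
    rs$frame$source_id <- fn
    write_frame(rs$frame, file.path(out_dir, fn))
    qt <- rotmat_to_quat(truth$orientation)
    rows[[i]] <- data.frame(filename = fn, is_blank = blank[i],
                            a = truth$cell[1], b = truth$cell[2],
                            c = truth$cell[3], alpha = truth$cell[4],
                            beta = truth$cell[5], gamma = truth$cell[6],
                            qw = qt[1], qx = qt[2], qy = qt[3], qz = qt[4],
                            D = truth$mosaic_block_size_D,
                            eta = truth$mosaic_angle_eta,
                            sigma_px = sig[i], intensity_mean = imean[i],
                            n_reflections = nrow(rs$manifest))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
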