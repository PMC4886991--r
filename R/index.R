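#' Target-cell indexing of a still image
#'
#' Determines the crystal orientation from found spots given a known
#' target unit cell.  Each spot centroid is mapped to a reciprocal-space
#' vector (assuming it lies on the Ewald sphere); a deterministic
#' low-discrepancy set of candidate orientations (Halton-sequence Shoemake
#' quaternions) is scored by the capped distance of the lowest-resolution
#' spots to their nearest reciprocal-lattice nodes, and the best
#' candidates are polished by iterating nearest-node assignment with an
#' orthogonal-Procrustes (Kabsch) orientation update over all spots.
#' Indexing succeeds iff at least `f_idx` of the spots land within
#' `t_idx` (reciprocal angstrom) of a lattice node.
#'
#' @param spots data.frame from [find_spots()] (needs `slow`, `fast`, `I`).
#' @param target_cell numeric(6) known unit cell.
#' @param geom a [detector_geometry()].
#' @param wavelength angstrom.
#' @param n_min minimum number of spots required (default 10).
#' @param f_idx minimum fraction of spots indexed for success (default 0.5).
#' @param t_idx indexing tolerance in reciprocal angstrom; default 0.15
#'   times the shortest reciprocal cell edge.
#' @param n_coarse size of the coarse orientation set (default 140000,
#'   roughly 2.5-degree covering of the rotation group).
#' @param n_score number of lowest-resolution spots used for coarse
#'   scoring (default 8).
#' @param n_refine number of top coarse candidates polished (default 80).
#' @param max_spots cap on the number of (strongest) spots used (default 200).
#' @return a `lattice_model` (list with `cell`, `orientation`,
#'   `mosaic_block_size_D`, `mosaic_angle_eta`, `beam_center_refined`,
#'   `rmsd_obs_pred`, `n_indexed`, `n_spots`, `hkl` assignment) or a
#'   `lattice_failure` (list with `reason`).
#' @export
fit_orientation <- function(spots, target_cell, geom, wavelength,
                            n_min = 10, f_idx = 0.5, t_idx = NULL,
                            n_coarse = 140000L, n_score = 8L,
                            n_refine = 80L, max_spots = 200L) {
  validate_cell(target_cell)
  if (nrow(spots) < n_min)
    return(structure(list(reason = "insufficient spots",
                          n_spots = nrow(spots)), class = "lattice_failure"))
  if (nrow(spots) > max_spots) spots <- spots[seq_len(max_spots), , drop = FALSE]
  B <- reciprocal_matrix(target_cell)
  if (is.null(t_idx)) t_idx <- 0.15 * min(sqrt(colSums(B^2)))
  q <- pixel_to_q(spots$slow, spots$fast, geom, wavelength)

  # coarse scoring on difference vectors between the lowest-resolution
  # (shortest |q|) spots: differences of reciprocal vectors are lattice
  # vectors too, and any constant q error from a mis-stated beam center
  # cancels exactly
  qlen <- sqrt(rowSums(q^2))
  sc <- order(qlen)[seq_len(min(n_score + 1L, nrow(q)))]
  dq <- sweep(q[sc[-1], , drop = FALSE], 2, q[sc[1], ])
  Mstack <- coarse_index_stack(target_cell, n_coarse)
  H <- Mstack$M %*% t(dq)                       # (3*M) x n_score fractional hkl
  E <- H - round(H)
  dim(E) <- c(3L, n_coarse * nrow(dq))
  r2 <- colSums(E * E)
  dim(r2) <- c(n_coarse, nrow(dq))
  cap <- 0.3^2
  score <- rowSums(pmin(r2, cap))
  top <- order(score)[seq_len(n_refine)]

  # bootstrap tolerance: loose enough to keep spots whose q carries a
  # systematic error from a mis-stated beam center (assignment itself uses
  # nearest-node rounding, which tolerates offsets up to half a spacing)
  t_boot <- max(t_idx, 0.35 * min(sqrt(colSums(B^2))))
  Binv <- solve(B)
  best <- NULL
  for (i in top) {
    R <- quat_to_rotmat(Mstack$quat[i, ])
    fit <- polish_orientation(R, q, B, Binv, t_boot)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  # a mis-stated beam center shifts every q by a nearly constant vector;
  # absorb it by translating the beam center along the mean residual of
  # the indexed spots and re-deriving q (a few fixed-point steps)
  g2 <- geom
  for (outer in 1:4) {
    if (best$n_indexed < 5) break
    pred <- best$R %*% B %*% t(best$hkl)
    res <- t(q) - pred
    mres <- rowMeans(res[, best$ok, drop = FALSE])
    dbc <- c(mres[2], mres[1]) * g2$distance * wavelength / g2$pixel_size
    if (max(abs(dbc)) < 0.05) break
    g2$beam_center <- g2$beam_center + dbc
    q <- pixel_to_q(spots$slow, spots$fast, g2, wavelength)
    best <- polish_orientation(best$R, q, B, Binv, t_boot)
  }
  best <- polish_orientation(best$R, q, B, Binv, t_idx)
  n_ok <- best$n_indexed
  if (n_ok / nrow(q) < f_idx)
    return(structure(list(reason = "indexing failed",
                          fraction_indexed = n_ok / nrow(q)),
                     class = "lattice_failure"))
  model <- lattice_model(target_cell, best$R, g2$beam_center)
  model$n_indexed <- n_ok
  model$n_spots <- nrow(q)
  model$used_idx <- seq_len(nrow(q))   # rows of the (intensity-sorted) input
  model$hkl <- best$hkl
  model$indexed <- best$ok
  model$rmsd_obs_pred <- model_rmsd(model, spots, geom, wavelength)
  model
}

# package-level cache of coarse orientation stacks (cell x n dependent)
.stillgrid_cache <- new.env(parent = emptyenv())

coarse_index_stack <- function(cell, n) {
  key <- paste(signif(cell, 8), n, collapse = "_")
  hit <- .stillgrid_cache[[key]]
  if (!is.null(hit)) return(hit)
  quat <- halton_quaternions(n)
  Binv <- solve(reciprocal_matrix(cell))
  w <- quat[, 1]; x <- quat[, 2]; y <- quat[, 3]; z <- quat[, 4]
  # vectorized rotation-matrix entries R[r, c] for all n quaternions
  Rv <- list(
    list(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    list(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    list(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  M <- matrix(0, 3 * n, 3)
  rows <- lapply(1:3, function(r) 3 * (seq_len(n) - 1L) + r)
  for (r in 1:3) for (cc in 1:3) {
    # (Binv %*% t(R))[r, cc] = sum_k Binv[r, k] * R[cc, k]
    M[rows[[r]], cc] <- Binv[r, 1] * Rv[[cc]][[1]] +
      Binv[r, 2] * Rv[[cc]][[2]] + Binv[r, 3] * Rv[[cc]][[3]]
  }
  out <- list(M = M, quat = quat)
  .stillgrid_cache[[key]] <- out
  out
}

# iterate nearest-node assignment + Kabsch update; returns best R, hkl, rss
polish_orientation <- function(R, q, B, Binv, t_idx, iters = 6L) {
  for (it in seq_len(iters)) {
    hkl <- round(Binv %*% t(R) %*% t(q))        # 3 x n
    pred <- R %*% B %*% hkl
    res2 <- colSums((t(q) - pred)^2)
    ok <- res2 <= t_idx^2 & colSums(abs(hkl)) > 0
    if (sum(ok) < 3) break
    # Kabsch: R minimizing sum |R B h - q|^2 over the indexed subset
    Cmat <- t(q)[, ok, drop = FALSE] %*% t((B %*% hkl)[, ok, drop = FALSE])
    sv <- svd(Cmat)
    d <- sign(det(sv$u %*% t(sv$v)))
    Rnew <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    if (max(abs(Rnew - R)) < 1e-12) { R <- Rnew; break }
    R <- Rnew
  }
  hkl <- round(Binv %*% t(R) %*% t(q))
  pred <- R %*% B %*% hkl
  res2 <- colSums((t(q) - pred)^2)
  ok <- res2 <= t_idx^2 & colSums(abs(hkl)) > 0
  list(R = R, hkl = t(hkl), ok = ok, n_indexed = sum(ok),
       rss = sum(pmin(res2, t_idx^2)))
}

#' Crystal lattice model for one still
#'
#' @param cell numeric(6).
#' @param orientation 3x3 proper rotation (checked: det = 1 within 1e-9).
#' @param beam_center numeric(2) refined beam center, pixels (slow, fast).
#' @return object of class `lattice_model`.
#' @export
lattice_model <- function(cell, orientation, beam_center) {
  validate_cell(cell)
  if (abs(det(orientation) - 1) > 1e-9)
    stop("orientation must be a proper rotation (det = 1)")
  structure(list(cell = as.numeric(cell), orientation = orientation,
                 mosaic_block_size_D = NA_real_, mosaic_angle_eta = NA_real_,
                 beam_center_refined = as.numeric(beam_center),
                 rmsd_obs_pred = NA_real_, n_indexed = NA_integer_,
                 refined = FALSE, mosaic_saturated = FALSE),
            class = "lattice_model")
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("lattice model: cell (%s)\n  %d/%s spots indexed, rmsd %.3f px, D = %s A, eta = %s rad\n",
              paste(signif(x$cell, 5), collapse = ", "),
              x$n_indexed, if (is.null(x$n_spots)) "?" else x$n_spots,
              x$rmsd_obs_pred,
              format(signif(x$mosaic_block_size_D, 3)),
              format(signif(x$mosaic_angle_eta, 3))))
  invisible(x)
}

# subset a spot table to the rows the model was fitted on
model_spots <- function(model, spots) {
  if (!is.null(model$used_idx) && nrow(spots) != length(model$indexed))
    spots <- spots[model$used_idx, , drop = FALSE]
  spots
}

# rmsd (pixels) between observed indexed spots and their predicted positions
model_rmsd <- function(model, spots, geom, wavelength) {
  spots <- model_spots(model, spots)
  ok <- model$indexed
  if (sum(ok) == 0) return(NA_real_)
  g2 <- geom
  g2$beam_center <- model$beam_center_refined
  B <- reciprocal_matrix(model$cell)
  qpred <- t(model$orientation %*% B %*% t(model$hkl[ok, , drop = FALSE]))
  pp <- q_to_pixel(qpred, g2, wavelength)
  sqrt(mean((pp$slow - spots$slow[ok])^2 + (pp$fast - spots$fast[ok])^2))
}

#' Refine orientation, cell lengths and beam center
#'
#' Least-squares refinement minimizing the pixel-space distance between
#' observed spot centroids and the predicted positions of their assigned
#' Miller indices.  Free parameters: a small rotation (3 axis-angle
#' components) composed with the input orientation, the three cell edge
#' lengths (angles held at the target values), and the beam center
#' (2 pixels).  Guarded: if the refined model's rmsd exceeds the input
#' model's, the input is returned flagged unrefined.
#'
#' @param model a `lattice_model` from [fit_orientation()].
#' @param spots the spot list the model was fitted to.
#' @param geom a [detector_geometry()].
#' @param wavelength angstrom.
#' @return refined `lattice_model` (field `refined` set accordingly;
#'   `rmsd_obs_pred` never larger than the input's).
#' @export
refine_lattice <- function(model, spots, geom, wavelength) {
  stopifnot(inherits(model, "lattice_model"))
  spots <- model_spots(model, spots)
  ok <- model$indexed
  if (sum(ok) < 5) { model$refined <- FALSE; return(model) }
  hkl <- t(model$hkl[ok, , drop = FALSE])
  obs_s <- spots$slow[ok]; obs_f <- spots$fast[ok]
  R0 <- model$orientation
  cell0 <- model$cell
  bc0 <- model$beam_center_refined
  g2 <- geom

  objective <- function(p) {
    if (any(abs(p[1:6]) > 0.5) || any(abs(p[7:8]) > 20)) return(1e12)
    R <- axis_angle_rotation(p[1:3]) %*% R0
    cell <- cell0; cell[1:3] <- cell0[1:3] * exp(p[4:6])
    B <- tryCatch(reciprocal_matrix(cell), error = function(e) NULL)
    if (is.null(B)) return(1e12)
    g2$beam_center <- bc0 + p[7:8]
    qpred <- t(R %*% B %*% hkl)
    pp <- q_to_pixel(qpred, g2, wavelength)
    if (anyNA(pp$slow)) return(1e12)
    sum((pp$slow - obs_s)^2 + (pp$fast - obs_f)^2)
  }
  fit <- stats::optim(rep(0, 8), objective, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12,
                                     parscale = c(rep(1e-3, 6), rep(0.1, 2))))
  p <- fit$par
  out <- model
  out$orientation <- axis_angle_rotation(p[1:3]) %*% R0
  out$cell[1:3] <- cell0[1:3] * exp(p[4:6])
  out$beam_center_refined <- bc0 + p[7:8]
  out$refined <- TRUE
  out$rmsd_obs_pred <- model_rmsd(out, spots, geom, wavelength)
  if (!is.na(model$rmsd_obs_pred) &&
      (is.na(out$rmsd_obs_pred) || out$rmsd_obs_pred > model$rmsd_obs_pred)) {
    model$refined <- FALSE
    return(model)
  }
  out
}

axis_angle_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-14) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Estimate mosaic parameters from indexed spots
#'
#' Coverage criterion: the smallest mosaic model (eta, 1/D), on a 2-D
#' scan, such that every indexed strong spot's reciprocal-lattice node
#' lies within w(d)/2 of the Ewald sphere (w from [spot_width()]).  Among
#' all feasible scan points the pair minimizing the Ewald proximal volume
#' is returned (ties: smaller eta, then larger D).  If no scanned pair
#' covers the spots, the scan-boundary values are returned flagged
#' saturated.
#'
#' @param model a `lattice_model` with spot assignments.
#' @param spots the spot list (used to select strong spots).
#' @param geom detector geometry.
#' @param wavelength angstrom.
#' @param d_L outer resolution limit used for the EPV ranking, angstrom.
#' @param strong_height spots with `height_sigma` at or above this value
#'   are the strong subset the model must cover (default 0 = all indexed).
#' @param eta_max,D_min,D_max,n_scan scan bounds and resolution.
#' @return the model with `mosaic_block_size_D`, `mosaic_angle_eta` (and
#'   `mosaic_saturated`) filled in.
#' @export
estimate_mosaic <- function(model, spots, geom, wavelength, d_L = 3.5,
                            strong_height = 0, eta_max = 0.02,
                            D_min = 50, D_max = 5000, n_scan = 33L) {
  stopifnot(inherits(model, "lattice_model"))
  spots <- model_spots(model, spots)
  ok <- model$indexed & spots$height_sigma >= strong_height
  if (sum(ok) == 0) ok <- model$indexed
  B <- reciprocal_matrix(model$cell)
  qn <- t(model$orientation %*% B %*% t(model$hkl[ok, , drop = FALSE]))
  dr <- abs(sqrt(qn[, 1]^2 + qn[, 2]^2 + (qn[, 3] + 1 / wavelength)^2) -
            1 / wavelength)
  dd <- 1 / sqrt(rowSums(qn^2))
  etas <- seq(0, eta_max, length.out = n_scan)
  # coverage requires 2/D + eta/d_i >= 2*dr_i for every strong spot; EPV
  # is increasing in both eta and 1/D, so for each scanned eta only the
  # exact minimal feasible 1/D (clamped to [1/D_max, 1/D_min]) can be
  # optimal
  cand <- lapply(etas, function(eta) {
    req <- max(2 * dr - eta / dd) / 2
    iD <- max(req, 1 / D_max)
    if (iD > 1 / D_min) return(NULL)
    c(eta = eta, invD = iD)
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand)) {
    model$mosaic_angle_eta <- eta_max
    model$mosaic_block_size_D <- D_min
    model$mosaic_saturated <- TRUE
    return(model)
  }
  epvs <- vapply(seq_len(nrow(cand)), function(i)
    compute_epv(1 / cand[i, "invD"], cand[i, "eta"], wavelength, d_L,
                quadrature_points = 64L), 0)
  pick <- order(epvs, cand[, "eta"], cand[, "invD"])[1]
  model$mosaic_angle_eta <- unname(cand[pick, "eta"])
  model$mosaic_block_size_D <- unname(1 / cand[pick, "invD"])
  model$mosaic_saturated <- FALSE
  model
}
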