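#' Spot-finding parameters
#'
#' The two parameters varied by the grid search: the minimum peak height,
#' expressed as the background-subtracted pixel intensity divided by the
#' background standard deviation, and the minimum spot area, the number of
#' connected pixels in a peak.
#'
#' @param min_height minimum peak height in background-sigma units (> 0).
#' @param min_area minimum connected-pixel count (integer >= 1).
#' @return object of class `spot_find_params`.
#' @export
spot_find_params <- function(min_height, min_area) {
  if (min_height <= 0) stop("min_height must be > 0")
  if (min_area < 1 || min_area != round(min_area))
    stop("min_area must be an integer >= 1")
  structure(list(min_height = min_height, min_area = as.integer(min_area)),
            class = "spot_find_params")
}

#' Per-pixel background level and sigma
#'
#' Robust local background model: the raster is divided into square tiles
#' (default 64 px) and each tile's unmasked pixels contribute a median
#' (level) and a scaled median absolute deviation (sigma); the tile values
#' are then expanded to per-pixel rasters.  Median/MAD statistics make the
#' estimate insensitive to the sparse bright Bragg pixels and to isolated
#' hot pixels.  Fully masked tiles inherit the global median; a fully
#' masked frame is an error.
#'
#' @param frame an [image_frame()].
#' @param tile tile edge in pixels (default 64).
#' @return list with matrices `level` and `sigma` (same shape as the
#'   raster).
#' @export
estimate_background <- function(frame, tile = 64L) {
  stopifnot(inherits(frame, "image_frame"), tile >= 4)
  v <- frame$raster
  mask <- if (is.null(frame$mask)) matrix(FALSE, nrow(v), ncol(v)) else frame$mask
  if (all(mask)) stop("cannot estimate background: frame is fully masked")
  ns <- nrow(v); nf <- ncol(v)
  ts <- ceiling(ns / tile); tf <- ceiling(nf / tile)
  lvl <- sig <- matrix(NA_real_, ts, tf)
  for (i in seq_len(ts)) {
    rows <- ((i - 1) * tile + 1):min(i * tile, ns)
    for (j in seq_len(tf)) {
      cols <- ((j - 1) * tile + 1):min(j * tile, nf)
      px <- v[rows, cols][!mask[rows, cols]]
      if (length(px) >= 8) {
        lvl[i, j] <- stats::median(px)
        sig[i, j] <- stats::mad(px)
      }
    }
  }
  if (anyNA(lvl)) {
    gl <- stats::median(v[!mask]); gs <- stats::mad(v[!mask])
    lvl[is.na(lvl)] <- gl; sig[is.na(sig)] <- gs
  }
  idx_s <- pmin((seq_len(ns) - 1L) %/% tile + 1L, ts)
  idx_f <- pmin((seq_len(nf) - 1L) %/% tile + 1L, tf)
  list(level = lvl[idx_s, idx_f, drop = FALSE],
       sigma = sig[idx_s, idx_f, drop = FALSE])
}

# 8-connected component labels for a sparse candidate-pixel set
label_components <- function(cand_idx, n_slow) {
  n <- length(cand_idx)
  if (n == 0) return(integer(0))
  s <- ((cand_idx - 1L) %% n_slow) + 1L
  f <- ((cand_idx - 1L) %/% n_slow) + 1L
  offs <- c(1L, n_slow, n_slow + 1L, n_slow - 1L)   # down, right, dr, ur
  pos <- match(c(cand_idx + offs[1], cand_idx + offs[2],
                 cand_idx + offs[3], cand_idx + offs[4]),
               cand_idx)
  from <- rep.int(seq_len(n), 4L)
  ok <- !is.na(pos)
  from <- from[ok]; to <- pos[ok]
  # linear-index arithmetic can wrap between column ends: keep only true
  # 8-neighbours
  ok2 <- abs(s[to] - s[from]) <= 1L & abs(f[to] - f[from]) <= 1L
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  e <- rbind(from[ok2], to[ok2])
  if (ncol(e) > 0) g <- igraph::add_edges(g, as.vector(e))
  igraph::components(g)$membership
}

#' Find candidate Bragg spots
#'
#' Classic serial-crystallography peak detection: a spot is a maximal 8-connected component
#' of pixels whose background-subtracted value is at least `min_height`
#' local background sigmas (and strictly positive), retained iff the
#' component has at least `min_area` pixels.  Masked pixels can never
#' belong to a spot.  Centroids are intensity weighted
#' (background-subtracted weights); the summed intensity is background
#' subtracted, with sigma from counting statistics
#' (`sqrt(sum counts + n_px * background variance)`); the d-spacing comes
#' from the detector geometry through [pixel_to_d()].  The output is
#' sorted by summed intensity, descending, ties broken by centroid
#' (slow, fast).
#'
#' @param frame an [image_frame()].
#' @param params a [spot_find_params()].
#' @param background optional precomputed [estimate_background()] result
#'   (one estimate per frame can be shared across all grid points).
#' @return data.frame with columns `slow`, `fast`, `area`,
#'   `height_sigma`, `I`, `sigI`, `d`; zero rows when nothing is found.
#' @export
find_spots <- function(frame, params, background = NULL) {
  stopifnot(inherits(frame, "image_frame"), inherits(params, "spot_find_params"))
  if (is.null(background)) background <- estimate_background(frame)
  v <- frame$raster
  excess <- v - background$level
  thr <- params$min_height * background$sigma
  cand <- excess >= thr & excess > 0
  if (!is.null(frame$mask)) cand <- cand & !frame$mask
  cand_idx <- which(cand)
  empty <- data.frame(slow = numeric(), fast = numeric(), area = integer(),
                      height_sigma = numeric(), I = numeric(),
                      sigI = numeric(), d = numeric())
  if (length(cand_idx) == 0) return(empty)
  lab <- label_components(cand_idx, nrow(v))
  ns <- nrow(v)
  slow <- ((cand_idx - 1L) %% ns) + 1L
  fast <- ((cand_idx - 1L) %/% ns) + 1L
  wgt <- excess[cand_idx]
  raw <- v[cand_idx]
  sig2 <- background$sigma[cand_idx]^2
  area <- tabulate(lab)
  keep_lab <- which(area >= params$min_area)
  if (length(keep_lab) == 0) return(empty)
  sum_w <- rowsum(wgt, lab)[, 1]
  cen_s <- rowsum(wgt * slow, lab)[, 1] / sum_w
  cen_f <- rowsum(wgt * fast, lab)[, 1] / sum_w
  sum_raw <- rowsum(raw, lab)[, 1]
  sum_sig2 <- rowsum(sig2, lab)[, 1]
  hmax <- vapply(split(wgt / pmax(sqrt(sig2), 1e-9), lab), max, 0)
  out <- data.frame(slow = cen_s, fast = cen_f, area = as.integer(area[sort(unique(lab))]),
                    height_sigma = hmax, I = sum_w,
                    sigI = sqrt(pmax(sum_raw, 0) + sum_sig2),
                    d = NA_real_)
  out <- out[out$area >= params$min_area, , drop = FALSE]
  out$d <- pixel_to_d(out$slow, out$fast, frame$geometry, frame$wavelength)
  out <- out[order(-out$I, out$slow, out$fast), , drop = FALSE]
  rownames(out) <- NULL
  out
}
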