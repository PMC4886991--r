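#' Build the spot-finding parameter grid
#'
#' All pairwise combinations of minimum spot height (background-sigma
#' units) and minimum spot area (connected pixels) are enumerated from a
#' median and a symmetric spread for each parameter, in unit steps
#' (heights `median - spread ... median + spread`, likewise areas).
#' Values below the validity floor (height <= 0, area < 1) are dropped;
#' the number dropped is recorded in attributes `dropped_heights` /
#' `dropped_areas`.  The grid is row-major with height as the outer
#' variable.
#'
#' @param height_median,height_spread spot-height median and half-range in
#'   sigma units.
#' @param area_median,area_spread spot-area median and half-range in pixels
#'   (integers).
#' @return data.frame with columns `min_height`, `min_area` and one row per
#'   grid point, ordered height-major; attributes `heights`, `areas`,
#'   `dropped_heights`, `dropped_areas`.
#' @examples
#' g <- build_grid(8, 7, 12, 10)   # the 15 x 21 = 315-point grid
#' nrow(g)
#' @export
build_grid <- function(height_median, height_spread, area_median, area_spread) {
  if (height_spread < 0 || area_spread < 0) stop("spreads must be non-negative")
  heights <- seq(height_median - height_spread, height_median + height_spread, by = 1)
  areas <- seq(area_median - area_spread, area_median + area_spread, by = 1)
  if (any(areas != round(areas))) stop("area values must be integers")
  dh <- sum(heights <= 0); da <- sum(areas < 1)
  heights <- heights[heights > 0]
  areas <- as.integer(areas[areas >= 1])
  if (length(heights) == 0 || length(areas) == 0)
    stop("empty grid after dropping invalid values (height <= 0 or area < 1)")
  grid <- expand.grid(min_area = areas, min_height = heights,
                      KEEP.OUT.ATTRS = FALSE)[, c("min_height", "min_area")]
  rownames(grid) <- NULL
  attr(grid, "heights") <- heights
  attr(grid, "areas") <- areas
  attr(grid, "dropped_heights") <- dh
  attr(grid, "dropped_areas") <- da
  grid
}

#' Median grid point of a parameter grid
#' @param grid a grid from [build_grid()].
#' @return one-row data.frame with the median `min_height` / `min_area`.
#' @export
grid_median_point <- function(grid) {
  h <- attr(grid, "heights"); a <- attr(grid, "areas")
  data.frame(min_height = h[ceiling(length(h) / 2)],
             min_area = a[ceiling(length(a) / 2)])
}

#' Two-step selection of the best integration result
#'
#' From the pool of per-grid-point integration results of one image:
#' (i) keep the `ceiling(epv_fraction * N)` results with the smallest
#' Ewald proximal volume; (ii) among those return the result with the most
#' strong reflections, i.e. reflections with `I/sigma(I)` strictly above
#' `strong_threshold`.  Ties on EPV in step (i) are broken by more
#' reflections, then by grid order; ties on the strong count in step (ii)
#' by smaller EPV, then grid order.  The outcome is invariant under
#' permutation of the input list.
#'
#' @param results non-empty list of `integration_result` objects (each
#'   carrying `epv`, a reflection table, and its `grid_index`).
#' @param epv_fraction fraction of smallest-EPV results kept in step (i)
#'   (default 0.25).
#' @param strong_threshold I/sigma(I) threshold defining a strong
#'   reflection (default 5, strict inequality).
#' @return the selected `integration_result`.
#' @export
select_best <- function(results, epv_fraction = 0.25, strong_threshold = 5) {
  if (length(results) == 0) stop("no integration results")
  epv <- vapply(results, function(r) r$epv, 0)
  nref <- vapply(results, function(r) nrow(r$reflections), 0L)
  gidx <- vapply(results, function(r) as.integer(r$grid_index), 0L)
  nstrong <- vapply(results, function(r)
    sum(r$reflections$I / r$reflections$sigI > strong_threshold), 0L)
  keep_n <- ceiling(epv_fraction * length(results))
  ord <- order(epv, -nref, gidx)
  pool <- ord[seq_len(keep_n)]
  win <- pool[order(-nstrong[pool], epv[pool], gidx[pool])][1]
  out <- results[[win]]
  out$n_strong <- nstrong[win]
  out
}
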