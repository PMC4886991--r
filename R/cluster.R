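#' Hierarchical clustering of unit cells
#'
#' Partitions accepted integration results (or raw cells) into groups of
#' similar unit-cell parameters: agglomerative clustering with average
#' linkage on the [cell_distance()] metric over Niggli-reduced cells, cut
#' at `linkage_threshold`.  All clusters are reported, with the most
#' prevalent one (most members; ties broken by lower cluster index)
#' marked as dominant.
#'
#' @param results list of `integration_result` objects, or a list/matrix
#'   of numeric(6) cells (matrix rows are cells).
#' @param linkage_threshold cut height in cell-distance units
#'   (angstrom-scale; default 5.0: 0.5 percent cell noise stays together
#'   while a doubled axis separates).
#' @param ids optional image identifiers (defaults to result `image_id`s
#'   or index numbers).
#' @param angle_weight passed to [cell_distance()].
#' @return object of class `cluster_report`: list with `clusters` (each
#'   with `members`, `centroid_cell`, `spread`, `size`),
#'   `dominant_index`, `linkage_threshold`, `assignment`.
#' @export
cluster_cells <- function(results, linkage_threshold = 5.0, ids = NULL,
                          angle_weight = 0.5) {
  cells <- extract_cells(results)
  n <- nrow(cells)
  if (n == 0) stop("no accepted results to cluster")
  if (is.null(ids)) ids <- extract_ids(results, n)
  red <- t(apply(cells, 1, niggli_reduce))
  if (n == 1) {
    assignment <- 1L
  } else {
    scaled <- cbind(red[, 1:3], red[, 4:6] * angle_weight)
    dm <- stats::dist(scaled)
    hc <- stats::hclust(dm, method = "average")
    assignment <- stats::cutree(hc, h = linkage_threshold)
  }
  k <- max(assignment)
  clusters <- lapply(seq_len(k), function(ci) {
    sel <- assignment == ci
    sub <- red[sel, , drop = FALSE]
    list(members = ids[sel],
         centroid_cell = colMeans(sub),
         spread = apply(sub, 2, stats::sd),
         size = sum(sel))
  })
  sizes <- vapply(clusters, function(cl) cl$size, 0L)
  structure(list(clusters = clusters,
                 dominant_index = which.max(sizes),   # ties -> lowest index
                 linkage_threshold = linkage_threshold,
                 assignment = assignment),
            class = "cluster_report")
}

extract_cells <- function(results) {
  if (is.matrix(results)) return(results)
  rows <- lapply(results, function(r) {
    if (inherits(r, "integration_result")) r$lattice$cell
    else if (inherits(r, "still_fit")) r$best$lattice$cell
    else as.numeric(r)
  })
  do.call(rbind, rows)
}

extract_ids <- function(results, n) {
  if (is.matrix(results) || is.numeric(results[[1]])) return(as.character(seq_len(n)))
  vapply(seq_along(results), function(i) {
    r <- results[[i]]
    id <- if (inherits(r, "integration_result")) r$image_id
          else if (inherits(r, "still_fit")) r$frame_id else ""
    if (nzchar(id)) id else as.character(i)
  }, "")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("unit-cell clustering: %d cluster(s) at threshold %g\n",
              length(x$clusters), x$linkage_threshold))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %scluster %d: %d member(s), cell (%s)\n",
                if (i == x$dominant_index) "*" else " ", i, cl$size,
                paste(signif(cl$centroid_cell, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Heat map of selected grid points
#'
#' Counts, over the selected best integration results (one per image),
#' how many images chose each (min spot height, min spot area) grid
#' point.  The matrix total equals the number of integrated images.
#'
#' @param best_results list of `integration_result` (or `still_fit`)
#'   objects, one per integrated image.
#' @param grid the parameter grid from [build_grid()].
#' @return integer matrix, rows = grid heights, columns = grid areas
#'   (dimnames give the values).
#' @export
heatmap_counts <- function(best_results, grid) {
  heights <- attr(grid, "heights"); areas <- attr(grid, "areas")
  m <- matrix(0L, length(heights), length(areas),
              dimnames = list(height = as.character(heights),
                              area = as.character(areas)))
  for (r in best_results) {
    if (inherits(r, "still_fit")) r <- r$best
    if (is.null(r)) next
    i <- match(r$grid_point[1], heights)
    j <- match(r$grid_point[2], areas)
    if (is.na(i) || is.na(j))
      stop("grid point (", r$grid_point[1], ", ", r$grid_point[2],
           ") outside the supplied grid")
    m[i, j] <- m[i, j] + 1L
  }
  m
}

#' Summarize a processing run
#'
#' Writes the run-level analytics to `out_dir`: `summary.tsv` (image
#' accounting: total, no-diffraction, not-integrated, failed-filter, and
#' per-cluster counts), `beam_centers.tsv` (refined direct-beam scatter,
#' one row per integrated image), `resolution_hist.tsv` (histogram of
#' per-image limiting resolutions, taken as the highest-resolution
#' integrated reflection), `heatmap.tsv` (selected grid-point counts),
#' `clusters.json`, and `downstream_params.txt`, a key=value stub for
#' downstream scaling/merging listing the dominant cluster's images, its
#' centroid cell and the lowest-symmetry Laue class of the requested
#' Bravais lattice.
#'
#' @param run a `still_run` from [process_dataset()].
#' @param cluster_report optional [cluster_cells()] result (computed from
#'   the run's integrated images if NULL).
#' @param out_dir output directory (created if needed).
#' @param bravais Bravais symbol used for the Laue-class line of the
#'   downstream stub (default "aP" if unknown).
#' @param linkage_threshold used when `cluster_report` is NULL.
#' @return invisibly, a list with the tables written (`counts`,
#'   `beam_centers`, `resolution_hist`, `heatmap`, `clusters`,
#'   `downstream`).
#' @export
summarize_run <- function(run, cluster_report = NULL, out_dir,
                          bravais = "aP", linkage_threshold = 5.0) {
  stopifnot(inherits(run, "still_run"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- length(run$ids)
  kept <- vapply(run$triage, function(t) t$keep, TRUE)
  has_fit <- !vapply(run$fits, is.null, TRUE)
  integrated <- vapply(run$fits, function(f) !is.null(f) && !is.null(f$best), TRUE)
  filtered_out <- vapply(run$fits, function(f)
    !is.null(f) && is.null(f$best) && f$n_filtered > 0 &&
      length(f$results) == 0, TRUE)

  best <- lapply(run$fits[integrated], function(f) f$best)
  ids_int <- run$ids[integrated]

  if (is.null(cluster_report) && length(best) > 0)
    cluster_report <- cluster_cells(best, linkage_threshold = linkage_threshold,
                                    ids = ids_int)

  counts <- data.frame(
    category = c("total", "no_diffraction", "not_integrated", "failed_filter",
                 if (!is.null(cluster_report))
                   paste0("cluster_", seq_along(cluster_report$clusters))),
    count = c(n, sum(!kept), sum(kept & !integrated & !filtered_out),
              sum(filtered_out),
              if (!is.null(cluster_report))
                vapply(cluster_report$clusters, function(cl) cl$size, 0L)))

  bc <- do.call(rbind, lapply(which(integrated), function(i) {
    m <- run$fits[[i]]$best$lattice
    data.frame(image = run$ids[i], slow = m$beam_center_refined[1],
               fast = m$beam_center_refined[2])
  }))
  if (is.null(bc)) bc <- data.frame(image = character(), slow = numeric(),
                                    fast = numeric())

  dlim <- vapply(run$fits[integrated], function(f)
    min(f$best$reflections$d), 0)
  if (length(dlim) > 0) {
    h <- graphics::hist(dlim, breaks = "Sturges", plot = FALSE)
    rhist <- data.frame(d_low = h$breaks[-length(h$breaks)],
                        d_high = h$breaks[-1], n_images = h$counts)
  } else rhist <- data.frame(d_low = numeric(), d_high = numeric(),
                             n_images = integer())

  hm <- heatmap_counts(best, run$grid)
  hm_df <- as.data.frame(as.table(hm), stringsAsFactors = FALSE)
  names(hm_df) <- c("min_height", "min_area", "n_images")

  tsv <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                           sep = "\t", row.names = FALSE,
                                           quote = FALSE)
  tsv(counts, "summary.tsv")
  tsv(bc, "beam_centers.tsv")
  tsv(rhist, "resolution_hist.tsv")
  tsv(hm_df, "heatmap.tsv")

  clusters_json <- NULL
  downstream <- character()
  if (!is.null(cluster_report)) {
    clusters_json <- lapply(seq_along(cluster_report$clusters), function(i) {
      cl <- cluster_report$clusters[[i]]
      list(index = i, dominant = (i == cluster_report$dominant_index),
           size = cl$size, centroid_cell = round(unname(cl$centroid_cell), 4),
           members = cl$members)
    })
    jsonlite::write_json(clusters_json, file.path(out_dir, "clusters.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    dom <- cluster_report$clusters[[cluster_report$dominant_index]]
    downstream <- c(
      sprintf("n_images=%d", dom$size),
      sprintf("image_list=%s", paste(dom$members, collapse = ",")),
      sprintf("unit_cell=%s", paste(signif(dom$centroid_cell, 6), collapse = " ")),
      sprintf("laue_class=%s", lowest_laue_class(bravais)))
    writeLines(downstream, file.path(out_dir, "downstream_params.txt"))
  }
  invisible(list(counts = counts, beam_centers = bc, resolution_hist = rhist,
                 heatmap = hm, clusters = clusters_json,
                 downstream = downstream))
}
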