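test_that("identical cells form a single cluster; infinite threshold coarsens", {
  cells <- do.call(rbind, rep(list(hewl_cell()), 5))
  rep1 <- cluster_cells(cells, linkage_threshold = 5)
  expect_equal(length(rep1$clusters), 1)
  expect_equal(rep1$clusters[[1]]$size, 5)

  mixed <- rbind(short_form_cell(), long_form_cell())
  rep2 <- cluster_cells(mixed, linkage_threshold = 1e9)
  expect_equal(length(rep2$clusters), 1)
})

test_that("the two crystal forms separate with full purity", {
  # 60/40 mix of the short and long unit-cell forms with 0.3% noise
  set.seed(5)
  n1 <- 12; n2 <- 8
  cells <- rbind(
    t(replicate(n1, short_form_cell() * c(rnorm(3, 1, 0.003), 1, 1, 1))),
    t(replicate(n2, long_form_cell() * c(rnorm(3, 1, 0.003), 1, 1, 1))))
  labels <- rep(c("short", "long"), c(n1, n2))
  rep <- cluster_cells(cells, linkage_threshold = 5)
  expect_equal(length(rep$clusters), 2)
  # purity: each cluster contains one form only
  for (cl in rep$clusters) {
    forms <- labels[as.integer(cl$members)]
    expect_equal(length(unique(forms)), 1)
  }
  # dominant cluster is the 60% (short) form
  dom <- rep$clusters[[rep$dominant_index]]
  expect_equal(dom$size, n1)
  expect_true(all(labels[as.integer(dom$members)] == "short"))
})

test_that("heat map counts conserve the number of integrated images", {
  grid <- build_grid(4, 1, 5, 2)
  mk <- function(h, a) {
    r <- integration_result(data.frame(h = 1L, k = 0L, l = 0L, I = 10,
                                       sigI = 1, d = 4),
                            lattice = NULL, epv = 1e-3, grid_point = c(h, a),
                            grid_index = 1L)
    r
  }
  res <- list(mk(4, 5), mk(4, 5), mk(4, 5), mk(3, 6))
  m <- heatmap_counts(res, grid)
  expect_equal(sum(m), 4)
  expect_equal(m["4", "5"], 3, ignore_attr = TRUE)
  expect_equal(m["3", "6"], 1, ignore_attr = TRUE)
  expect_error(heatmap_counts(list(mk(9, 5)), grid), "outside")
})

test_that("run summary partitions the image set and writes all tables", {
  # small end-to-end run: 5 frames, 2 blank, tiny grid
  det <- std_detector()
  frames <- lapply(1:5, function(i) {
    tr <- random_crystal(hewl_cell(), c(400, 600), c(0.001, 0.003), 100 + i)
    tr$is_blank <- i <= 2
    render_still(tr, det, rng_seed = 100 + i, sigma_px = 1.0,
                 intensity_mean = 5000)$frame
  })
  grid <- build_grid(4, 0, 5, 0)
  run <- process_dataset(frames, hewl_cell(), grid, min_spots = 10)
  out <- withr::local_tempdir()
  rep <- summarize_run(run, out_dir = out, bravais = "tP")

  counts <- rep$counts
  n_clustered <- sum(counts$count[grepl("cluster", counts$category)])
  accounted <- sum(counts$count[counts$category %in%
                     c("no_diffraction", "not_integrated", "failed_filter")]) +
    n_clustered
  expect_equal(accounted, 5)
  expect_equal(counts$count[counts$category == "total"], 5)
  expect_equal(counts$count[counts$category == "no_diffraction"], 2)

  expect_equal(nrow(rep$beam_centers), n_clustered)
  expect_equal(sum(rep$heatmap), n_clustered)
  expect_true(all(file.exists(file.path(out,
    c("summary.tsv", "beam_centers.tsv", "resolution_hist.tsv",
      "heatmap.tsv", "clusters.json", "downstream_params.txt")))))
  stub <- readLines(file.path(out, "downstream_params.txt"))
  expect_true(any(grepl("laue_class=P4/m", stub)))
})
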