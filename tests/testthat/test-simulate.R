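test_that("random_crystal honours degenerate ranges and is deterministic", {
  t1 <- random_crystal(c(79, 79, 38, 90, 90, 90), c(500, 500),
                       c(0.001, 0.001), rng_seed = 1)
  expect_equal(t1$mosaic_block_size_D, 500)
  expect_equal(t1$mosaic_angle_eta, 0.001)
  expect_equal(det(t1$orientation), 1, tolerance = 1e-12)
  t2 <- random_crystal(c(79, 79, 38, 90, 90, 90), c(500, 500),
                       c(0.001, 0.001), rng_seed = 1)
  expect_identical(t1, t2)
  expect_error(random_crystal(c(-1, 79, 38, 90, 90, 90), c(500, 500),
                              c(0.001, 0.001), 1), "edge a")
})

test_that("orientation sampling is uniform over axis directions", {
  # chi-square on octant counts of the rotation axis over many draws
  n <- 4000
  octant <- integer(n)
  for (i in seq_len(n)) {
    tr <- random_crystal(c(10, 10, 10, 90, 90, 90), c(100, 100), c(0, 0), i)
    R <- tr$orientation
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    octant[i] <- 1 + (ax[1] > 0) + 2 * (ax[2] > 0) + 4 * (ax[3] > 0)
  }
  p <- chisq.test(tabulate(octant, 8), p = rep(1 / 8, 8))$p.value
  expect_gt(p, 0.01)
})

test_that("rendering respects the spot-width cutoff and conserves intensity", {
  det <- std_detector()
  # w -> 0 limit: enormous mosaic blocks, no rotational spread
  tr <- random_crystal(hewl_cell(), c(1e8, 1e8), c(0, 0), 5)
  rs <- render_still(tr, det, background_mean = 0, rng_seed = 5, noise = FALSE)
  expect_lt(nrow(rs$manifest), 3)   # measure-zero condition: 0-few spots

  # conservation: zero background, total counts match manifest intensity
  rs2 <- quick_still(7, background_mean = 0, noise = FALSE)
  on_det <- rs2$manifest$on_detector
  expect_gt(sum(on_det), 10)
  total_true <- sum(rs2$manifest$intensity[on_det])
  expect_equal(sum(as.numeric(rs2$frame$raster)), total_true,
               tolerance = 0.02)

  # all manifest entries obey the proximity condition
  w <- spot_width(rs2$manifest$d, 500, 0.002)
  expect_true(all(abs(rs2$manifest$delta_r) <= w / 2))
  expect_true(all(rs2$manifest$d >= 3.5))
})

test_that("blank frames contain only background", {
  det <- std_detector()
  tr <- random_crystal(hewl_cell(), c(500, 500), c(0.002, 0.002), 3)
  tr$is_blank <- TRUE
  rs <- render_still(tr, det, background_mean = 20, rng_seed = 3)
  expect_equal(nrow(rs$manifest), 0)
  # Poisson(20): no pixel's expected value exceeds the background
  expect_lt(mean(rs$frame$raster), 21)
  expect_lt(max(rs$frame$raster), 60)
})

test_that("generate_dataset writes frames plus a reproducible manifest", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  pops <- list(list(cell = short_form_cell(), weight = 0.5),
               list(cell = long_form_cell(), weight = 0.5))
  det <- detector_geometry(96, 96, 0.1, 50, c(48.5, 48.5))
  m1 <- generate_dataset(8, blank_fraction = 0.25, populations = pops,
                         out_dir = dir1, rng_seed = 11, det = det)
  m2 <- generate_dataset(8, blank_fraction = 0.25, populations = pops,
                         out_dir = dir2, rng_seed = 11, det = det)
  expect_equal(m1, m2)
  expect_identical(unname(tools::md5sum(file.path(dir1, "img_0001.img"))),
                   unname(tools::md5sum(file.path(dir2, "img_0001.img"))))
  expect_equal(nrow(m1), 8)
  expect_true(all(file.exists(file.path(dir1, m1$filename))))
  # cells drawn from the two populations only
  expect_true(all(m1$c %in% c(146.9, 291.9)))

  # blank_fraction = 1 flags everything blank
  dir3 <- withr::local_tempdir()
  m3 <- generate_dataset(5, blank_fraction = 1, populations = pops,
                         out_dir = dir3, rng_seed = 1, det = det)
  expect_true(all(m3$is_blank))
  expect_true(all(m3$n_reflections == 0))
})

test_that("mean rendered reflection count matches EPV * V_cell", {
  # cross-module consistency of the expected spot-count relation,
  # averaged over random orientations
  cell <- hewl_cell(); lambda <- 1.3; d_L <- 3.5
  D <- 500; eta <- 0.002
  n_or <- 60
  counts <- vapply(seq_len(n_or), function(i) {
    tr <- random_crystal(cell, c(D, D), c(eta, eta), 1000 + i)
    nodes <- stillgrid:::enumerate_nodes(cell, tr$orientation, d_L)
    dr <- sqrt(nodes$q[, 1]^2 + nodes$q[, 2]^2 +
               (nodes$q[, 3] + 1 / lambda)^2) - 1 / lambda
    sum(abs(dr) <= spot_width(nodes$d, D, eta) / 2)
  }, 0)
  expected <- expected_spot_count(compute_epv(D, eta, lambda, d_L), cell)
  expect_equal(mean(counts), expected, tolerance = 0.05)
})
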