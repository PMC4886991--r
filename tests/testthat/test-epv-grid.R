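test_that("spot width follows the two-parameter mosaic model", {
  # eta = 0: width is the constant base diameter 2/D at every resolution
  expect_equal(spot_width(c(1, 2, 10, 100), D = 500, eta = 0),
               rep(2 / 500, 4))
  # the eta term grows as 1/d
  eta <- 0.003
  expect_equal(spot_width(2, 500, eta) - spot_width(4, 500, eta),
               eta * (1 / 2 - 1 / 4), tolerance = 1e-12)
  # monotone: increasing in eta at fixed d, decreasing in D at fixed eta
  expect_gt(spot_width(3, 500, 0.004), spot_width(3, 500, 0.002))
  expect_gt(spot_width(3, 250, 0.002), spot_width(3, 500, 0.002))
  expect_error(spot_width(-1, 500, 0), "positive")
  expect_error(spot_width(3, -5, 0), "positive")
})

test_that("EPV quadrature converges and obeys its limits", {
  epv_128 <- compute_epv(500, 0.002, 1.3, 3.5, quadrature_points = 128)
  epv_256 <- compute_epv(500, 0.002, 1.3, 3.5, quadrature_points = 256)
  expect_equal(epv_128, epv_256, tolerance = 1e-6)
  # perfect-crystal limit: w -> 0 so the volume vanishes
  expect_lt(compute_epv(1e9, 0, 1.3, 3.5), 1e-8)
  expect_error(compute_epv(500, 0.002, 1.3, 0.5), "unreachable")
  expect_error(compute_epv(500, 0.002, 1.3, 3.5, quadrature_points = 4),
               "at least 16")
})

test_that("EPV is strictly monotone in the mosaic parameters", {
  # finite-difference checks at several points
  for (eta in seq(0, 0.0045, length.out = 10)) {
    expect_gt(compute_epv(500, eta + 5e-4, 1.3, 3.5),
              compute_epv(500, eta, 1.3, 3.5))
  }
  for (D in seq(100, 2000, length.out = 10)) {
    expect_gt(compute_epv(D, 0.002, 1.3, 3.5),
              compute_epv(D * 1.2, 0.002, 1.3, 3.5))
  }
})

test_that("EPV matches the Monte-Carlo volume oracle", {
  # quick version (the full 1e7-sample sweep runs in the acceptance suite)
  for (ps in list(c(500, 0.002), c(100, 0.001), c(2000, 0.005))) {
    q <- compute_epv(ps[1], ps[2], 1.3, 3.5)
    mc <- mc_epv_oracle(ps[1], ps[2], 1.3, 3.5, n_samples = 1e6, seed = 7)
    expect_equal(q, mc, tolerance = 0.01)
  }
})

test_that("expected spot count scales linearly with cell volume", {
  expect_equal(expected_spot_count(0, hewl_cell()), 0)
  epv <- 1.2e-3
  n1 <- expected_spot_count(epv, c(50, 60, 70, 90, 90, 90))
  n2 <- expected_spot_count(epv, c(100, 60, 70, 90, 90, 90))
  expect_equal(n2, 2 * n1, tolerance = 1e-12)
  expect_equal(n1, epv * 50 * 60 * 70, tolerance = 1e-12)
})

test_that("grid construction enumerates unit steps with validity flooring", {
  g <- build_grid(8, 7, 12, 10)
  expect_equal(length(attr(g, "heights")), 15)
  expect_equal(length(attr(g, "areas")), 21)
  expect_equal(nrow(g), 315)
  # row-major, height outer
  expect_equal(g$min_height[1:21], rep(1, 21))
  expect_equal(g$min_area[1:21], 2:22)

  g1 <- build_grid(5, 0, 5, 0)
  expect_equal(nrow(g1), 1)
  expect_equal(unlist(g1), c(min_height = 5, min_area = 5))

  # flooring: heights {-1, 0} dropped
  g2 <- build_grid(2, 3, 5, 0)
  expect_equal(attr(g2, "heights"), 1:5)
  expect_equal(nrow(g2), 5)
  expect_equal(attr(g2, "dropped_heights"), 2)
  expect_error(build_grid(-5, 1, 5, 0), "empty grid")
})
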