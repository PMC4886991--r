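test_that("cell validation names the offending parameter", {
  expect_error(validate_cell(c(-1, 10, 10, 90, 90, 90)), "edge a")
  expect_error(validate_cell(c(10, 10, 10, 90, 90, 200)), "angle gamma")
  # geometrically impossible angle combination
  expect_error(validate_cell(c(10, 10, 10, 170, 170, 170)), "determinant")
  expect_silent(validate_cell(c(79.1, 79.1, 38.4, 90, 90, 90)))
})

test_that("cell volume and reciprocal matrix are mutually consistent", {
  cell <- c(10, 20, 30, 80, 95, 100)
  A <- direct_matrix(cell)
  expect_equal(abs(det(A)), cell_volume(cell), tolerance = 1e-12)
  B <- reciprocal_matrix(cell)
  expect_equal(t(B) %*% A, diag(3), tolerance = 1e-12)
})

test_that("Niggli reduction reproduces reference reduced cells", {
  # frozen oracle values (external cell-reduction reference)
  expect_equal(niggli_reduce(c(79, 79, 38, 90, 90, 90)),
               c(38, 79, 79, 90, 90, 90), tolerance = 1e-6)
  expect_equal(niggli_reduce(c(146.9, 69.1, 171.6, 90, 90, 90)),
               c(69.1, 146.9, 171.6, 90, 90, 90), tolerance = 1e-6)
  expect_equal(niggli_reduce(c(10, 20, 30, 100, 80, 95)),
               c(10, 20, 29.930103, 98.333454, 99.210267, 95), tolerance = 1e-5)
})

test_that("Niggli reduction is idempotent and setting-invariant", {
  cells <- list(c(69.1, 146.9, 171.6, 90, 90, 90),
                c(100, 100, 100, 90, 90, 90),
                c(10, 20, 29.93, 98.33, 99.21, 95))
  for (cell in cells) {
    red <- niggli_reduce(cell)
    expect_equal(niggli_reduce(red), red, tolerance = 1e-6)
  }
  # a sheared setting of the same lattice reduces to the same cell:
  # basis (a, b, c) -> (a, b, a + c)
  A <- direct_matrix(c(10, 20, 30, 90, 90, 90))
  A2 <- A %*% matrix(c(1, 0, 1, 0, 1, 0, 0, 0, 1), 3, 3)
  G <- crossprod(A2)
  sheared <- stillgrid:::metric_to_cell(G)
  expect_equal(niggli_reduce(sheared), niggli_reduce(c(10, 20, 30, 90, 90, 90)),
               tolerance = 1e-6)
})

test_that("cell distance is a symmetric separation measure on reduced cells", {
  a <- short_form_cell(); b <- long_form_cell()
  expect_equal(cell_distance(a, a), 0, tolerance = 1e-9)
  expect_equal(cell_distance(a, b), cell_distance(b, a), tolerance = 1e-12)
  # the two crystal forms are far apart compared to 0.5% cell noise
  noisy <- a * c(1.005, 1.005, 1.005, 1, 1, 1)
  expect_gt(cell_distance(a, b), 10 * cell_distance(a, noisy))
})

test_that("Bravais filter keeps matching cells and drops skewed ones", {
  expect_true(bravais_filter(c(69.1, 171.6, 146.9, 90, 90, 90), "oP"))
  expect_false(bravais_filter(c(69.1, 171.6, 146.9, 90, 95, 90), "oP",
                              angle_tol = 1))
  # monotone in tolerance
  expect_true(bravais_filter(c(69.1, 171.6, 146.9, 90, 95, 90), "oP",
                             angle_tol = 10))
  # target-cell comparison
  expect_true(bravais_filter(c(69.4, 171.0, 147.5, 90, 90, 90), "oP",
                             target_cell = short_form_cell()))
  expect_false(bravais_filter(long_form_cell(), "oP",
                              target_cell = short_form_cell()))
})

test_that("lowest Laue class lookup matches crystallographic tables", {
  expect_equal(lowest_laue_class("tP"), "P4/m")
  expect_equal(lowest_laue_class("oP"), "Pmmm")
  expect_equal(lowest_laue_class("cP"), "Pm-3")
  expect_equal(lowest_laue_class("aP"), "P-1")
  expect_error(lowest_laue_class("xQ"), "unknown")
})
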