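test_that("noiseless stills index to sub-0.1-degree orientations", {
  cell <- hewl_cell(); det <- std_detector()
  syms <- lattice_symmetry_ops("tetragonal")
  B <- reciprocal_matrix(cell)
  for (seed in c(2, 5, 8)) {
    rs <- quick_still(seed, D = 2000, eta = 5e-4, background_mean = 0,
                      noise = FALSE, intensity_mean = 3000)
    sp <- find_spots(rs$frame, spot_find_params(4, 5))
    m <- fit_orientation(sp, cell, det, 1.3)
    expect_s3_class(m, "lattice_model")
    m <- refine_lattice(m, sp, det, 1.3)
    expect_lt(orientation_difference(m$orientation, rs$truth$orientation,
                                     syms, B), 0.1)
    # refined cell within 0.1% of truth
    expect_lt(max(abs(m$cell[1:3] - cell[1:3]) / cell[1:3]), 0.001)
  }
})

test_that("indexing failure modes carry informative reasons", {
  det <- std_detector()
  empty <- data.frame(slow = numeric(), fast = numeric(), I = numeric())
  f1 <- fit_orientation(empty, hewl_cell(), det, 1.3)
  expect_s3_class(f1, "lattice_failure")
  expect_match(f1$reason, "insufficient spots")

  # random junk positions do not index
  set.seed(9)
  junk <- data.frame(slow = runif(40, 20, 380), fast = runif(40, 20, 380),
                     I = runif(40, 10, 100))
  f2 <- fit_orientation(junk, hewl_cell(), det, 1.3)
  expect_s3_class(f2, "lattice_failure")
  expect_match(f2$reason, "indexing failed")
})

test_that("refinement is a guarded fixed point and recovers a beam offset", {
  cell <- hewl_cell(); det <- std_detector()
  rs <- quick_still(12, D = 2000, eta = 5e-4, background_mean = 0,
                    noise = FALSE, intensity_mean = 3000)
  sp <- find_spots(rs$frame, spot_find_params(4, 5))
  m1 <- refine_lattice(fit_orientation(sp, cell, det, 1.3), sp, det, 1.3)
  # refining an already-optimal model leaves parameters unchanged
  m2 <- refine_lattice(m1, sp, det, 1.3)
  expect_lte(m2$rmsd_obs_pred, m1$rmsd_obs_pred + 1e-9)
  expect_equal(m2$cell, m1$cell, tolerance = 1e-4)
  expect_equal(m2$beam_center_refined, m1$beam_center_refined,
               tolerance = 0.05)

  # a deliberately mis-stated beam center (2 px) is recovered within 0.3 px
  det_off <- det; det_off$beam_center <- det$beam_center - c(2, 0)
  fr_off <- image_frame(rs$frame$raster, det_off, 1.3, source_id = "off")
  sp_off <- find_spots(fr_off, spot_find_params(4, 5))
  mo <- fit_orientation(sp_off, cell, det_off, 1.3)
  expect_s3_class(mo, "lattice_model")
  mo <- refine_lattice(mo, sp_off, det_off, 1.3)
  expect_lt(max(abs(mo$beam_center_refined - det$beam_center)), 0.3)
})

test_that("mosaic estimation recovers parameters and is monotone in eta", {
  cell <- hewl_cell(); det <- std_detector()
  # recovery within 50% (coverage criterion) on a dense noiseless list
  rs <- quick_still(23, D = 500, eta = 0.002, background_mean = 0,
                    noise = FALSE, intensity_mean = 4000)
  sp <- find_spots(rs$frame, spot_find_params(4, 5))
  m <- refine_lattice(fit_orientation(sp, cell, det, 1.3), sp, det, 1.3)
  m <- estimate_mosaic(m, sp, det, 1.3, strong_height = 0)
  expect_lt(abs(m$mosaic_block_size_D - 500) / 500, 0.5)
  expect_lt(abs(m$mosaic_angle_eta - 0.002) / 0.002, 0.5)

  # larger true eta -> larger estimate (3-point sweep)
  est <- vapply(c(0.001, 0.003, 0.006), function(eta) {
    rs <- quick_still(17, D = 2000, eta = eta, background_mean = 0,
                      noise = FALSE, intensity_mean = 4000)
    sp <- find_spots(rs$frame, spot_find_params(4, 5))
    m <- refine_lattice(fit_orientation(sp, cell, det, 1.3), sp, det, 1.3)
    estimate_mosaic(m, sp, det, 1.3, strong_height = 0)$mosaic_angle_eta
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("a single on-sphere node yields the minimal scanned mosaic model", {
  # cubic 100 A cell; rotate node (1,0,0) exactly onto the Ewald sphere
  cell <- c(100, 100, 100, 90, 90, 90)
  lambda <- 1.3; r0 <- 1 / lambda; qlen <- 0.01
  cz <- -qlen^2 * lambda / 2
  cx <- sqrt(qlen^2 - cz^2)
  th <- atan2(-cz, cx)
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)   # rotation about y
  model <- lattice_model(cell, R, c(200.5, 200.5))
  model$hkl <- matrix(c(1, 0, 0), 1, 3)
  model$indexed <- TRUE
  model$used_idx <- 1L
  spots <- data.frame(slow = 1, fast = 1, height_sigma = 10)
  m <- estimate_mosaic(model, spots, std_detector(), lambda)
  expect_equal(m$mosaic_angle_eta, 0)
  expect_equal(m$mosaic_block_size_D, 5000)
  expect_false(m$mosaic_saturated)

  # an impossibly distant node saturates the scan
  model$hkl <- matrix(c(0, 0, 5), 1, 3)
  model$orientation <- diag(3)
  m2 <- estimate_mosaic(model, spots, std_detector(), lambda)
  expect_true(m2$mosaic_saturated)
})

test_that("predictions obey the resolution limit and the w -> 0 limit", {
  cell <- hewl_cell(); det <- std_detector()
  rs <- quick_still(12, D = 2000, eta = 5e-4, background_mean = 0,
                    noise = FALSE, intensity_mean = 3000)
  sp <- find_spots(rs$frame, spot_find_params(4, 5))
  m <- refine_lattice(fit_orientation(sp, cell, det, 1.3), sp, det, 1.3)
  m$mosaic_block_size_D <- 2000; m$mosaic_angle_eta <- 5e-4
  pr <- predict_reflections(m, det, 1.3, 3.5)
  expect_true(all(pr$d >= 3.5))
  w <- spot_width(pr$d, 2000, 5e-4)
  expect_true(all(abs(pr$delta_r) <= w / 2))
  # near-perfect crystal: the proximal volume is essentially empty
  m$mosaic_block_size_D <- 1e8; m$mosaic_angle_eta <- 0
  expect_lt(nrow(predict_reflections(m, det, 1.3, 3.5)), 3)
})

test_that("integration recovers truth on clean data and nulls on blanks", {
  cell <- hewl_cell(); det <- std_detector()
  rs <- quick_still(12, D = 2000, eta = 5e-4, background_mean = 0,
                    noise = FALSE, intensity_mean = 3000)
  sp <- find_spots(rs$frame, spot_find_params(4, 5))
  m <- refine_lattice(fit_orientation(sp, cell, det, 1.3), sp, det, 1.3)
  m <- estimate_mosaic(m, sp, det, 1.3, strong_height = 0)
  pr <- predict_reflections(m, det, 1.3, 3.5)
  ii <- integrate_reflections(rs$frame, pr, radius_px = 3)
  # the fitted orientation may relabel hkl by a lattice symmetry op, so
  # match integrated reflections to the rendered manifest by detector
  # position (join back through the prediction table)
  key <- function(h, k, l) paste(h, k, l)
  pos <- pr[match(key(ii$reflections$h, ii$reflections$k, ii$reflections$l),
                  key(pr$h, pr$k, pr$l)), c("slow", "fast")]
  man <- rs$manifest[rs$manifest$on_detector, ]
  idx <- vapply(seq_len(nrow(pos)), function(i) {
    d2 <- (man$slow - pos$slow[i])^2 + (man$fast - pos$fast[i])^2
    j <- which.min(d2)
    if (d2[j] < 1) j else NA_integer_
  }, 1L)
  ok <- !is.na(idx) & man$intensity[ifelse(is.na(idx), 1, idx)] > 500
  expect_gt(sum(ok), 20)
  relerr <- abs(ii$reflections$I[ok] - man$intensity[idx[ok]]) /
    man$intensity[idx[ok]]
  expect_lt(median(relerr), 0.05)

  # blank frame: intensities consistent with zero
  tr <- random_crystal(cell, c(500, 500), c(0.002, 0.002), 77)
  tr$is_blank <- TRUE
  blank <- render_still(tr, det, background_mean = 20, rng_seed = 77)$frame
  ib <- integrate_reflections(blank, pr)
  expect_gte(mean(abs(ib$reflections$I) < 3 * ib$reflections$sigI), 0.99)

  # predictions fully under a beam-stop mask are dropped and tallied
  masked <- rs$frame
  masked$mask <- make_beamstop_mask(det, 60)
  im <- integrate_reflections(masked, pr)
  expect_gt(im$n_dropped, 0)
  expect_equal(im$n_dropped + im$n_integrated, nrow(pr))
})

test_that("spots from a doubled axis index poorly against the short cell", {
  # the long crystal form doubles c; its odd-l reflections fall between
  # the short form's reciprocal nodes
  long <- long_form_cell(); short <- short_form_cell()
  det <- std_detector()
  truth <- random_crystal(long, c(4000, 4000), c(2e-4, 2e-4), 31)
  rs <- render_still(truth, det, background_mean = 0, d_min = 7,
                     rng_seed = 31, intensity_mean = 3000, noise = FALSE)
  sp <- find_spots(rs$frame, spot_find_params(4, 3))
  q <- pixel_to_q(sp$slow, sp$fast, det, 1.3)

  frac <- function(cell) {
    B <- reciprocal_matrix(cell)
    t_idx <- 0.15 * min(sqrt(colSums(B^2)))
    fit <- stillgrid:::polish_orientation(truth$orientation, q, B, solve(B),
                                          t_idx)
    fit$n_indexed / nrow(q)
  }
  f_long <- frac(long); f_short <- frac(short)
  # against the short cell the odd-l half of the reflections cannot index:
  # the fraction drops below the success threshold, well under the
  # correct-cell fraction
  expect_lt(f_short, 0.5)
  expect_lt(f_short, f_long - 0.2)
})
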