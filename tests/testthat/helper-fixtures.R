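# shared fixtures: a HEWL-like tetragonal cell on a small virtual detector

hewl_cell <- function() c(79.1, 79.1, 38.4, 90, 90, 90)

short_form_cell <- function() c(69.1, 171.6, 146.9, 90, 90, 90)
long_form_cell <- function() c(69.6, 171.1, 291.9, 90, 90, 90)

std_detector <- function() detector_geometry(400, 400, 0.1, 50, c(200.5, 200.5))

# quick rendered still (Poisson background 20, lambda 1.3, d_min 3.5)
quick_still <- function(seed, D = 500, eta = 0.002, sigma_px = 1.0,
                        intensity_mean = 4000, background_mean = 20,
                        noise = TRUE, cell = hewl_cell(),
                        det = std_detector()) {
  truth <- random_crystal(cell, c(D, D), c(eta, eta), seed)
  rs <- render_still(truth, det, background_mean = background_mean,
                     d_min = 3.5, rng_seed = seed, sigma_px = sigma_px,
                     intensity_mean = intensity_mean, noise = noise)
  rs$truth <- truth
  rs
}

# small flat Poisson frame for spot-finder tests
flat_frame <- function(mean = 50, n = 128, seed = 1) {
  set.seed(seed)
  raster <- matrix(rpois(n * n, mean), n, n)
  image_frame(raster, detector_geometry(n, n, 0.1, 50, c((n + 1) / 2, (n + 1) / 2)), 1.3,
              source_id = "flat")
}

# drop one Gaussian blob of integrated intensity I at (s0, f0) onto a frame
with_blob <- function(frame, s0, f0, I, sigma_px = 2) {
  r <- stillgrid:::add_gaussian_spot(frame$raster + 0, s0, f0, I, sigma_px)
  r <- matrix(as.integer(round(r)), nrow(r), ncol(r))
  image_frame(r, frame$geometry, frame$wavelength, mask = frame$mask,
              source_id = frame$source_id)
}
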