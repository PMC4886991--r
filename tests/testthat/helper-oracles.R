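# Monte-Carlo volume oracle for the Ewald proximal volume, independent of
# the quadrature implementation: uniform points in the bounding spherical
# shell sector, accepted iff within w(d)/2 of the Ewald sphere.
mc_epv_oracle <- function(D, eta, lambda, d_L, n_samples = 1e6, seed = 1,
                          chunk = 1e6) {
  set.seed(seed)
  tau_max <- 2 * asin(lambda / (2 * d_L))
  w_max <- 2 / D + eta * 2 * sin(tau_max / 2) / lambda
  r0 <- 1 / lambda
  r_lo <- r0 - w_max / 2; r_hi <- r0 + w_max / 2
  c_lo <- cos(tau_max)
  vol_box <- (2 * pi) * (r_hi^3 - r_lo^3) / 3 * (1 - c_lo)
  n_acc <- 0; n_done <- 0
  while (n_done < n_samples) {
    m <- min(chunk, n_samples - n_done)
    r <- (r_lo^3 + runif(m) * (r_hi^3 - r_lo^3))^(1 / 3)
    ct <- c_lo + runif(m) * (1 - c_lo)
    tau <- acos(ct)
    w <- 2 / D + eta * 2 * sin(tau / 2) / lambda
    n_acc <- n_acc + sum(abs(r - r0) <= w / 2)
    n_done <- n_done + m
  }
  vol_box * n_acc / n_samples
}

# index-arithmetic oracle for recentering: expected padding on one axis
recenter_pad_oracle <- function(n, bc) {
  delta <- round(n + 1 - 2 * bc)
  if (delta >= 0) c(low = delta, high = 0) else c(low = 0, high = -delta)
}
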