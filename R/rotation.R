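#' Rotation and quaternion helpers
#'
#' Orientations are proper rotations (3x3, det = +1).  Uniform sampling over
#' the rotation group uses the Shoemake subgroup-algorithm map from three
#' uniform variates to a unit quaternion; deterministic low-discrepancy
#' orientation sets (used by the coarse indexing search) feed the same map
#' with a Halton sequence in bases 2, 3, 5.
#'
#' @name rotations
#' @keywords internal
NULL

quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# Shoemake map: three variates in [0,1) -> uniform unit quaternion
shoemake_quat <- function(u) {
  s1 <- sqrt(1 - u[, 1]); s2 <- sqrt(u[, 1])
  t1 <- 2 * pi * u[, 2]; t2 <- 2 * pi * u[, 3]
  cbind(s1 * sin(t1), s1 * cos(t1), s2 * sin(t2), s2 * cos(t2))
}

#' Draw a uniform random rotation
#' @return 3x3 proper rotation matrix; uses the current RNG state.
#' @keywords internal
random_rotation <- function() {
  q <- shoemake_quat(matrix(stats::runif(3), 1, 3))[1, ]
  quat_to_rotmat(q)
}

# radical-inverse Halton sequence (deterministic)
halton_seq <- function(n, base) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; r <- 0; k <- i
    while (k > 0) {
      f <- f / base
      r <- r + f * (k %% base)
      k <- k %/% base
    }
    out[i] <- r
  }
  out
}

#' Deterministic low-discrepancy orientation set
#' @param n number of orientations.
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @keywords internal
halton_quaternions <- function(n) {
  u <- cbind(halton_seq(n, 2), halton_seq(n, 3), halton_seq(n, 5))
  shoemake_quat(u)
}

#' Angle between two rotations
#' @param R1,R2 3x3 rotation matrices.
#' @return rotation angle of `t(R1) %*% R2` in degrees.
#' @export
rotation_angle <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' Smallest orientation difference up to lattice symmetry
#'
#' The orientation recovered by indexing is defined only up to a proper
#' rotation of the lattice point group; this returns the minimum
#' misorientation angle over the supplied symmetry operations.
#'
#' @param R_fit,R_true 3x3 rotations.
#' @param ops list of 3x3 integer matrices acting on Miller indices
#'   (default: the proper point group of an orthorhombic/tetragonal cell
#'    from [lattice_symmetry_ops()]).
#' @param B reciprocal matrix of the cell (needed to express index-space
#'   operations in Cartesian space).
#' @return misorientation angle in degrees.
#' @export
orientation_difference <- function(R_fit, R_true, ops, B) {
  best <- Inf
  for (op in ops) {
    S <- B %*% op %*% solve(B)   # Cartesian action of the index-space op
    best <- min(best, rotation_angle(R_fit %*% S, R_true))
  }
  best
}

#' Proper point-group operations of a lattice (index space)
#'
#' Returns the proper rotations, as integer matrices acting on (h, k, l),
#' that map the lattice onto itself; used to compare fitted orientations to
#' ground truth.  Covers orthorhombic (222) and tetragonal (422 about c).
#'
#' @param kind `"orthorhombic"` or `"tetragonal"` (4-fold along c).
#' @return list of 3x3 integer matrices with determinant +1.
#' @export
lattice_symmetry_ops <- function(kind = c("orthorhombic", "tetragonal")) {
  kind <- match.arg(kind)
  d <- function(a, b, c) diag(c(a, b, c))
  ops <- list(d(1, 1, 1), d(1, -1, -1), d(-1, 1, -1), d(-1, -1, 1))
  if (kind == "tetragonal") {
    r4 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    extra <- list()
    for (op in ops) extra <- c(extra, list(r4 %*% op, r4 %*% r4 %*% op, t(r4) %*% op))
    ops <- c(ops, extra)
  }
  ops
}
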