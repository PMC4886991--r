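#' Unit-cell utilities
#'
#' A unit cell is a numeric vector of length six: edge lengths a, b, c in
#' angstrom and angles alpha, beta, gamma in degrees.  All cells handled by
#' this package are in the primitive setting, so the cell volume returned by
#' [cell_volume()] is the primitive-setting volume used in the expected
#' spot-count relation N_spot = EPV * V_cell.
#'
#' @param cell numeric(6): a, b, c (angstrom), alpha, beta, gamma (degrees).
#' @return `validate_cell` returns the cell invisibly (or stops);
#'   `cell_volume` the volume in cubic angstrom; `direct_matrix` the 3x3
#'   matrix whose columns are the direct-basis vectors in a Cartesian frame;
#'   `reciprocal_matrix` the 3x3 matrix B whose columns are the reciprocal
#'   basis vectors, so that a reciprocal node with Miller indices h is at
#'   `B %*% h`.
#' @name cell-utils
NULL

#' @rdname cell-utils
#' @export
validate_cell <- function(cell) {
  if (!is.numeric(cell) || length(cell) != 6L || anyNA(cell))
    stop("cell must be a numeric vector of 6 finite values (a, b, c, alpha, beta, gamma)")
  nm <- c("a", "b", "c", "alpha", "beta", "gamma")
  for (i in 1:3)
    if (cell[i] <= 0) stop("invalid cell: edge ", nm[i], " = ", cell[i], " must be > 0")
  for (i in 4:6)
    if (cell[i] <= 0 || cell[i] >= 180)
      stop("invalid cell: angle ", nm[i], " = ", cell[i], " must lie in (0, 180)")
  ca <- cos(cell[4] * pi / 180); cb <- cos(cell[5] * pi / 180); cg <- cos(cell[6] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0)
    stop("invalid cell: angles (alpha, beta, gamma) = (",
         paste(cell[4:6], collapse = ", "), ") give a non-positive metric determinant")
  invisible(cell)
}

#' @rdname cell-utils
#' @export
cell_volume <- function(cell) {
  validate_cell(cell)
  ca <- cos(cell[4] * pi / 180); cb <- cos(cell[5] * pi / 180); cg <- cos(cell[6] * pi / 180)
  cell[1] * cell[2] * cell[3] * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' @rdname cell-utils
#' @export
direct_matrix <- function(cell) {
  validate_cell(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  # a along x, b in the xy plane
  av <- c(a, 0, 0)
  bv <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  cbind(av, bv, c(cx, cy, cz), deparse.level = 0)
}

#' @rdname cell-utils
#' @export
reciprocal_matrix <- function(cell) {
  A <- direct_matrix(cell)
  t(solve(A))   # columns a*, b*, c*; satisfies t(B) %*% A == I
}

#' Metric tensor of a cell (direct space)
#' @param cell numeric(6) unit cell.
#' @return 3x3 symmetric matrix of basis-vector dot products.
#' @keywords internal
cell_metric <- function(cell) {
  A <- direct_matrix(cell)
  crossprod(A)
}

metric_to_cell <- function(G) {
  a <- sqrt(G[1, 1]); b <- sqrt(G[2, 2]); cc <- sqrt(G[3, 3])
  al <- acos(G[2, 3] / (b * cc)) * 180 / pi
  be <- acos(G[1, 3] / (a * cc)) * 180 / pi
  ga <- acos(G[1, 2] / (a * b)) * 180 / pi
  c(a, b, cc, al, be, ga)
}

#' Niggli reduction of a unit cell
#'
#' Canonical reduced setting of a lattice (Krivy & Gruber style algorithm on
#' the metric tensor), enabling comparison of cells indexed in different
#' settings.  Idempotent: reducing an already reduced cell returns it
#' unchanged (within numerical tolerance).
#'
#' @param cell numeric(6) unit cell (a, b, c in angstrom; angles in degrees).
#' @param eps relative numerical tolerance used in the reduction decisions.
#' @return numeric(6): the Niggli-reduced cell.
#' @examples
#' niggli_reduce(c(79, 79, 38, 90, 90, 90))   # -> 38, 79, 79, 90, 90, 90
#' @export
niggli_reduce <- function(cell, eps = 1e-5) {
  validate_cell(cell)
  G <- cell_metric(cell)
  A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
  xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]
  e <- eps * mean(c(A, B, C))
  for (iter in 1:200) {
    # step 1: order A <= B
    if (A > B + e || (abs(A - B) <= e && abs(xi) > abs(eta) + e)) {
      tmp <- A; A <- B; B <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
    }
    # step 2: order B <= C
    if (B > C + e || (abs(B - C) <= e && abs(eta) > abs(zeta) + e)) {
      tmp <- B; B <- C; C <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      next
    }
    # step 3/4: fix signs (all positive, or all non-positive)
    if (xi * eta * zeta > 0) {
      xi <- abs(xi); eta <- abs(eta); zeta <- abs(zeta)
    } else {
      xi <- -abs(xi); eta <- -abs(eta); zeta <- -abs(zeta)
    }
    # step 5
    if (abs(xi) > B + e || (abs(xi - B) <= e && 2 * eta < zeta - e) ||
        (abs(xi + B) <= e && zeta < -e)) {
      s <- if (xi > 0) 1 else -1
      C <- B + C - s * xi
      eta <- eta - s * zeta
      xi <- xi - 2 * s * B
      next
    }
    # step 6
    if (abs(eta) > A + e || (abs(eta - A) <= e && 2 * xi < zeta - e) ||
        (abs(eta + A) <= e && zeta < -e)) {
      s <- if (eta > 0) 1 else -1
      C <- A + C - s * eta
      xi <- xi - s * zeta
      eta <- eta - 2 * s * A
      next
    }
    # step 7
    if (abs(zeta) > A + e || (abs(zeta - A) <= e && 2 * xi < eta - e) ||
        (abs(zeta + A) <= e && eta < -e)) {
      s <- if (zeta > 0) 1 else -1
      B <- A + B - s * zeta
      xi <- xi - s * eta
      zeta <- zeta - 2 * s * A
      next
    }
    # step 8
    if (xi + eta + zeta + A + B < -e ||
        (abs(xi + eta + zeta + A + B) <= e && 2 * (A + eta) + zeta > e)) {
      C <- A + B + C + xi + eta + zeta
      xi <- 2 * B + xi + zeta
      eta <- 2 * A + eta + zeta
      next
    }
    break
  }
  Gr <- matrix(c(A, zeta / 2, eta / 2,
                 zeta / 2, B, xi / 2,
                 eta / 2, xi / 2, C), 3, 3)
  out <- metric_to_cell(Gr)
  validate_cell(out)
  out
}

#' Distance between two unit cells
#'
#' Metric used as the linkage distance for unit-cell clustering: both cells
#' are Niggli-reduced, then the distance is the Euclidean norm of the
#' differences of the reduced edge lengths (angstrom) plus the reduced
#' angles scaled by `angle_weight` (angstrom per degree).  This is a
#' documented simplification of the Andrews-Bernstein G6 cell distance; it
#' is zero iff the reduced cells are identical, and symmetric.
#'
#' @param cell_a,cell_b numeric(6) unit cells.
#' @param angle_weight scale factor converting degrees to angstrom-equivalent
#'   distance (default 0.5).
#' @param reduce reduce the cells first (default TRUE; set FALSE if inputs
#'   are already Niggli-reduced).
#' @return non-negative scalar distance.
#' @export
cell_distance <- function(cell_a, cell_b, angle_weight = 0.5, reduce = TRUE) {
  if (reduce) {
    cell_a <- niggli_reduce(cell_a)
    cell_b <- niggli_reduce(cell_b)
  }
  d <- cell_a - cell_b
  sqrt(sum(d[1:3]^2) + angle_weight^2 * sum(d[4:6]^2))
}

#' Bravais-lattice consistency filter
#'
#' Decides whether an indexed cell is consistent with a required Bravais
#' lattice type, using the Niggli-reduced cell and a lattice-character
#' tolerance test (not a full symmetry scoring).  Supported lattice symbols
#' are the 14 two-letter Bravais symbols (aP, mP, mC, oP, oC, oF, oI, tP,
#' tI, hP, hR, cP, cF, cI); only the crystal-family constraints on the
#' reduced primitive cell are tested (angles within `angle_tol` of the
#' family values, required edge equalities within `length_tol` relative),
#' plus an optional comparison against a target cell.
#'
#' @param cell numeric(6) indexed unit cell.
#' @param lattice required Bravais symbol, e.g. `"oP"`.
#' @param target_cell optional numeric(6); if given, reduced edge lengths
#'   must also match the reduced target edges within `length_tol`.
#' @param angle_tol angular tolerance in degrees (default 1).
#' @param length_tol relative edge-length tolerance (default 0.05).
#' @return logical: keep (TRUE) or drop (FALSE).
#' @export
bravais_filter <- function(cell, lattice, target_cell = NULL,
                           angle_tol = 1, length_tol = 0.05) {
  sym <- match.arg(lattice, c("aP", "mP", "mC", "oP", "oC", "oF", "oI",
                              "tP", "tI", "hP", "hR", "cP", "cF", "cI"))
  red <- niggli_reduce(cell)
  fam <- substr(sym, 1, 1)
  ok <- TRUE
  ang90 <- function(x) abs(x - 90) <= angle_tol
  releq <- function(x, y) abs(x - y) <= length_tol * pmax(x, y)
  if (fam %in% c("o", "t", "c")) {
    # primitive reduced cell of these families has 90-degree angles for the
    # P setting; centred settings can reduce to non-90 cells, so the angle
    # test is only enforced for primitive lattices
    if (substr(sym, 2, 2) == "P") ok <- ok && all(ang90(red[4:6]))
  }
  if (fam == "t" && sym == "tP") ok <- ok && (releq(red[1], red[2]) || releq(red[2], red[3]))
  if (fam == "c" && sym == "cP") ok <- ok && releq(red[1], red[2]) && releq(red[2], red[3])
  if (fam == "h" && sym == "hP")
    ok <- ok && all(ang90(red[4:5])) && abs(red[6] - 120) <= angle_tol && releq(red[1], red[2])
  if (!is.null(target_cell)) {
    tred <- niggli_reduce(target_cell)
    ok <- ok && all(abs(red[1:3] - tred[1:3]) <= length_tol * tred[1:3]) &&
      all(abs(red[4:6] - tred[4:6]) <= max(angle_tol, 1e-9))
  }
  isTRUE(ok)
}

#' Lowest-symmetry Laue class of a Bravais lattice
#'
#' For downstream scaling and merging the lowest-symmetry Laue class
#' compatible with the Bravais lattice is chosen (e.g. P4/m rather than
#' P4/mmm for a primitive tetragonal lattice).  Fixed lookup table; the
#' hexagonal-P lattice also hosts trigonal point groups, so its lowest
#' class is P-3.
#'
#' @param bravais_lattice two-letter Bravais symbol (e.g. `"oP"`, `"tI"`).
#' @return Laue class symbol as a string.
#' @examples
#' lowest_laue_class("tP")  # "P4/m"
#' lowest_laue_class("oP")  # "Pmmm"
#' @export
lowest_laue_class <- function(bravais_lattice) {
  tab <- c(aP = "P-1",
           mP = "P2/m",  mC = "C2/m",
           oP = "Pmmm",  oC = "Cmmm", oF = "Fmmm", oI = "Immm",
           tP = "P4/m",  tI = "I4/m",
           hP = "P-3",   hR = "R-3",
           cP = "Pm-3",  cF = "Fm-3", cI = "Im-3")
  if (!bravais_lattice %in% names(tab))
    stop("unknown Bravais lattice symbol: ", bravais_lattice)
  unname(tab[[bravais_lattice]])
}
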