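# Vector geometry: internal-to-Cartesian atom placement, dihedrals, and
# least-squares rigid superposition.

#' @keywords internal
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
vunit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Natural extension reference frame: place atom D bonded to C with bond
# length |CD|, angle B-C-D, and dihedral A-B-C-D (degrees).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign convention: A-B-C-D right-handed
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  p <- vcross(n, bc)
  c + bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * p + sin(tor) * n))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% x + t` against `y` over paired points. Reflections are never
#' returned: the rotation determinant is +1.
#'
#' @param x,y n x 3 coordinate matrices of paired points (x is moved onto y).
#' @param pairing optional two-column index matrix selecting rows of `x` and
#'   `y` to pair; by default rows are paired in order.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
kabsch_superpose <- function(x, y, pairing = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(pairing)) {
    x <- x[pairing[, 1], , drop = FALSE]
    y <- y[pairing[, 2], , drop = FALSE]
  }
  if (nrow(x) != nrow(y)) stop("paired coordinate sets differ in size")
  if (nrow(x) < 3) stop("superposition requires at least 3 paired points")
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2) {
    stop("degenerate (collinear) point set: superposition undefined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- unname(cy - as.vector(rot %*% cx))
  moved <- sweep(x %*% t(rot), 2, trans, "+")
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - y)^2))))
}

#' @keywords internal
apply_rigid <- function(coords, rotation, translation) {
  sweep(as.matrix(coords) %*% t(rotation), 2, translation, "+")
}

# Apply a 4x4 homogeneous transform to an n x 3 coordinate matrix.
#' @keywords internal
apply_transform <- function(coords, mat) {
  stopifnot(all(dim(mat) == c(4, 4)))
  r <- mat[1:3, 1:3]
  t <- mat[1:3, 4]
  sweep(as.matrix(coords) %*% t(r), 2, t, "+")
}

#' @keywords internal
rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3, 3, byrow = TRUE)
}

#' @keywords internal
make_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  m
}

# Rotate coordinates into their principal-axis frame with a deterministic
# sign convention. Sphere-point sampling done in this frame is invariant
# under rigid motions of the input (up to axis degeneracies).
#' @keywords internal
canonical_frame <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) return(xyz)
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  v <- svd(x0)$v
  idx <- seq_len(nrow(x0)) - (nrow(x0) + 1) / 2
  for (k in 1:3) {
    p <- x0 %*% v[, k]
    s <- sum(p * idx)          # orientation from atom order: frame-free
    if (abs(s) < 1e-9) s <- sum(p^3)
    if (s < 0) v[, k] <- -v[, k]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  x0 %*% v
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral); used by the SASA sampler.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
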