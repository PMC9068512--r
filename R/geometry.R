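# Low-level vector geometry shared across modules.

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four 3-D points using the
#' atan2 formulation, with the IUPAC sign convention (clockwise rotation
#' of the 1-2 bond relative to the 3-4 bond, viewed along 2-3, is
#' positive). This is the convention under which a side-chain chi1
#' dihedral is reported from atoms N, CA, CB, OG1.
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors, positions in Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # cis, 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20)
    stop("dihedral_angle: two consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("dihedral_angle: collinear bond geometry, dihedral undefined")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Wrap degrees into (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Minimal circular difference a - b in degrees, in (-180, 180].
angle_diff <- function(a, b) wrap_angle(a - b)

# Place a fourth atom from three anchors and internal coordinates
# (bond length, bond angle in degrees at p3, torsion in degrees about
# p2-p3).  Standard NeRF construction.
place_atom <- function(p1, p2, p3, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d <- c(-length * cos(ang),
         length * sin(ang) * cos(tor),
         length * sin(ang) * sin(tor))
  bc <- p3 - p2
  bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p1
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(p3 + M %*% d)
}

# Kabsch optimal rotation mapping x onto y (both n x 3, already centred).
# Returns proper rotation matrix R (det +1) such that x %*% R ~ y.
kabsch_rotation <- function(x, y) {
  h <- crossprod(x, y)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  sv$u %*% s %*% t(sv$v)
}

# RMSD of x vs y (n x 3) after optimal rigid superposition.
superpose_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  r <- kabsch_rotation(xc, yc)
  d <- xc %*% r - yc
  sqrt(sum(d^2) / nrow(x))
}

# Rotation matrix taking unit vector a to unit vector b by the minimal
# rotation (Rodrigues).  Deterministic; handles a ~ -b via a fixed
# perpendicular axis.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- cross3(a, b)
  s2 <- sum(v^2)
  cth <- sum(a * b)
  if (s2 < 1e-18) {
    if (cth > 0) return(diag(3))
    # a = -b: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- cross3(a, p)
    ax <- ax / sqrt(sum(ax^2))
    return(rotation_about(ax, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
}

# Rotation matrix about unit axis by angle (radians).
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s_ <- sin(theta)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    c_ + x^2 * (1 - c_),     x * y * (1 - c_) + z * s_, x * z * (1 - c_) - y * s_,
    x * y * (1 - c_) - z * s_, c_ + y^2 * (1 - c_),     y * z * (1 - c_) + x * s_,
    x * z * (1 - c_) + y * s_, y * z * (1 - c_) - x * s_, c_ + z^2 * (1 - c_)
  ), 3, 3)
}

# Shoelace area of a polygon given 2-D vertices in order (n x 2).
shoelace_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}
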