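# Low-level vector/rotation helpers shared by the frame, step and pucker code.
# All rotations are 3x3 proper orthogonal matrices acting on column vectors;
# angles at the interfaces are degrees, radians internally.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the (not necessarily unit)
#' axis `axis`.
#'
#' @param axis numeric length-3 axis vector.
#' @param angle rotation angle in degrees (right-hand rule).
#' @return A 3x3 proper rotation matrix.
#' @keywords internal
rot_about <- function(axis, angle) {
  u <- unitv(axis)
  a <- angle * DEG
  ca <- cos(a); sa <- sin(a)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ca * diag(3) + sa * ux + (1 - ca) * (u %o% u)
}

# Signed angle (degrees) from vector a to vector b, measured about axis n
# (right-hand rule); a and b need not be perpendicular to n.
signed_angle <- function(a, b, n) {
  n <- unitv(n)
  a <- a - sum(a * n) * n
  b <- b - sum(b * n) * n
  atan2(sum(n * pracma_cross(a, b)), sum(a * b)) / DEG
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Axis-angle decomposition of a proper rotation matrix.
# Returns list(axis = unit 3-vector, angle = degrees in [0, 180]).
axis_angle <- function(R) {
  tr <- sum(diag(R))
  ca <- (tr - 1) / 2
  ca <- min(1, max(-1, ca))
  ang <- acos(ca)
  if (ang < 1e-12) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (pi - ang < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonal elements
    i <- which.max(ax)
    if (i == 1) { ax[2] <- B[1, 2] / ax[1]; ax[3] <- B[1, 3] / ax[1] }
    if (i == 2) { ax[1] <- B[1, 2] / ax[2]; ax[3] <- B[2, 3] / ax[2] }
    if (i == 3) { ax[1] <- B[1, 3] / ax[3]; ax[2] <- B[2, 3] / ax[3] }
    return(list(axis = unitv(ax), angle = ang / DEG))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  list(axis = unitv(ax), angle = ang / DEG)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention (right-hand rule about the b-c bond): looking from
#' b towards c, a clockwise rotation of the far bond is positive.
#'
#' @param a,b,c,d numeric length-3 coordinates.
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) / DEG  # sign matches the convention of bio3d/IUPAC
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle (degrees) into (-180, 180], ties at -180 mapped to +180.
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Least-squares rigid superposition (Kabsch, SVD form)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' sum_i w_i |R x_i + t - y_i|^2; mirror solutions are rejected by flipping
#' the sign of the smallest singular direction so det(R) = +1, which is
#' essential for near-planar point sets such as base rings.
#'
#' @param x,y n x 3 coordinate matrices (x is moved onto y).
#' @param w optional non-negative weights, length n.
#' @return list with `R` (3x3, det +1), `t` (length 3), `rmsd` (Angstrom).
#' @keywords internal
kabsch <- function(x, y, w = NULL) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3, ncol(y) == 3,
            nrow(x) == nrow(y), nrow(x) >= 3)
  if (is.null(w)) w <- rep(1, nrow(x))
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  H <- t(x0 * w) %*% y0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(x0 %*% t(R), 2, cy, `+`)
  rmsd <- sqrt(sum(rowSums((fit - y)^2) * w))
  list(R = R, t = t, rmsd = rmsd)
}

# Internal-coordinate (NeRF) placement: position atom D bonded to C given
# the chain A-B-C, bond length |CD|, angle B-C-D (deg), dihedral A-B-C-D (deg).
nerf_place <- function(a, b, c, length, angle, dihedral) {
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  ang <- angle * DEG; dih <- dihedral * DEG
  d2 <- length * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Orthonormality check helper for frame validation.
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < 1e-6
}
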