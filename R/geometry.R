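# Elementary 3D geometry: signed dihedrals, bond angles, internal-coordinate
# (NeRF-style) atom placement, and rotation of atom blocks about a bond axis.
# Interfaces are in degrees and Angstroms; radians are used internally.

.d2r <- pi / 180
.r2d <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))
.vhat <- function(v) v / .vnorm(v)
.vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstroms).
#' @return dihedral in degrees in \code{[-180, 180)}.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vhat(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * .r2d)
}

#' Bond angle at p2 in degrees
#' @param p1,p2,p3 numeric 3-vectors.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- .vhat(p1 - p2); v <- .vhat(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * .r2d
}

# wrap to [-180, 180)
wrap_angle <- function(x) ((x + 180) %% 360) - 180

# Place atom D bonded to C with |CD| = bond, angle(B,C,D) = ang and
# dihedral(A,B,C,D) = tors (degrees).  Errors on a collinear frame.
place_atom <- function(A, B, C, bond, ang, tors) {
  bc <- C - B
  nbc <- .vnorm(bc)
  ab <- B - A
  n <- .vcross(ab, bc)
  nn <- .vnorm(n)
  if (nbc < 1e-8 || nn < 1e-8)
    stop("degenerate (collinear) reference frame for atom placement")
  bc <- bc / nbc
  n <- n / nn
  m <- .vcross(n, bc)
  th <- ang * .d2r; ta <- tors * .d2r
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ta), -bond * sin(th) * sin(ta))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rodrigues rotation of the rows `idx` of xyz about the axis through point
# `origin` with unit direction `u`, by `ang` degrees (right-handed).
rotate_about_axis <- function(xyz, idx, origin, u, ang) {
  if (!length(idx) || abs(ang) < 1e-13) return(xyz)
  a <- ang * .d2r
  ca <- cos(a); sa <- sin(a)
  p <- sweep(xyz[idx, , drop = FALSE], 2, origin)
  dotpu <- p %*% u
  crossup <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                   u[3] * p[, 1] - u[1] * p[, 3],
                   u[1] * p[, 2] - u[2] * p[, 1])
  r <- p * ca + crossup * sa + (dotpu %*% t(u)) * (1 - ca)
  xyz[idx, ] <- sweep(r, 2, origin, "+")
  xyz
}
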