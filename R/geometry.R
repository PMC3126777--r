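# Vector geometry primitives shared by the model builder, torsion engine,
# loop closure and secondary-structure code. Angles are in degrees
# throughout the user-facing API.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Bond angle at b (degrees)
#' @param a,b,c coordinate vectors (length 3).
#' @return Angle a-b-c in degrees.
#' @export
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) / DEG
}

#' Dihedral angle (degrees, in (-180, 180])
#' @param a,b,c,d coordinate vectors (length 3).
#' @return Torsion angle of the a-b-c-d chain in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural extension reference frame (NeRF) placement: position atom d bonded
# to c with |cd| = bond, angle(b,c,d) = angle and dihedral(a,b,c,d) = torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * DEG
  tor <- torsion * DEG
  # the sign of the out-of-plane component is chosen so that the measured
  # dihedral_angle(a, b, c, d) equals `torsion` exactly
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + c)
}

# Rodrigues rotation matrix about a unit axis, theta in degrees
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  t <- theta * DEG
  ct <- cos(t)
  st <- sin(t)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         3L, 3L, byrow = TRUE)
}

# rotate rows of `pts` (n x 3) by theta degrees about the axis through
# `origin` with direction `axis`
rotate_points <- function(pts, origin, axis, theta) {
  R <- rotation_about_axis(axis, theta)
  sweep(sweep(pts, 2L, origin) %*% t(R), 2L, origin, `+`)
}
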