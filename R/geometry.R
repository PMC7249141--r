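# Small 3-vector geometry kit used throughout the package. Coordinates are
# N x 3 matrices in Angstrom; angles are returned in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Distance between two atoms
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param i,j 1-based row indices.
#' @return Distance in Angstrom.
#' @keywords internal
atom_distance <- function(xyz, i, j) vnorm(xyz[j, ] - xyz[i, ])

#' Bond angle i-j-k (j central), degrees
#' @inheritParams atom_distance
#' @param k third atom index.
#' @keywords internal
atom_angle <- function(xyz, i, j, k) {
  u <- unitv(xyz[i, ] - xyz[j, ])
  w <- unitv(xyz[k, ] - xyz[j, ])
  rad2deg(acos(max(-1, min(1, sum(u * w)))))
}

#' Proper torsion i-j-k-l, degrees in (-180, 180]
#' @inheritParams atom_angle
#' @param l fourth atom index.
#' @keywords internal
atom_dihedral <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Rodrigues rotation matrix about unit axis by angle (radians).
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# NeRF-style atom placement: position a new atom at bond length r from a,
# bond angle theta (deg) w.r.t. b-a, and torsion phi (deg) w.r.t. c-b-a.
place_atom <- function(a, b, c, r, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  bc <- unitv(a - b)
  n <- unitv(cross3(b - c, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th),
         r * sin(th) * cos(ph),
         -r * sin(th) * sin(ph))
  a + d[1] * bc + d[2] * m + d[3] * n
}
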