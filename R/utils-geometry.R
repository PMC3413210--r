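# Low-level 3D geometry used throughout: internal-coordinate atom placement
# (the NeRF construction), bond angles, torsions, and least-squares planes.
# All coordinates are plain numeric length-3 vectors in Angstrom.

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at vertex b (degrees) for points a-b-c
#' @noRd
bond_angle <- function(a, b, c) {
  u <- vec_unit(a - b)
  v <- vec_unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion a-b-c-d in degrees, IUPAC sign convention
#' @noRd
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Place atom D from reference atoms A, B, C such that |C-D| = r,
#' angle(B,C,D) = theta (deg) and torsion(A,B,C,D) = chi (deg).
#' @noRd
nerf_place <- function(a, b, c, r, theta, chi) {
  th <- deg2rad(theta)
  ph <- deg2rad(chi)
  bc <- vec_unit(c - b)
  n  <- vec_unit(vec_cross(b - a, bc))
  m  <- vec_cross(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Wrap an angular difference into (-180, 180]
#' @noRd
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Least-squares plane fit: returns list(center, normal, rmsd) for an n x 3
#' coordinate matrix (n >= 3). The plane minimises the sum of squared
#' perpendicular distances (smallest singular vector of the centred cloud).
#' @noRd
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  d <- as.numeric(sweep(xyz, 2, ctr) %*% normal)
  list(center = ctr, normal = normal, rmsd = sqrt(mean(d^2)))
}

#' Rotation matrix for angle deg about unit axis
#' @noRd
rotation_about <- function(axis, deg) {
  u <- vec_unit(axis)
  th <- deg2rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}
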