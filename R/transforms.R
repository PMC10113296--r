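# Rigid-transform and angle utilities shared by the kinematic and optic code.
# Convention: positions in mm, angles in degrees at the API surface and
# radians internally; cavity frame is right-handed with origin at the
# fulcrum F, +z along the mean insertion axis (into the cavity), +y superior.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the half-open interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles congruent to `theta` modulo `2*pi`, wrapped to `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  w <- theta %% (2 * pi)          # [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi # (-pi, pi]
  w
}

#' Smallest wrapped angular difference in degrees
#'
#' Smallest unsigned angle between two orientations given in degrees,
#' so that 359 deg vs 1 deg scores 2 deg.
#'
#' @param a,b orientations in degrees.
#' @return unsigned wrapped difference in degrees, in `[0, 180]`.
#' @export
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

rot_x <- function(t) {
  c_ <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(t) {
  c_ <- cos(t); s <- sin(t)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(t) {
  c_ <- cos(t); s <- sin(t)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, t) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop_scopeskill("degenerate_axis", "cannot normalise a zero vector")
  v / n
}

# Orthonormal basis (x0, y0) perpendicular to unit vector u, with x0 the
# unit projection of the superior direction (+y); falls back to +x when u
# is (anti)parallel to +y. Used as the roll reference frame.
shaft_frame <- function(u) {
  ref <- c(0, 1, 0)
  x0 <- ref - sum(ref * u) * u
  if (vnorm(x0) < 1e-9) {
    ref <- c(1, 0, 0)
    x0 <- ref - sum(ref * u) * u
  }
  x0 <- x0 / vnorm(x0)
  y0 <- c(u[2] * x0[3] - u[3] * x0[2],
          u[3] * x0[1] - u[1] * x0[3],
          u[1] * x0[2] - u[2] * x0[1])
  list(x0 = x0, y0 = y0)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
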