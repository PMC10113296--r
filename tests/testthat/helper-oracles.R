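# Independent oracles, deliberately written with different machinery than
# the implementation they check.

# Homogeneous-transform product for the 3-joint positioning chain.
oracle_attachment <- function(th, geom) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  H <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  Tz <- function(l) H(diag(3), c(0, 0, l))
  M <- H(geom$base_rotation, geom$base_position) %*%
    H(Rz(th[1]), c(0, 0, 0)) %*% Tz(geom$l1) %*%
    H(Ry(th[2]), c(0, 0, 0)) %*% Tz(geom$l2) %*%
    H(Ry(th[3]), c(0, 0, 0)) %*% Tz(geom$l3)
  M[1:3, 4]
}

# Full 6-joint forward kinematics: chain, gimbal (theta4 about local y,
# theta5 about local x), tool shaft of length L along local z, roll about
# it (theta6 does not move the tip).
oracle_tip <- function(joints, geom) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  R3 <- geom$base_rotation %*% Rz(joints[1]) %*% Ry(joints[2]) %*% Ry(joints[3])
  A <- oracle_attachment(joints[1:3], geom)
  Rfull <- R3 %*% Ry(joints[4]) %*% Rx(joints[5])
  shaft <- drop(Rfull %*% c(0, 0, 1))
  list(attachment = A, shaft_dir = shaft,
       tip = A + geom$tool_length * shaft)
}

# Distance from point p to the infinite line through a with direction u
# (cross-product form; the difference-of-squares form loses ~6 digits at
# this scale).
point_line_distance <- function(p, a, u) {
  u <- u / sqrt(sum(u^2))
  w <- p - a
  cr <- c(w[2] * u[3] - w[3] * u[2],
          w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  sqrt(sum(cr^2))
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Monte-Carlo rasterization oracle for accuracy_score: fraction of points
# uniform in the overlay ellipse that fall inside the ring boundary
# polygon.
oracle_overlap_pct <- function(overlay, ring_poly, n_pts = 2e5) {
  r <- sqrt(runif(n_pts))
  a <- runif(n_pts, 0, 2 * pi)
  x0 <- overlay$semi_major * r * cos(a)
  y0 <- overlay$semi_minor * r * sin(a)
  o <- overlay$orientation * pi / 180
  px <- overlay$center[1] + x0 * cos(o) - y0 * sin(o)
  py <- overlay$center[2] + x0 * sin(o) + y0 * cos(o)
  100 * mean(points_in_polygon(px, py, ring_poly))
}
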