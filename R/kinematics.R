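# Fulcrum-constrained pose recovery.
#
# The endoscope shaft must pass through the fulcrum F at the cavity
# entrance. Joints 1-3 place the scope attachment point A; the shaft axis
# is then forced to be the line through A and F, which fixes the two
# unencoded gimbal joints (theta4, theta5); theta6 is the scope roll. So
# the four encoded angles determine the full 6-joint state and the tip
# pose: tip = A + L*u with u = (F - A)/|F - A| and insertion depth
# d = L - |F - A|.

#' Encoder reading
#'
#' One timestamped reading of the four encoded joints.
#'
#' @param theta1,theta2,theta3 positioning-chain joint angles, radians
#'   (wrapped to `(-pi, pi]`).
#' @param theta6 scope roll joint angle, radians.
#' @param t timestamp, seconds (>= 0).
#' @return an object of class `encoder_reading`.
#' @export
encoder_reading <- function(theta1, theta2, theta3, theta6, t = 0) {
  if (t < 0) stop_scopeskill("config_invalid", "timestamp must be >= 0")
  structure(list(theta1 = wrap_angle(theta1), theta2 = wrap_angle(theta2),
                 theta3 = wrap_angle(theta3), theta6 = wrap_angle(theta6),
                 t = t),
            class = "encoder_reading")
}

#' Forward kinematics of the encoded positioning sub-chain
#'
#' Maps the first three encoder angles to the endoscope attachment point A
#' in the cavity frame. Total on wrapped angles and continuous everywhere.
#'
#' @param enc3 numeric vector `c(theta1, theta2, theta3)` in radians (an
#'   `encoder_reading` is also accepted).
#' @param geom an [arm_geometry()].
#' @return attachment point, 3-vector mm in the cavity frame.
#' @export
chain_attachment_point <- function(enc3, geom) {
  if (inherits(enc3, "encoder_reading"))
    enc3 <- c(enc3$theta1, enc3$theta2, enc3$theta3)
  drop(chain_attachment_points(matrix(enc3, 1, 3), geom))
}

# Vectorised form: th is an n x 3 matrix of (theta1, theta2, theta3);
# returns an n x 3 matrix of attachment points.
chain_attachment_points <- function(th, geom) {
  s <- geom$joint_signs
  t1 <- s[1] * th[, 1]; t2 <- s[2] * th[, 2]; t3 <- s[3] * th[, 3]
  # planar 2R in the (local x, z) plane after the yaw joint
  x_pl <- geom$l2 * sin(t2) + geom$l3 * sin(t2 + t3)
  z_pl <- geom$l1 + geom$l2 * cos(t2) + geom$l3 * cos(t2 + t3)
  local <- cbind(cos(t1) * x_pl, sin(t1) * x_pl, z_pl)
  local %*% t(geom$base_rotation) +
    matrix(geom$base_position, nrow(th), 3, byrow = TRUE)
}

#' Oblique-optic view direction
#'
#' The optical axis of an oblique endoscope is tilted `optic_offset`
#' degrees away from the mechanical shaft axis; rotating the scope (roll)
#' swings the view axis around the shaft on a cone. Roll zero points the
#' optic toward the superior (+y) side of the cavity frame; positive roll
#' is clockwise as seen from the eyepiece looking along the shaft.
#'
#' @param shaft_dir unit 3-vector, attachment-to-tip shaft direction.
#' @param roll scope roll, degrees.
#' @param optic_offset oblique angle, degrees.
#' @return unit 3-vector: the optical-axis direction.
#' @export
view_direction <- function(shaft_dir, roll, optic_offset = 30) {
  u <- shaft_dir
  if (abs(vnorm(u) - 1) > 1e-9)
    stop_scopeskill("config_invalid", "shaft_dir must be a unit vector")
  if (optic_offset == 0) return(u)
  fr <- shaft_frame(u)
  r <- deg2rad(roll)
  w <- cos(r) * fr$x0 - sin(r) * fr$y0
  off <- deg2rad(optic_offset)
  cos(off) * u + sin(off) * w
}

#' Endoscope tip pose
#'
#' Container for the recovered tool-tip pose. Usually produced by
#' [resolve_tip_pose()]; the constructor builds one from shaft direction,
#' insertion depth and roll.
#'
#' @param shaft_dir unit 3-vector, shaft direction (attachment toward tip).
#' @param insertion_depth distance from the fulcrum to the tip along the
#'   shaft, mm (>= 0).
#' @param roll scope roll, degrees.
#' @param geom an [arm_geometry()] (supplies the fulcrum and optic offset).
#' @return an object of class `tip_pose` with fields `position`,
#'   `shaft_dir`, `view_dir`, `roll`, `insertion_depth`.
#' @export
tip_pose <- function(shaft_dir, insertion_depth, roll, geom) {
  u <- unitize(shaft_dir)
  if (insertion_depth < 0)
    stop_scopeskill("retracted", "insertion depth must be >= 0")
  structure(list(
    position = geom$rcm_point + insertion_depth * u,
    shaft_dir = u,
    view_dir = view_direction(u, roll, geom$optic_offset),
    roll = roll,
    insertion_depth = insertion_depth
  ), class = "tip_pose")
}

#' @export
print.tip_pose <- function(x, ...) {
  cat(sprintf("Tip pose: position (%.2f, %.2f, %.2f) mm, depth %.2f mm, roll %.1f deg\n",
              x$position[1], x$position[2], x$position[3],
              x$insertion_depth, x$roll))
  invisible(x)
}

#' Recover the tip pose and full joint state from one encoder reading
#'
#' Applies the fulcrum constraint: the shaft axis is the line through the
#' chain attachment point A and the fulcrum F, so
#' `tip = A + tool_length * u` with `u = (F - A)/|F - A|`, insertion depth
#' `d = tool_length - |F - A|`, and the unencoded gimbal joints theta4,
#' theta5 are the angles aligning the chain's distal frame with u (branch
#' with `|theta4| <= 90` degrees).
#'
#' @param enc an [encoder_reading()].
#' @param geom an [arm_geometry()].
#' @return a list with components `pose` (a `tip_pose`) and `joints`
#'   (named numeric theta1..theta6, radians).
#' @export
resolve_tip_pose <- function(enc, geom) {
  A <- chain_attachment_point(enc, geom)
  FA <- geom$rcm_point - A
  dist_AF <- vnorm(FA)
  if (dist_AF < 1e-6)
    stop_scopeskill("degenerate_axis",
                    "attachment point coincides with the fulcrum; shaft axis undefined")
  u <- FA / dist_AF
  d <- geom$tool_length - dist_AF
  if (d < 0)
    stop_scopeskill("retracted",
                    sprintf("tool withdrawn past the fulcrum (d = %.3f mm)", d),
                    insertion_depth = d)
  roll <- rad2deg(geom$joint_signs[6] * enc$theta6)
  pose <- tip_pose(u, d, roll, geom)

  # distal frame of the positioning chain
  s <- geom$joint_signs
  R3 <- geom$base_rotation %*% rot_z(s[1] * enc$theta1) %*%
    rot_y(s[2] * enc$theta2) %*% rot_y(s[3] * enc$theta3)
  v <- drop(t(R3) %*% u)  # shaft direction in the distal frame
  # Ry(t4) Rx(t5) e_z = (sin t4 cos t5, -sin t5, cos t4 cos t5)
  t5 <- asin(max(-1, min(1, -v[2])))
  t4 <- atan2(v[1], v[3])
  if (abs(t4) > pi / 2 + 1e-12) {  # take the |theta4| <= 90 deg branch
    t4 <- wrap_angle(t4 + pi)
    t5 <- wrap_angle(pi - t5)
  }
  joints <- c(theta1 = enc$theta1, theta2 = enc$theta2, theta3 = enc$theta3,
              theta4 = t4, theta5 = t5, theta6 = enc$theta6)
  list(pose = pose, joints = joints)
}

# Vectorised pose recovery for whole sample streams. th: n x 4 matrix with
# columns theta1..theta3, theta6. Returns a list of n x 3 matrices
# (position, shaft_dir) plus vectors roll (deg) and depth (mm). Samples
# with d < 0 or a degenerate axis are flagged in `ok` rather than erroring
# (a log may legitimately start outside the cavity).
resolve_tip_poses <- function(th, geom) {
  A <- chain_attachment_points(th[, 1:3, drop = FALSE], geom)
  FA <- -sweep(A, 2, geom$rcm_point)
  dist_AF <- sqrt(rowSums(FA^2))
  ok <- dist_AF >= 1e-6
  u <- FA / pmax(dist_AF, 1e-12)
  d <- geom$tool_length - dist_AF
  ok <- ok & d >= -1e-9   # tolerate rounding at the fulcrum boundary
  d <- pmax(d, 0)
  pos <- matrix(geom$rcm_point, nrow(th), 3, byrow = TRUE) + u * d
  list(position = pos, shaft_dir = u, depth = d,
       roll = rad2deg(geom$joint_signs[6] * th[, 4]), ok = ok)
}

#' Encoder angles realising a given tip pose
#'
#' Inverse map used by the simulator to emit the encoder stream hardware
#' would produce. The attachment point implied by the pose is
#' `A = position - tool_length * shaft_dir`; the yaw joint is the azimuth
#' of A in the base frame and the two pitch joints solve the planar 2R
#' problem (deterministic elbow branch: theta3 >= 0).
#'
#' @param pose a [tip_pose()].
#' @param geom an [arm_geometry()].
#' @param t timestamp for the resulting reading, seconds.
#' @return an [encoder_reading()] such that [resolve_tip_pose()] reproduces
#'   `pose`.
#' @export
encoders_from_pose <- function(pose, geom, t = 0) {
  th <- encoders_from_params(
    matrix(c(acos(pmin(1, pmax(-1, pose$shaft_dir[3]))),
             atan2(pose$shaft_dir[2], pose$shaft_dir[1]),
             pose$insertion_depth, pose$roll), 1, 4), geom)
  encoder_reading(th[1, 1], th[1, 2], th[1, 3], th[1, 4], t = t)
}

# Vectorised inverse kinematics on shaft parameters. par: n x 4 matrix of
# (polar, azimuth [rad], depth [mm], roll [deg]); returns n x 4 matrix of
# encoder angles (theta1, theta2, theta3, theta6).
encoders_from_params <- function(par, geom) {
  sp <- sin(par[, 1])
  u <- cbind(sp * cos(par[, 2]), sp * sin(par[, 2]), cos(par[, 1]))
  A <- matrix(geom$rcm_point, nrow(par), 3, byrow = TRUE) +
    (par[, 3] - geom$tool_length) * u
  # into the base frame
  Ab <- sweep(A, 2, geom$base_position) %*% geom$base_rotation
  r <- sqrt(Ab[, 1]^2 + Ab[, 2]^2)
  t1 <- atan2(Ab[, 2], Ab[, 1])
  zeta <- Ab[, 3] - geom$l1
  D2 <- r^2 + zeta^2
  c3 <- (D2 - geom$l2^2 - geom$l3^2) / (2 * geom$l2 * geom$l3)
  if (any(abs(c3) > 1 + 1e-9))
    stop_scopeskill("unreachable",
                    "required attachment point is outside the 3R chain workspace")
  c3 <- pmin(1, pmax(-1, c3))
  t3 <- acos(c3)  # elbow branch theta3 >= 0
  t2 <- atan2(r, zeta) - atan2(geom$l3 * sin(t3), geom$l2 + geom$l3 * cos(t3))
  s <- geom$joint_signs
  cbind(wrap_angle(t1 / s[1]), wrap_angle(t2 / s[2]),
        wrap_angle(t3 / s[3]), wrap_angle(deg2rad(par[, 4]) / s[6]))
}

# Shaft parameterisation (polar, azimuth, depth, roll) of a tip_pose.
pose_params <- function(pose) {
  c(polar = acos(pmin(1, pmax(-1, pose$shaft_dir[3]))),
    azimuth = atan2(pose$shaft_dir[2], pose$shaft_dir[1]),
    depth = pose$insertion_depth,
    roll = pose$roll)
}

params_pose <- function(par, geom) {
  par <- unname(par)
  sp <- sin(par[1])
  tip_pose(c(sp * cos(par[2]), sp * sin(par[2]), cos(par[1])),
           par[3], par[4], geom)
}
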