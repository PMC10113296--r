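#' Tracker-arm geometry
#'
#' Physical constants of the passive measurement arm holding the endoscope.
#' The arm has six passive rotational joints but only four encoders
#' (theta1, theta2, theta3 on the positioning chain and theta6 on the scope
#' roll): the fulcrum constraint at the cavity entrance removes the two
#' remaining degrees of freedom, which is what makes four encoders
#' sufficient to recover the full tool-tip pose.
#'
#' The positioning chain is an articulated yaw--pitch--pitch 3R arm: joint 1
#' rotates about the base z axis, joints 2 and 3 pitch about the rotated y
#' axis, with links `l1`, `l2`, `l3` stacked along the local z axis. At the
#' all-zero configuration the attachment point sits `l1+l2+l3` along the
#' base z axis. The endoscope shaft (length `tool_length`) is attached at
#' the chain tip and pivots about the fulcrum `rcm_point`.
#'
#' @param l1,l2,l3 link lengths of the positioning chain, mm.
#' @param tool_length endoscope length from attachment point to tip, mm.
#' @param rcm_point fulcrum position, 3-vector mm in the cavity frame
#'   (the cavity frame origin *is* the fulcrum by default).
#' @param base_position position of the arm base in the cavity frame, mm.
#' @param base_rotation 3x3 rotation of the base frame in the cavity frame.
#' @param optic_offset angle between the endoscope shaft axis and the
#'   optical axis, degrees (30 for the oblique scope trained here).
#' @param joint_signs length-6 vector of +1/-1 sign conventions.
#' @return an object of class `arm_geometry`.
#' @export
arm_geometry <- function(l1 = 150, l2 = 200, l3 = 200,
                         tool_length = 350,
                         rcm_point = c(0, 0, 0),
                         base_position = c(0, 0, -300),
                         base_rotation = diag(3),
                         optic_offset = 30,
                         joint_signs = rep(1, 6)) {
  lengths <- c(l1 = l1, l2 = l2, l3 = l3, tool_length = tool_length)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop_scopeskill("config_invalid", "all link and tool lengths must be positive")
  if (length(rcm_point) != 3 || length(base_position) != 3)
    stop_scopeskill("config_invalid", "rcm_point and base_position must be 3-vectors")
  if (!all(dim(base_rotation) == c(3, 3)) ||
      max(abs(crossprod(base_rotation) - diag(3))) > 1e-8)
    stop_scopeskill("config_invalid", "base_rotation must be a 3x3 rotation matrix")
  reach <- l1 + l2 + l3
  if (vnorm(rcm_point - base_position) >= reach + tool_length)
    stop_scopeskill("config_invalid", "fulcrum is outside the arm's reach")
  if (!(optic_offset >= 0 && optic_offset < 90))
    stop_scopeskill("config_invalid", "optic_offset must lie in [0, 90) degrees")
  structure(list(
    l1 = l1, l2 = l2, l3 = l3,
    tool_length = tool_length,
    rcm_point = as.numeric(rcm_point),
    base_position = as.numeric(base_position),
    base_rotation = base_rotation,
    optic_offset = optic_offset,
    joint_signs = joint_signs
  ), class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("Tracker-arm geometry\n")
  cat(sprintf("  links (mm): l1=%g l2=%g l3=%g, tool length %g\n",
              x$l1, x$l2, x$l3, x$tool_length))
  cat(sprintf("  fulcrum at (%g, %g, %g) mm, base at (%g, %g, %g) mm\n",
              x$rcm_point[1], x$rcm_point[2], x$rcm_point[3],
              x$base_position[1], x$base_position[2], x$base_position[3]))
  cat(sprintf("  optic offset %g deg\n", x$optic_offset))
  invisible(x)
}

#' Pinhole camera model for the endoscopic optic
#'
#' @param fov horizontal field of view, degrees.
#' @param image_size image width and height, px.
#' @param principal_point image-plane principal point, px; defaults to the
#'   image centre.
#' @param optic_offset oblique-optic angle, degrees.
#' @param near_limit minimum depth along the optical axis for a point to be
#'   considered in front of the camera, mm.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(fov = 70, image_size = c(640, 480),
                         principal_point = image_size / 2,
                         optic_offset = 30, near_limit = 1) {
  if (!(fov > 0 && fov < 180))
    stop_scopeskill("config_invalid", "fov must lie in (0, 180) degrees")
  if (any(image_size <= 0))
    stop_scopeskill("config_invalid", "image_size must be positive")
  if (!(optic_offset >= 0 && optic_offset < 90))
    stop_scopeskill("config_invalid", "optic_offset must lie in [0, 90) degrees")
  structure(list(
    fov = fov,
    image_size = as.numeric(image_size),
    principal_point = as.numeric(principal_point),
    optic_offset = optic_offset,
    near_limit = near_limit,
    focal_px = (image_size[1] / 2) / tan(deg2rad(fov) / 2)
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Pinhole camera: fov %g deg, %gx%g px, f = %.1f px, optic offset %g deg\n",
              x$fov, x$image_size[1], x$image_size[2], x$focal_px, x$optic_offset))
  invisible(x)
}
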