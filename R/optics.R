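# Image formation for the oblique optic and the ellipse-in-ring focus
# score. The camera sits at the endoscope tip with its optical axis along
# the view direction; the image horizon is kept gravity-aligned by the
# optical coupler, so the image up-vector is the projection of the cavity
# +y axis. The on-screen reticle is an ellipse fixed at the principal
# point; the user "focuses" a target by manoeuvring the scope until the
# whole reticle lies inside the projected black ring.

camera_basis <- function(pose) {
  zc <- pose$view_dir
  up <- c(0, 1, 0) - sum(c(0, 1, 0) * zc) * zc
  if (vnorm(up) < 1e-9) up <- c(1, 0, 0) - sum(c(1, 0, 0) * zc) * zc
  up <- up / vnorm(up)
  yc <- -up                # image y grows downward
  xc <- cross3(yc, zc)
  list(xc = xc, yc = yc, zc = zc)
}

#' Project a cavity-frame point into the endoscopic image
#'
#' Standard pinhole projection along the view direction. Points on the
#' optical axis map to the principal point; the projection is
#' scale-invariant along view rays.
#'
#' @param p 3-vector, point in the cavity frame (mm).
#' @param pose a [tip_pose()] (camera centre and optical axis).
#' @param cam a [camera_model()].
#' @return length-2 numeric: image coordinates in px. Signals a
#'   `scopeskill_behind_camera` condition if the point's depth along the
#'   optical axis is `<= cam$near_limit`.
#' @export
project_point <- function(p, pose, cam) {
  b <- camera_basis(pose)
  rel <- p - pose$position
  z <- sum(rel * b$zc)
  if (z <= cam$near_limit)
    stop_scopeskill("behind_camera",
                    sprintf("point at depth %.3f mm is behind the image plane", z))
  cam$principal_point + cam$focal_px * c(sum(rel * b$xc), sum(rel * b$yc)) / z
}

# Vectorised projection: pts is n x 3; returns list(px = n x 2, depth = n).
project_points <- function(pts, pose, cam) {
  b <- camera_basis(pose)
  rel <- sweep(pts, 2, pose$position)
  z <- drop(rel %*% b$zc)
  px <- cbind(cam$principal_point[1] + cam$focal_px * drop(rel %*% b$xc) / z,
              cam$principal_point[2] + cam$focal_px * drop(rel %*% b$yc) / z)
  list(px = px, depth = z)
}

# n points on a 3-D circle (centre, unit normal, radius).
circle3d_points <- function(center, normal, radius, n = 64) {
  nrm <- unitize(normal)
  e1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(e1 - sum(e1 * nrm) * nrm)
  e2 <- cross3(nrm, e1)
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  sweep(radius * (outer(cos(tt), e1) + outer(sin(tt), e2)), 2, center, `+`)
}

#' Project a ring target into the image
#'
#' Projects the outer and inner boundary circles of a black annulus target
#' as closed polygonal curves (the exact projection of a circle is a conic;
#' the polygonal approximation uses `n_vertices` samples per boundary).
#'
#' @param target a target marker, see [make_target_layout()].
#' @param pose a [tip_pose()].
#' @param cam a [camera_model()].
#' @param n_vertices vertices per boundary curve (>= 64).
#' @return an object of class `projected_ring`: list with `outer`, `inner`
#'   (n x 2 px matrices) and `visible = TRUE`. Signals
#'   `scopeskill_not_visible` if any boundary sample is behind the camera
#'   or outside a 120-degree viewing cone, and
#'   `scopeskill_oblique_degenerate` if the view ray meets the ring plane
#'   at under 5 degrees (grazing view).
#' @export
project_ring <- function(target, pose, cam, n_vertices = 64) {
  n_vertices <- max(64L, as.integer(n_vertices))
  ray <- target$center - pose$position
  rayu <- ray / vnorm(ray)
  # angle between the view ray and the ring plane
  plane_angle <- rad2deg(asin(min(1, abs(sum(rayu * unitize(target$normal))))))
  if (plane_angle < 5)
    stop_scopeskill("oblique_degenerate",
                    sprintf("ring viewed at %.2f deg to its plane", plane_angle))
  out3 <- circle3d_points(target$center, target$normal, target$ring_outer_radius, n_vertices)
  in3 <- circle3d_points(target$center, target$normal, target$ring_inner_radius, n_vertices)
  all3 <- rbind(out3, in3)
  b <- camera_basis(pose)
  rel <- sweep(all3, 2, pose$position)
  z <- drop(rel %*% b$zc)
  if (any(z <= cam$near_limit))
    stop_scopeskill("not_visible", "part of the ring is behind the image plane")
  ang <- acos(pmin(1, z / sqrt(rowSums(rel^2))))
  if (any(ang > deg2rad(60)))
    stop_scopeskill("not_visible", "ring extends outside the 120-degree viewing cone")
  px <- cbind(cam$principal_point[1] + cam$focal_px * drop(rel %*% b$xc) / z,
              cam$principal_point[2] + cam$focal_px * drop(rel %*% b$yc) / z)
  structure(list(outer = px[seq_len(n_vertices), , drop = FALSE],
                 inner = px[n_vertices + seq_len(n_vertices), , drop = FALSE],
                 visible = TRUE),
            class = "projected_ring")
}

#' On-screen reticle ellipse
#'
#' The overlay the user must place inside the target ring. It is fixed at
#' the principal point; its semi-axes are the difficulty knob (a wider
#' overlay demands a closer, better-centred view).
#'
#' @param semi_major,semi_minor semi-axes, px.
#' @param orientation major-axis orientation in the image plane, degrees.
#' @param center ellipse centre, px (the principal point).
#' @return an object of class `overlay_ellipse`.
#' @export
overlay_ellipse <- function(semi_major = 40, semi_minor = 28,
                            orientation = 0, center = c(320, 240)) {
  if (!(semi_minor > 0 && semi_major >= semi_minor))
    stop_scopeskill("config_invalid",
                    "need 0 < semi_minor <= semi_major for the overlay ellipse")
  structure(list(center = as.numeric(center), semi_major = semi_major,
                 semi_minor = semi_minor, orientation = orientation),
            class = "overlay_ellipse")
}

# Polygonal approximation of an overlay ellipse (n vertices, CCW).
ellipse_polygon <- function(overlay, n = 128) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  o <- deg2rad(overlay$orientation)
  x <- overlay$semi_major * cos(tt)
  y <- overlay$semi_minor * sin(tt)
  cbind(overlay$center[1] + x * cos(o) - y * sin(o),
        overlay$center[2] + x * sin(o) + y * cos(o))
}

# Ensure counter-clockwise orientation for the clipping kernel.
ccw_polygon <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Focus-accuracy score
#'
#' Percentage of the overlay ellipse lying inside the target's black ring
#' (inside its outer boundary by default: the black circle delimits the
#' valid zone). Computed by convex polygon clipping on 128-vertex
#' approximations.
#'
#' @param overlay an [overlay_ellipse()].
#' @param ring a `projected_ring` from [project_ring()].
#' @param boundary which ring boundary delimits the valid zone, `"outer"`
#'   (default) or `"inner"`.
#' @param n_vertices vertices for the overlay polygon.
#' @return score in `[0, 100]`: 100 iff the overlay is entirely inside,
#'   0 iff disjoint.
#' @export
accuracy_score <- function(overlay, ring, boundary = c("outer", "inner"),
                           n_vertices = 128) {
  boundary <- match.arg(boundary)
  ov <- ellipse_polygon(overlay, n_vertices)
  clip <- ccw_polygon(ring[[boundary]])
  a_ov <- abs(polygon_signed_area(ov))
  100 * clipped_area(ov, clip) / a_ov
}

#' Is the target correctly focused?
#'
#' TRUE iff the whole overlay ellipse lies inside the ring (score 100,
#' boundary-inclusive).
#'
#' @inheritParams accuracy_score
#' @return logical flag.
#' @export
is_focused <- function(overlay, ring, boundary = c("outer", "inner")) {
  accuracy_score(overlay, ring, boundary) >= 100 - 1e-9
}
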