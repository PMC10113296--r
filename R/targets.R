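# Ten ring targets on the wall of a simplified uterine cavity, plus the
# geometric solve that yields each target's ideal focusing pose and
# nominal scope roll. The cavity is modelled as a triangular prism:
# narrow at the internal os (where the fulcrum sits), widening toward the
# fundus, with the two cornua at the upper corners.

#' Cavity configuration
#'
#' @param depth fundus-to-isthmus depth along the insertion axis, mm.
#' @param width inter-cornual width, mm.
#' @param ap anteroposterior thickness, mm.
#' @param ring_outer_radius,ring_inner_radius outer/inner radius of the
#'   black annulus of each target, mm.
#' @param led_radius radius of the central LED disc, mm.
#' @param focus_distance working distance tip-to-target of the ideal
#'   focusing pose, mm.
#' @return an object of class `cavity_config`.
#' @export
cavity_config <- function(depth = 60, width = 40, ap = 25,
                          ring_outer_radius = 6, ring_inner_radius = 4,
                          led_radius = 2, focus_distance = 30) {
  if (any(c(depth, width, ap, focus_distance) <= 0))
    stop_scopeskill("config_invalid", "cavity dimensions must be positive")
  if (!(0 < led_radius && led_radius < ring_inner_radius &&
        ring_inner_radius < ring_outer_radius))
    stop_scopeskill("config_invalid",
                    "need 0 < led_radius < ring_inner_radius < ring_outer_radius")
  structure(as.list(environment()), class = "cavity_config")
}

target_marker <- function(id, center, normal, label, cavity) {
  structure(list(
    id = id, center = as.numeric(center), normal = unitize(normal),
    ring_outer_radius = cavity$ring_outer_radius,
    ring_inner_radius = cavity$ring_inner_radius,
    led_radius = cavity$led_radius,
    nominal_roll = NA_real_, ideal_pose = NULL, focus_distance = NA_real_,
    anatomical_label = label
  ), class = "target_marker")
}

#' Build the ten-target navigation layout
#'
#' Places the ten ring markers at their anatomical stations (fundus,
#' cornua, tubal ostia, anterior/posterior/lateral walls, isthmus) on the
#' cavity wall, with normals pointing into the cavity, and solves each
#' target's ideal focusing pose and nominal scope roll (see
#' [solve_focus_pose()]).
#'
#' @param cavity a [cavity_config()].
#' @param geom an [arm_geometry()].
#' @param cam a [camera_model()].
#' @return a list of 10 `target_marker` objects, each carrying
#'   `nominal_roll` (degrees) and `ideal_pose` (a [tip_pose()]).
#' @export
make_target_layout <- function(cavity = cavity_config(),
                               geom = arm_geometry(),
                               cam = camera_model()) {
  d <- cavity$depth; w <- cavity$width; ap <- cavity$ap
  spec <- list(
    list("fundus",             c(0, 0, d),                 c(0, 0, -1)),
    list("left cornua",        c(-0.45 * w, 0, 0.93 * d),  c(0.6, 0, -0.8)),
    list("right cornua",       c(0.45 * w, 0, 0.93 * d),   c(-0.6, 0, -0.8)),
    list("left ostium",        c(-0.375 * w, 0, 0.83 * d), c(0.7, 0, -0.5)),
    list("right ostium",       c(0.375 * w, 0, 0.83 * d),  c(-0.7, 0, -0.5)),
    list("anterior wall",      c(0, 0.44 * ap, 0.58 * d),  c(0, -1, -0.5)),
    list("posterior wall",     c(0, -0.44 * ap, 0.58 * d), c(0, 1, -0.5)),
    list("left lateral wall",  c(-0.275 * w, 0, 0.58 * d), c(1, 0, -0.55)),
    list("right lateral wall", c(0.275 * w, 0, 0.58 * d),  c(-1, 0, -0.55)),
    list("isthmus",            c(0, -0.24 * ap, 0.25 * d), c(0, 0.8, -0.3))
  )
  targets <- vector("list", 10)
  for (i in seq_along(spec)) {
    tg <- target_marker(i, spec[[i]][[2]], spec[[i]][[3]], spec[[i]][[1]], cavity)
    # a forward-oblique optic cannot view a near-entrance marker from far
    # away, so cap the working distance by the marker's distance from the
    # fulcrum
    tg$focus_distance <- min(cavity$focus_distance,
                             0.55 * vnorm(tg$center - geom$rcm_point))
    sol <- solve_focus_pose(tg, geom, cam, distance = tg$focus_distance)
    tg$nominal_roll <- sol$roll
    tg$ideal_pose <- sol$pose
    targets[[i]] <- tg
  }
  targets
}

#' Ideal focusing pose for a ring target
#'
#' Finds a tip pose whose view ray passes through the target centre at the
#' given working distance while the shaft passes through the fulcrum and
#' the optical axis keeps its fixed oblique offset from the shaft. With
#' `roll = NULL` the remaining free degree of freedom is closed by keeping
#' the view ray, shaft and insertion axis coplanar (1-D root find), and the
#' scope roll realising that view is returned as the target's nominal
#' roll. With a fixed `roll` the shaft direction is re-solved by a damped
#' fixed-point iteration started from the coplanar solution, which is how
#' a user keeps a target in view with an imperfect roll.
#'
#' @param target a `target_marker`.
#' @param geom an [arm_geometry()].
#' @param cam a [camera_model()].
#' @param roll scope roll in degrees, or `NULL` to solve for it.
#' @param distance working distance from tip to target centre, mm.
#' @return list with `pose` (a [tip_pose()]), `roll` (degrees) and
#'   `residual` (mm, distance from the view ray at `distance` to the
#'   target centre). Signals `scopeskill_unreachable` when no pose exists.
#' @export
solve_focus_pose <- function(target, geom, cam, roll = NULL, distance = 30) {
  Fc <- geom$rcm_point
  cvec <- target$center
  off <- geom$optic_offset
  m <- unitize(cvec - Fc)
  if (is.null(roll)) {
    # coplanar closure: view direction w(eta) rotated from m about an axis
    # perpendicular to the (m, insertion-axis) plane
    pref <- c(0, 0, 1)
    ax <- cross3(m, pref)
    if (vnorm(ax) < 1e-6) ax <- cross3(m, c(0, 1, 0))
    ax <- unitize(ax)
    gfun <- function(eta) {
      w <- drop(rot_axis(ax, eta) %*% m)
      tipp <- cvec - distance * w
      u <- tipp - Fc
      nu <- vnorm(u)
      if (nu < 1e-9) return(90 - off)
      rad2deg(acos(pmin(1, pmax(-1, sum(u / nu * w))))) - off
    }
    root <- NULL
    for (iv in list(c(1e-6, 1.4), c(-1.4, -1e-6))) {
      g1 <- gfun(iv[1]); g2 <- gfun(iv[2])
      if (is.finite(g1) && is.finite(g2) && g1 * g2 < 0) {
        root <- stats::uniroot(gfun, iv, tol = 1e-12)$root
        break
      }
    }
    if (is.null(root))
      stop_scopeskill("unreachable",
                      sprintf("no coplanar focusing pose for target %d (%s)",
                              target$id, target$anatomical_label))
    w <- drop(rot_axis(ax, root) %*% m)
    tipp <- cvec - distance * w
    u <- unitize(tipp - Fc)
    depth <- vnorm(tipp - Fc)
    fr <- shaft_frame(u)
    wp <- unitize(w - sum(w * u) * u)
    roll_out <- rad2deg(atan2(-sum(wp * fr$y0), sum(wp * fr$x0)))
    pose <- tip_pose(u, depth, roll_out, geom)
  } else {
    # start from the coplanar solution's shaft direction (cached on the
    # target when the layout was built)
    u <- if (!is.null(target$ideal_pose)) target$ideal_pose$shaft_dir
         else solve_focus_pose(target, geom, cam, roll = NULL,
                               distance = distance)$pose$shaft_dir
    lambda <- 0.5
    converged <- FALSE
    for (k in seq_len(300)) {
      v <- view_direction(u, roll, off)
      tipp <- cvec - distance * v
      if (vnorm(tipp - Fc) < 1e-9) break
      u_new <- unitize(tipp - Fc)
      stepn <- vnorm(u_new - u)
      u <- unitize((1 - lambda) * u + lambda * u_new)
      if (stepn < 1e-13) { converged <- TRUE; break }
    }
    v <- view_direction(u, roll, off)
    tipp <- cvec - distance * v
    if (!converged && vnorm(unitize(tipp - Fc) - u) > 1e-9)
      stop_scopeskill("unreachable",
                      sprintf("no focusing pose at roll %.1f deg for target %d",
                              roll, target$id))
    depth <- vnorm(tipp - Fc)
    roll_out <- roll
    pose <- tip_pose(u, depth, roll_out, geom)
  }
  resid <- vnorm(pose$position + distance * pose$view_dir - cvec)
  if (pose$insertion_depth < 0 || resid > 1e-6)
    stop_scopeskill("unreachable",
                    sprintf("focusing pose invalid for target %d (residual %.2e mm)",
                            target$id, resid))
  list(pose = pose, roll = roll_out, residual = resid)
}

#' Randomised target orders
#'
#' Five distinct permutations of the ten target ids, deterministic in the
#' seed; trials use them round-robin (trial i takes order `(i - 1) %% 5 + 1`)
#' so that users cannot memorise a single sequence.
#'
#' @param seed integer seed.
#' @param n_orders number of orders (default 5).
#' @param n_targets number of targets (default 10).
#' @return list of `n_orders` integer permutations of `1:n_targets`.
#' @export
make_orders <- function(seed, n_orders = 5, n_targets = 10) {
  withr::with_seed(as.integer(seed), {
    orders <- list()
    while (length(orders) < n_orders) {
      cand <- sample.int(n_targets)
      if (!any(vapply(orders, function(o) all(o == cand), logical(1))))
        orders[[length(orders) + 1]] <- cand
    }
    orders
  })
}
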