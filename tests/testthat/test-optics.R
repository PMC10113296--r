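test_that("pinhole projection maps axis points to the principal point and matches a matrix oracle", {
  sc <- default_scene()
  geom <- sc$geom; cam <- sc$cam
  pose <- tip_pose(c(0, 0, 1), 20, 35, geom)
  # point straight along the optical axis
  expect_equal(project_point(pose$position + 50 * pose$view_dir, pose, cam),
               cam$principal_point, tolerance = 1e-9)
  # scale invariance along the ray
  p1 <- project_point(pose$position + 15 * pose$view_dir + c(2, 1, 0), pose, cam)
  expect_type(p1, "double")
  # behind the camera
  expect_error(project_point(pose$position - 10 * pose$view_dir, pose, cam),
               class = "scopeskill_behind_camera")
  # random points against a homogeneous projection-matrix oracle
  b <- scopeskill:::camera_basis(pose)
  P <- cam$focal_px * rbind(b$xc, b$yc) # 2x3
  withr::with_seed(7, {
    for (i in 1:20) {
      q <- pose$position + 30 * pose$view_dir + runif(3, -10, 10)
      rel <- q - pose$position
      z <- sum(rel * b$zc)
      oracle <- cam$principal_point + drop(P %*% rel) / z
      expect_equal(project_point(q, pose, cam), oracle, tolerance = 1e-6)
    }
  })
})

test_that("projected rings obey pinhole arithmetic and compose with per-point projection", {
  sc <- default_scene()
  geom <- sc$geom
  cam <- camera_model(optic_offset = 0)
  geom0 <- arm_geometry(optic_offset = 0)
  cavity <- cavity_config()
  D <- 40; r_out <- cavity$ring_outer_radius
  pose <- tip_pose(c(0, 0, 1), 10, 0, geom0)
  face_on <- structure(list(id = 1L, center = pose$position + c(0, 0, D),
                            normal = c(0, 0, -1), ring_outer_radius = r_out,
                            ring_inner_radius = cavity$ring_inner_radius,
                            led_radius = cavity$led_radius),
                       class = "target_marker")
  ring <- project_ring(face_on, pose, cam)
  rad <- sqrt(rowSums(sweep(ring$outer, 2, cam$principal_point)^2))
  expect_equal(mean(rad), cam$focal_px * r_out / D, tolerance = 1e-6)
  expect_lt(diff(range(rad)), 1e-6)  # concentric circle

  # tilted ring projects to an ellipse with axis ratio cos(tilt)
  tilted <- face_on
  tilted$normal <- c(sin(pi / 3), 0, -cos(pi / 3))
  ring_t <- project_ring(tilted, pose, cam, n_vertices = 256)
  ctr <- colMeans(ring_t$outer)
  rel <- sweep(ring_t$outer, 2, ctr)
  sv <- svd(rel)$d
  expect_equal(sv[2] / sv[1], cos(pi / 3), tolerance = 0.02)

  # vertices agree with project_point applied to the same 3-D samples
  pts3 <- scopeskill:::circle3d_points(face_on$center, face_on$normal,
                                       r_out, 64)
  px <- t(apply(pts3, 1, project_point, pose = pose, cam = cam))
  expect_equal(ring$outer, px, tolerance = 1e-9, ignore_attr = TRUE)

  # grazing view is refused
  grazing <- face_on
  grazing$normal <- c(1, 0, -0.02)
  expect_error(project_ring(grazing, pose, cam),
               class = "scopeskill_oblique_degenerate")
})

test_that("accuracy score is the clipped-area fraction, checked against rasterization", {
  pp <- c(320, 240)
  circle_poly <- function(r, ctr = pp, n = 256) {
    tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(ctr[1] + r * cos(tt), ctr[2] + r * sin(tt))
  }
  fake_ring <- function(outer_poly) structure(
    list(outer = outer_poly, inner = outer_poly * 0.5, visible = TRUE),
    class = "projected_ring")

  small <- overlay_ellipse(20, 14, 0, pp)
  expect_equal(accuracy_score(small, fake_ring(circle_poly(80))), 100)
  # disjoint
  far <- overlay_ellipse(20, 14, 0, pp + c(500, 0))
  expect_equal(accuracy_score(far, fake_ring(circle_poly(80))), 0)
  # equal circles, centres one radius apart: known lens area
  r <- 50
  ov <- overlay_ellipse(r, r, 0, pp + c(r, 0))
  got <- accuracy_score(ov, fake_ring(circle_poly(r)))
  lens_frac <- (2 * pi / 3 - sqrt(3) / 2) / pi * 100  # closed form, d = r
  expect_equal(got, lens_frac, tolerance = 0.2)
  withr::with_seed(13, {
    mc <- oracle_overlap_pct(ov, circle_poly(r))
    expect_lt(abs(got - mc), 0.5)
  })
})

test_that("score is monotone under translation away from the ring and under overlay growth", {
  pp <- c(320, 240)
  tt <- seq(0, 2 * pi, length.out = 129)[-129]
  ring <- structure(list(outer = cbind(pp[1] + 60 * cos(tt), pp[2] + 60 * sin(tt)),
                         inner = cbind(pp[1] + 40 * cos(tt), pp[2] + 40 * sin(tt)),
                         visible = TRUE), class = "projected_ring")
  dirs <- list(c(1, 0), c(0, 1), c(0.6, -0.8))
  for (d in dirs) {
    scores <- vapply(seq(0, 140, by = 10), function(s)
      accuracy_score(overlay_ellipse(40, 28, 0, pp + s * d), ring), numeric(1))
    expect_true(all(diff(scores) <= 1e-9))
  }
  # widening the overlay (difficulty up) never helps
  s_by_width <- vapply(seq(30, 90, by = 10), function(w)
    accuracy_score(overlay_ellipse(w, 28, 0, pp + c(30, 0)), ring), numeric(1))
  expect_true(all(diff(s_by_width) <= 1e-9))
  # rigid-motion invariance of the pair
  shift <- c(37, -12)
  rot <- function(p, a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sweep(sweep(p, 2, pp) %*% t(R), 2, pp + shift, `+`)
  }
  a <- 0.7
  ring2 <- structure(list(outer = rot(ring$outer, a), inner = rot(ring$inner, a),
                          visible = TRUE), class = "projected_ring")
  ov1 <- overlay_ellipse(40, 28, 10, pp + c(25, 5))
  ctr2 <- drop(rot(matrix(pp + c(25, 5), 1, 2), a))
  ov2 <- overlay_ellipse(40, 28, 10 + a * 180 / pi, ctr2)
  expect_equal(accuracy_score(ov1, ring), accuracy_score(ov2, ring2),
               tolerance = 1e-6)
})

test_that("is_focused is the boundary-inclusive 100% predicate", {
  pp <- c(320, 240)
  tt <- seq(0, 2 * pi, length.out = 129)[-129]
  ring <- structure(list(outer = cbind(pp[1] + 60 * cos(tt), pp[2] + 60 * sin(tt)),
                         inner = cbind(pp[1] + 40 * cos(tt), pp[2] + 40 * sin(tt)),
                         visible = TRUE), class = "projected_ring")
  expect_true(is_focused(overlay_ellipse(30, 20, 0, pp), ring))
  # tangent from inside (polygonal boundary: use the inscribed radius)
  r_in <- 60 * cos(pi / 128)
  expect_true(is_focused(overlay_ellipse(r_in, r_in, 0, pp), ring))
  off <- overlay_ellipse(40, 28, 0, pp + c(25, 0))
  sc <- accuracy_score(off, ring)
  expect_lt(sc, 100)
  expect_false(is_focused(off, ring))
})
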