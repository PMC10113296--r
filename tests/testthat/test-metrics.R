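test_that("trajectory length matches a hand-summed log and stationary logs score zero", {
  sc <- default_scene()
  geom <- sc$geom
  # hand-built 5-sample log with known tip positions on the insertion axis
  depths <- c(5, 12, 9, 20, 20)
  par <- cbind(0, 0, depths, 0)
  th <- scopeskill:::encoders_from_params(par, geom)
  samples <- data.frame(t = seq(0, 0.04, by = 0.01), theta1 = th[, 1],
                        theta2 = th[, 2], theta3 = th[, 3], theta6 = th[, 4],
                        pedal = c(0, 0, 0, 0, 1))
  events <- data.frame(target_id = rep(1L, 10),
                       t_press = seq(0.04, length.out = 10, by = 0.01),
                       accuracy_at_press = 50, roll_at_press = 0,
                       timed_out = FALSE)
  log <- structure(list(trial_index = 1L, protocol = exercise_protocol(1:10),
                        samples = samples, events = events),
                   class = "trial_log")
  m <- compute_trial_metrics(log, geom, sc$targets, "S1")
  expect_equal(m$traj_length_mm, sum(abs(diff(depths))))  # 7 + 3 + 11 + 0
  expect_equal(m$total_rotation_deg, 0)
  expect_equal(m$accuracy_pct, 50)

  # stationary never-press trial: all timeouts, zero path, 300 s
  prot <- exercise_protocol(1:10, dt = 0.02)
  slog <- run_trial(statue_agent(dt = 0.02), prot, geom, sc$cam, sc$targets,
                    1, seed = 3)
  sm <- compute_trial_metrics(slog, geom, sc$targets, "S1")
  expect_equal(sm$exec_time_s, 300)
  expect_equal(sm$accuracy_pct, 0)
  expect_equal(sm$traj_length_mm, 0)
  expect_equal(sm$total_rotation_deg, 0)

  expect_error(compute_trial_metrics(
    structure(list(samples = samples[0, ], events = events), class = "trial_log"),
    geom, sc$targets), class = "scopeskill_empty_log")
})

test_that("an agent moving straight between ideal poses achieves unit economy ratios", {
  sc <- default_scene()
  geom <- sc$geom
  dt <- 0.01
  # straight-line tip interpolation between consecutive ideal poses: any
  # tip position determines its shaft parameters uniquely via the fulcrum
  straight_agent <- list(plan = function(current, target, trial_index, max_time) {
    p0 <- scopeskill:::params_pose(current, geom)$position
    r0 <- current[4]
    p1 <- target$ideal_pose$position
    r1 <- target$ideal_pose$roll
    n <- 100
    s <- seq_len(n) / n
    tips <- outer(1 - s, p0) + outer(s, p1)
    u <- tips / sqrt(rowSums(tips^2))
    droll <- scopeskill::wrap_angle((r1 - r0) * pi / 180) * 180 / pi
    par <- cbind(acos(pmin(1, u[, 3])), atan2(u[, 2], u[, 1]),
                 sqrt(rowSums(tips^2)), r0 + s * droll)
    list(par = par, press_idx = n)
  })
  prot <- exercise_protocol(make_orders(8)[[1]], dt = dt)
  log <- run_trial(straight_agent, prot, geom, sc$cam, sc$targets, 1, seed = 1)
  m <- compute_trial_metrics(log, geom, sc$targets, "S1")
  expect_equal(m$econ_translation, 1, tolerance = 0.002)
  expect_equal(m$econ_rotation, 1, tolerance = 0.002)
  # path length can never undercut the first-to-last straight line
  first_last <- vnorm(scopeskill:::params_pose(c(0, 0, 5, 0), geom)$position -
                        sc$targets[[prot$order[10]]]$ideal_pose$position)
  expect_gte(m$traj_length_mm, first_last - 1e-9)
})

test_that("the ideal economy baseline is a pairwise-distance sum, reversal-invariant between targets", {
  sc <- default_scene()
  prot <- exercise_protocol(make_orders(5)[[2]])
  base <- ideal_economy_baseline(prot, sc$targets, sc$geom)
  # brute-force oracle
  tips <- t(vapply(sc$targets[prot$order], function(tg) tg$ideal_pose$position,
                   numeric(3)))
  legs <- sum(sqrt(rowSums((tips[-1, ] - tips[-10, ])^2)))
  home_tip <- scopeskill:::params_pose(c(0, 0, 5, 0), sc$geom)$position
  expect_equal(base$translation, legs + vnorm(tips[1, ] - home_tip),
               tolerance = 1e-9)
  expect_gt(base$rotation, 0)
  # reversal invariance of the inter-target portion
  rev_prot <- exercise_protocol(rev(prot$order))
  b1 <- ideal_economy_baseline(prot, sc$targets, sc$geom, include_entry = FALSE)
  b2 <- ideal_economy_baseline(rev_prot, sc$targets, sc$geom, include_entry = FALSE)
  expect_equal(b1$translation, b2$translation, tolerance = 1e-9)
  expect_equal(b1$rotation, b2$rotation, tolerance = 1e-9)
  # coincident consecutive ideal poses contribute a zero leg
  twin <- sc$targets
  twin[[prot$order[2]]]$ideal_pose <- twin[[prot$order[1]]]$ideal_pose
  b3 <- ideal_economy_baseline(prot, twin, sc$geom, include_entry = FALSE)
  tips3 <- tips; tips3[2, ] <- tips3[1, ]
  expect_equal(b3$translation,
               sum(sqrt(rowSums((tips3[-1, ] - tips3[-10, ])^2))),
               tolerance = 1e-9)
})

test_that("metrics are stable under uniform time-resampling of the log", {
  sc <- default_scene()
  params <- sample_cohort(1, seed = 9)[[1]]
  agent <- nav_agent(params, sc$geom, sc$cam, sc$overlay)
  prot <- exercise_protocol(make_orders(2)[[1]])
  log <- run_trial(agent, prot, sc$geom, sc$cam, sc$targets, 5, seed = 12)
  m1 <- compute_trial_metrics(log, sc$geom, sc$targets, "S1")
  # keep every second sample (preserving pedal samples)
  keep <- sort(union(seq(1, nrow(log$samples), by = 2),
                     which(log$samples$pedal == 1)))
  log2 <- log
  log2$samples <- log$samples[keep, ]
  m2 <- compute_trial_metrics(log2, sc$geom, sc$targets, "S1")
  expect_equal(m2$traj_length_mm, m1$traj_length_mm,
               tolerance = 0.005)
  expect_equal(m2$accuracy_pct, m1$accuracy_pct)
  expect_equal(m2$orientation_error_deg, m1$orientation_error_deg)
})

test_that("metrics CSV round-trips with the exact column contract", {
  sc <- default_scene()
  params <- sample_cohort(1, seed = 4)[[1]]
  prot <- list(exercise_protocol(make_orders(1)[[1]]),
               exercise_protocol(make_orders(1)[[2]]))
  sess <- simulate_session(params, prot, sc$geom, sc$cam, sc$targets, seed = 8)
  m <- compute_session_metrics(sess, sc$geom, sc$targets)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, path)
  header <- readLines(path, n = 1)
  expect_identical(header, paste("subject_id,trial_index,exec_time_s",
                                 "accuracy_pct,orientation_error_deg",
                                 "traj_length_mm,total_rotation_deg",
                                 "econ_translation,econ_rotation", sep = ","))
  back <- read_metrics(path)
  expect_equal(back$traj_length_mm, m$traj_length_mm, tolerance = 1e-12)
  expect_error(write_metrics(m[, -3], path), class = "scopeskill_config_invalid")
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_metrics(bad), class = "scopeskill_schema_mismatch")
})
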