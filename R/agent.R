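# Synthetic-surgeon cohort. Each agent carries per-metric learning
# parameters (initial level, asymptote, rate); its skill on trial i
# follows an exponential approach to the asymptote,
#   level(i) = c + (a - c) * exp(-k * (i - 1)),
# which produces the logarithmic-looking trial-mean curves seen in
# dry-lab navigation studies. Motion is a minimum-jerk reach in shaft
# space (tilt about the fulcrum, insertion depth, roll) corrupted by
# smooth path jitter, a terminal aiming offset, a persistent roll error,
# and noisy self-assessment of the focus score that gates the pedal press.

agent_channels <- c("time", "path_jitter", "roll_jitter", "aim_error",
                    "press_noise")

#' Learning-schedule level
#'
#' @param a initial level, `c_` asymptote, `k` learning rate (> 0).
#' @param trial trial index (1-based).
#' @return `c_ + (a - c_) * exp(-k * (trial - 1))`, monotone non-increasing
#'   in `trial` for `a >= c_`.
#' @export
schedule_level <- function(a, c_, k, trial) c_ + (a - c_) * exp(-k * (trial - 1))

#' Per-class priors for the synthetic cohort
#'
#' Mean initial level `a`, asymptote `c` and learning rate `k` of each
#' skill channel for the three experience classes, plus the cohort class
#' mix. Units: `time` is seconds per trial; `path_jitter` mm of tip
#' jitter amplitude; `roll_jitter` degrees of persistent roll error
#' (the channel that drives orientation error); `aim_error` degrees of
#' terminal shaft aiming offset; `press_noise` score points of
#' self-assessment noise.
#'
#' @param proportions named class proportions (must sum to 1).
#' @return a `cohort_priors` list.
#' @export
default_cohort_priors <- function(proportions = c(novice = 0.4,
                                                  intermediate = 0.4,
                                                  expert = 0.2)) {
  proportions <- unlist(proportions)
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop_scopeskill("config_invalid", "class proportions must be >= 0 and sum to 1")
  if (!all(names(proportions) %in% c("novice", "intermediate", "expert")) ||
      is.null(names(proportions)))
    stop_scopeskill("config_invalid",
                    "proportions must be named novice/intermediate/expert")
  classes <- list(
    novice = list(
      a = c(time = 210, path_jitter = 4.0, roll_jitter = 52, aim_error = 7.0, press_noise = 16),
      c = c(time = 100, path_jitter = 2.6, roll_jitter = 42, aim_error = 1.8, press_noise = 8.0),
      k = c(time = 0.13, path_jitter = 0.12, roll_jitter = 0.05, aim_error = 0.12, press_noise = 0.12)),
    intermediate = list(
      a = c(time = 170, path_jitter = 3.2, roll_jitter = 46, aim_error = 5.5, press_noise = 13),
      c = c(time = 92,  path_jitter = 2.2, roll_jitter = 38, aim_error = 1.5, press_noise = 6.5),
      k = c(time = 0.15, path_jitter = 0.14, roll_jitter = 0.06, aim_error = 0.14, press_noise = 0.14)),
    expert = list(
      a = c(time = 130, path_jitter = 2.4, roll_jitter = 40, aim_error = 4.0, press_noise = 9),
      c = c(time = 80,  path_jitter = 1.7, roll_jitter = 33, aim_error = 1.2, press_noise = 5.0),
      k = c(time = 0.18, path_jitter = 0.16, roll_jitter = 0.07, aim_error = 0.16, press_noise = 0.16))
  )
  for (cl in classes)
    if (any(cl$a < cl$c) || any(cl$k <= 0) || any(cl$c <= 0))
      stop_scopeskill("config_invalid", "priors must satisfy a >= c > 0, k > 0")
  structure(list(classes = classes, proportions = proportions,
                 subject_sigma = 0.18),
            class = "cohort_priors")
}

#' Sample a synthetic cohort
#'
#' Draws `n` agent parameter sets. Experience classes are assigned in the
#' configured proportions (deterministically rounded, then shuffled);
#' within a class, each subject's `a` and `c` get a common lognormal
#' subject factor and `k` an independent one, so that better-than-average
#' novices exist but every subject keeps `a >= c > 0`.
#'
#' @param n cohort size (>= 1).
#' @param priors a [default_cohort_priors()] object.
#' @param seed integer seed; the draw is deterministic in it.
#' @return list of `agent_params` objects (fields `subject_id`,
#'   `experience_class`, `a`, `c`, `k`).
#' @export
sample_cohort <- function(n, priors = default_cohort_priors(), seed = 1) {
  if (n < 1) stop_scopeskill("config_invalid", "cohort size must be >= 1")
  withr::with_seed(as.integer(seed), {
    counts <- floor(n * priors$proportions)
    while (sum(counts) < n) {
      i <- which.max(n * priors$proportions - counts)
      counts[i] <- counts[i] + 1
    }
    labels <- sample(rep(names(counts), counts))
    lapply(seq_len(n), function(i) {
      cl <- priors$classes[[labels[i]]]
      f_level <- exp(stats::rnorm(length(agent_channels), 0, priors$subject_sigma))
      f_rate <- exp(stats::rnorm(length(agent_channels), 0, priors$subject_sigma))
      names(f_level) <- names(f_rate) <- agent_channels
      structure(list(subject_id = sprintf("S%03d", i),
                     experience_class = labels[i],
                     a = cl$a * f_level, c = cl$c * f_level,
                     k = cl$k * f_rate),
                class = "agent_params")
    })
  })
}

#' Construct a navigation agent
#'
#' Wraps a parameter set into the motion-policy object consumed by
#' [run_trial()]: its `plan()` method produces the shaft-space sample
#' stream for one target approach (see [plan_motion()]).
#'
#' @param params an `agent_params` set from [sample_cohort()].
#' @param geom,cam,overlay scene the agent acts in.
#' @param dt sampling period, seconds.
#' @return a `nav_agent` list with a `plan` function.
#' @export
nav_agent <- function(params, geom, cam, overlay = overlay_ellipse(),
                      dt = 0.01) {
  force(params); force(geom); force(cam); force(overlay); force(dt)
  structure(list(
    params = params,
    plan = function(current, target, trial_index, max_time) {
      plan_motion(current, target, params, trial_index, geom, cam,
                  overlay, dt = dt, max_time = max_time)
    }), class = "nav_agent")
}

# Smooth zero-mean jitter: sum of 3 random sinusoids, windowed to vanish
# at both ends of the move.
jitter_wave <- function(n, dt, amplitude) {
  if (amplitude <= 0 || n < 4) return(numeric(n))
  tt <- dt * seq_len(n)
  w <- numeric(n)
  for (j in 1:3) {
    f <- stats::runif(1, 0.4, 1.6)
    w <- w + stats::rnorm(1, 0, 1) * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  }
  s <- seq(0, 1, length.out = n)
  amplitude / sqrt(3) * w * (4 * s * (1 - s))
}

min_jerk <- function(x) x^3 * (10 - 15 * x + 6 * x^2)

# Minimum-jerk interpolation of shaft parameters over n samples, with
# angular channels (azimuth, roll) taken along the shortest arc.
reach_segment <- function(from, to, n) {
  s <- min_jerk(seq_len(n) / n)
  d_az <- wrap_angle(to[2] - from[2])
  d_roll <- rad2deg(wrap_angle(deg2rad(to[4] - from[4])))
  cbind(from[1] + s * (to[1] - from[1]),
        from[2] + s * d_az,
        from[3] + s * (to[3] - from[3]),
        from[4] + s * d_roll)
}

#' Plan one target approach
#'
#' Produces the timed shaft-parameter samples of a single reach: a
#' minimum-jerk profile from the current pose to the target's focusing
#' pose (solved at this trial's roll error), plus smooth path and roll
#' jitter and a terminal aiming offset, followed by fixation: every 0.1 s
#' the agent compares its perceived focus score (true score + perception
#' noise) against 100 and either presses the pedal or makes a small
#' corrective movement toward the exact focusing pose. All noise
#' amplitudes follow the agent's learning schedule, so late trials are
#' faster, straighter and steadier.
#'
#' @param current length-4 shaft parameters (polar, azimuth, depth, roll).
#' @param target a `target_marker`.
#' @param params an `agent_params` set.
#' @param trial_index trial number (drives the learning schedule).
#' @param geom,cam,overlay scene objects.
#' @param dt sample period, s.
#' @param max_time time budget for this target, s.
#' @return `list(par, press_idx)`: sample matrix and pedal row (or NA).
#' @export
plan_motion <- function(current, target, params, trial_index,
                        geom, cam, overlay = overlay_ellipse(),
                        dt = 0.01, max_time = 30) {
  lv <- function(ch) schedule_level(params$a[[ch]], params$c[[ch]],
                                    params$k[[ch]], trial_index)
  # persistent roll error for this approach, compensated by re-aiming the
  # shaft so the target can still be focused
  roll_err <- stats::rnorm(1, 0, lv("roll_jitter"))
  goal_roll <- target$nominal_roll + roll_err
  goal <- tryCatch(
    pose_params(solve_focus_pose(target, geom, cam, roll = goal_roll,
                                 distance = target$focus_distance)$pose),
    scopeskill_unreachable = function(e) {
      p <- pose_params(target$ideal_pose)
      p[4] <- goal_roll
      p
    })
  # terminal aiming offset (shrinks over trials)
  aim <- deg2rad(lv("aim_error"))
  aimed <- goal + c(stats::rnorm(1, 0, aim),
                    stats::rnorm(1, 0, aim / max(sin(goal[1]), 0.3)),
                    stats::rnorm(1, 0, lv("aim_error") * 0.8),
                    stats::rnorm(1, 0, lv("aim_error") * 1.5))
  # reach duration: share of the trial-level time budget for one target
  t_move <- max(0.4, lv("time") / 10 * 0.75 * exp(stats::rnorm(1, 0, 0.2)))
  n_move <- max(4L, ceiling(t_move / dt))
  par <- reach_segment(current, aimed, n_move)
  # smooth jitter: tip-space mm mapped to tilt via the working depth
  amp_tilt <- lv("path_jitter") / max(goal[3], 15)
  par[, 1] <- par[, 1] + jitter_wave(n_move, dt, amp_tilt)
  par[, 2] <- par[, 2] + jitter_wave(n_move, dt, amp_tilt / max(sin(goal[1]), 0.3))
  par[, 3] <- par[, 3] + jitter_wave(n_move, dt, lv("path_jitter") * 0.8)
  par[, 4] <- par[, 4] + jitter_wave(n_move, dt, lv("roll_jitter") * 0.08)
  par[, 1] <- pmax(par[, 1], 0)
  par[, 3] <- pmax(par[, 3], 0.5)  # stay just inside the cavity

  # fixation: look, judge, press or correct
  chunks <- list(par)
  n_total <- n_move
  n_budget <- ceiling(max_time / dt) + 10L
  cur <- par[n_move, ]
  press_idx <- NA_integer_
  n_hold <- max(1L, round(0.1 / dt))
  sigma_press <- lv("press_noise")
  repeat {
    if (n_total >= n_budget) break
    hold <- matrix(cur, n_hold, 4, byrow = TRUE)
    chunks[[length(chunks) + 1]] <- hold
    n_total <- n_total + n_hold
    true_score <- score_params(cur, target, overlay, geom, cam)
    # perceived score: true score + overconfidence bias + perception noise
    if (true_score + sigma_press +
        stats::rnorm(1, 0, sigma_press) >= 100 - 1e-9) {
      press_idx <- n_total
      break
    }
    # corrective micro-movement toward the exact focusing pose
    n_corr <- max(2L, round(0.25 / dt))
    step_to <- cur + 0.45 * (goal - cur)
    corr <- reach_segment(cur, step_to, n_corr)
    chunks[[length(chunks) + 1]] <- corr
    n_total <- n_total + n_corr
    cur <- corr[n_corr, ]
  }
  list(par = do.call(rbind, chunks), press_idx = press_idx)
}

#' Simulate one subject's session
#'
#' Runs the agent through the supplied trial protocols (one per trial,
#' default 30) and returns the full session log. Bit-reproducible in the
#' seed.
#'
#' @param params an `agent_params` set.
#' @param protocols list of [exercise_protocol()]s, one per trial.
#' @param geom,cam,targets scene objects.
#' @param seed integer session seed.
#' @param config_fingerprint fingerprint string stored in the log header.
#' @return a `session_log`: list with `subject_id`, `seed`,
#'   `config_fingerprint` and `trials` (list of `trial_log`s).
#' @export
simulate_session <- function(params, protocols, geom, cam, targets,
                             seed = 1, config_fingerprint = "") {
  withr::with_seed(as.integer(seed), {
    trials <- lapply(seq_along(protocols), function(i) {
      agent <- nav_agent(params, geom, cam,
                         overlay = protocols[[i]]$overlay,
                         dt = protocols[[i]]$dt)
      run_trial(agent, protocols[[i]], geom, cam, targets, trial_index = i)
    })
    structure(list(subject_id = params$subject_id, seed = as.integer(seed),
                   config_fingerprint = config_fingerprint, trials = trials),
              class = "session_log")
  })
}

#' Standard session protocols
#'
#' The default session: `n_trials` trials using `n_orders` randomised
#' target orders assigned round-robin (trial i uses order
#' `(i - 1) %% n_orders + 1`).
#'
#' @param seed seed for [make_orders()].
#' @param n_trials trials per session.
#' @param n_orders distinct target orders.
#' @param ... passed to [exercise_protocol()].
#' @return list of [exercise_protocol()]s.
#' @export
session_protocols <- function(seed = 1, n_trials = 30, n_orders = 5, ...) {
  orders <- make_orders(seed, n_orders = n_orders)
  lapply(seq_len(n_trials), function(i) {
    oi <- (i - 1) %% n_orders + 1
    exercise_protocol(orders[[oi]], id = oi, ...)
  })
}
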