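# Trial engine for the camera-navigation exercise: sequence the ten
# targets in the protocol order, stream agent motion samples, record one
# acquisition event per target at the first pedal press (or at timeout),
# and log everything.

#' Exercise protocol
#'
#' @param order integer permutation of the target ids `1:10`.
#' @param time_limit maximum time allowed per target, seconds.
#' @param overlay an [overlay_ellipse()] (the difficulty knob).
#' @param dt sampling period of the simulated encoder stream, seconds
#'   (must be <= 0.02).
#' @param id protocol identifier stored in trial logs.
#' @return an object of class `exercise_protocol`.
#' @export
exercise_protocol <- function(order, time_limit = 30,
                              overlay = overlay_ellipse(), dt = 0.01,
                              id = NA_integer_) {
  if (length(order) < 1 || !all(sort(order) == seq_along(order)))
    stop_scopeskill("config_invalid", "order must be a permutation of target ids")
  if (time_limit <= 0) stop_scopeskill("config_invalid", "time limit must be > 0")
  if (dt <= 0 || dt > 0.02)
    stop_scopeskill("config_invalid", "sample period must be in (0, 0.02] s")
  structure(list(order = as.integer(order), time_limit = time_limit,
                 overlay = overlay, dt = dt, id = id),
            class = "exercise_protocol")
}

# Home pose parameters (polar, azimuth, depth, roll): scope just inside
# the cavity, shaft on the insertion axis.
home_params <- function() c(polar = 0, azimuth = 0, depth = 5, roll = 0)

# Accuracy of a single shaft-parameter sample against a target, as the
# exercise engine scores it: not-visible / degenerate views count as 0.
score_params <- function(par, target, overlay, geom, cam) {
  pose <- params_pose(par, geom)
  tryCatch(accuracy_score(overlay, project_ring(target, pose, cam)),
           scopeskill_not_visible = function(e) 0,
           scopeskill_oblique_degenerate = function(e) 0)
}

#' Run one trial of the camera-navigation exercise
#'
#' For each target in the protocol order the engine activates the target,
#' streams the agent's motion plan, and records an acquisition event at
#' the agent's first pedal press -- with the focus accuracy evaluated at
#' that very sample -- or a timed-out event (accuracy 0) when the
#' per-target clock runs out.
#'
#' @param agent a navigation agent: a list with a `plan(current_par,
#'   target, trial_index, max_time)` function returning `list(par, press_idx)`
#'   where `par` is an n x 4 matrix of shaft parameters (polar, azimuth in
#'   radians, depth in mm, roll in degrees) sampled at the protocol `dt`,
#'   and `press_idx` is the pedal-press row index or `NA`. See
#'   [nav_agent()].
#' @param protocol an [exercise_protocol()].
#' @param geom an [arm_geometry()].
#' @param cam a [camera_model()].
#' @param targets layout from [make_target_layout()].
#' @param trial_index index of this trial within the session (1..30).
#' @param seed optional integer; when given, the trial is run under its
#'   own RNG state and is bit-reproducible.
#' @return a `trial_log`: list with `trial_index`, `protocol`, `samples`
#'   (data.frame t, theta1..theta3, theta6, pedal) and `events`
#'   (data.frame target_id, t_press, accuracy_at_press, roll_at_press,
#'   timed_out).
#' @export
run_trial <- function(agent, protocol, geom, cam, targets,
                      trial_index = 1L, seed = NULL) {
  runner <- function() {
    dt <- protocol$dt
    cur <- home_params()
    t0 <- 0
    sample_chunks <- list()
    events <- vector("list", length(protocol$order))
    for (k in seq_along(protocol$order)) {
      tg <- targets[[protocol$order[k]]]
      plan <- agent$plan(cur, tg, trial_index, protocol$time_limit)
      n <- nrow(plan$par)
      if (n < 1)
        stop_scopeskill("agent_stall", "agent emitted no samples for a target")
      n_max <- max(1L, floor(protocol$time_limit / dt))
      press <- plan$press_idx
      if (!is.na(press) && press > n_max) press <- NA
      if (is.na(press)) {
        # timeout: keep (possibly truncated) samples up to the window end
        keep <- min(n, n_max)
        timed_out <- TRUE
      } else {
        keep <- press
        timed_out <- FALSE
      }
      par <- plan$par[seq_len(keep), , drop = FALSE]
      pedal <- numeric(keep)
      tvec <- t0 + dt * (seq_len(keep) - 1)
      if (!timed_out) {
        pedal[keep] <- 1
        acc <- score_params(par[keep, ], tg, protocol$overlay, geom, cam)
        t_press <- tvec[keep]
      } else {
        acc <- 0
        t_press <- t0 + protocol$time_limit
      }
      roll_press <- rad2deg(wrap_angle(deg2rad(par[keep, 4])))
      th <- encoders_from_params(par, geom)
      sample_chunks[[k]] <- cbind(t = tvec, theta1 = th[, 1], theta2 = th[, 2],
                                  theta3 = th[, 3], theta6 = th[, 4],
                                  pedal = pedal)
      events[[k]] <- data.frame(target_id = tg$id, t_press = t_press,
                                accuracy_at_press = acc,
                                roll_at_press = roll_press,
                                timed_out = timed_out)
      cur <- par[keep, ]
      t0 <- if (timed_out) t0 + protocol$time_limit else t_press + dt
    }
    samples <- as.data.frame(do.call(rbind, sample_chunks))
    structure(list(trial_index = as.integer(trial_index),
                   protocol = protocol,
                   samples = samples,
                   events = do.call(rbind, events)),
              class = "trial_log")
  }
  if (is.null(seed)) runner() else withr::with_seed(as.integer(seed), runner())
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("Trial %d: %d samples, %d/%d targets acquired, mean accuracy %.1f%%\n",
              x$trial_index, nrow(x$samples), sum(!x$events$timed_out),
              nrow(x$events), mean(x$events$accuracy_at_press)))
  invisible(x)
}
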