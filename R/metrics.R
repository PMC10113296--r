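# Per-trial evaluation indices: execution time, mean focus accuracy,
# mean orientation error, tool-tip trajectory length, total endoscope
# rotation, and the two economy-of-movement ratios (observed / ideal).

metric_columns <- c("exec_time_s", "accuracy_pct", "orientation_error_deg",
                    "traj_length_mm", "total_rotation_deg",
                    "econ_translation", "econ_rotation")

#' Ideal economy-of-movement baseline for a protocol
#'
#' The shortest useful motion for a trial: the sum of straight-line tip
#' distances between the ideal focusing poses of consecutive targets in
#' protocol order (optionally preceded by the entry leg from the home
#' pose), and the sum of minimal wrapped roll changes between consecutive
#' nominal orientations.
#'
#' @param protocol an [exercise_protocol()].
#' @param targets layout from [make_target_layout()].
#' @param geom an [arm_geometry()].
#' @param include_entry include the home-to-first-target leg in the
#'   translation baseline.
#' @return list with `translation` (mm) and `rotation` (degrees).
#' @export
ideal_economy_baseline <- function(protocol, targets, geom,
                                   include_entry = TRUE) {
  poses <- lapply(targets[protocol$order], function(tg) {
    if (is.null(tg$ideal_pose))
      stop_scopeskill("unreachable", "target has no ideal pose; rebuild the layout")
    tg$ideal_pose
  })
  tips <- t(vapply(poses, function(p) p$position, numeric(3)))
  rolls <- vapply(poses, function(p) p$roll, numeric(1))
  translation <- sum(sqrt(rowSums(diff(tips)^2)))
  rotation <- sum(abs(rad2deg(wrap_angle(deg2rad(diff(rolls))))))
  if (include_entry) {
    home <- params_pose(home_params(), geom)
    translation <- translation + vnorm(tips[1, ] - home$position)
    rotation <- rotation +
      abs(rad2deg(wrap_angle(deg2rad(rolls[1] - home$roll))))
  }
  list(translation = translation, rotation = rotation)
}

#' Compute the evaluation metrics of one trial
#'
#' `exec_time_s` is the time of the last acquisition event relative to the
#' first sample; `accuracy_pct` the mean of the per-target accuracies at
#' pedal press (timed-out targets count 0); `orientation_error_deg` the
#' mean wrapped difference between the roll at acquisition and the
#' target's nominal roll; `traj_length_mm` the summed tip displacement
#' over the resolved sample poses; `total_rotation_deg` the summed
#' absolute wrapped roll increments; the economy ratios divide the two
#' trajectory totals by the protocol's ideal baseline.
#'
#' @param log a `trial_log` from [run_trial()].
#' @param geom an [arm_geometry()].
#' @param targets layout from [make_target_layout()].
#' @param subject_id identifier copied into the result.
#' @return one-row data.frame with columns `subject_id`, `trial_index`,
#'   and the seven metric columns.
#' @export
compute_trial_metrics <- function(log, geom, targets, subject_id = NA_character_) {
  s <- log$samples
  if (is.null(s) || nrow(s) == 0)
    stop_scopeskill("empty_log", "trial log contains no samples")
  th <- cbind(s$theta1, s$theta2, s$theta3, s$theta6)
  res <- resolve_tip_poses(th, geom)
  if (!all(res$ok)) {
    bad <- which(!res$ok)[1]
    stop_scopeskill("unresolvable_sample",
                    sprintf("sample %d cannot be resolved to a pose", bad),
                    sample_index = bad)
  }
  traj <- sum(sqrt(rowSums(diff(res$position)^2)))
  rot <- sum(abs(rad2deg(wrap_angle(deg2rad(diff(res$roll))))))
  ev <- log$events
  nominal <- vapply(ev$target_id,
                    function(id) targets[[id]]$nominal_roll, numeric(1))
  orient <- mean(angle_diff_deg(ev$roll_at_press, nominal))
  base <- ideal_economy_baseline(log$protocol, targets, geom)
  data.frame(
    subject_id = subject_id,
    trial_index = log$trial_index,
    exec_time_s = max(ev$t_press) - s$t[1],
    accuracy_pct = mean(ev$accuracy_at_press),
    orientation_error_deg = orient,
    traj_length_mm = traj,
    total_rotation_deg = rot,
    econ_translation = traj / base$translation,
    econ_rotation = rot / base$rotation
  )
}

#' Metrics table for a whole session
#'
#' @param session a `session_log` from [simulate_session()].
#' @param geom,targets scene objects.
#' @return data.frame with one row per trial (columns as
#'   [compute_trial_metrics()]).
#' @export
compute_session_metrics <- function(session, geom, targets) {
  do.call(rbind, lapply(session$trials, compute_trial_metrics,
                        geom = geom, targets = targets,
                        subject_id = session$subject_id))
}

#' Write / read the per-trial metrics table
#'
#' Plain CSV with a mandatory header, comma separator and `.` decimal
#' mark, with exactly the columns `subject_id`, `trial_index`,
#' `exec_time_s`, `accuracy_pct`, `orientation_error_deg`,
#' `traj_length_mm`, `total_rotation_deg`, `econ_translation`,
#' `econ_rotation`.
#'
#' @param metrics data.frame of per-trial metrics.
#' @param path file path.
#' @return `read_metrics` returns the data.frame; `write_metrics` its
#'   input, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("subject_id", "trial_index", metric_columns)
  missing <- setdiff(cols, names(metrics))
  if (length(missing))
    stop_scopeskill("config_invalid",
                    paste("metrics table lacks columns:",
                          paste(missing, collapse = ", ")))
  utils::write.csv(metrics[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(metrics)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "trial_index", metric_columns), names(m))
  if (length(missing))
    stop_scopeskill("schema_mismatch",
                    paste("metrics CSV lacks columns:",
                          paste(missing, collapse = ", ")))
  m
}
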