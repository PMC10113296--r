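# JSONL session logs, YAML run configuration, and the
# simulate -> score -> analyze -> report pipeline.

SCHEMA_VERSION <- 1L

#' Write a session log as JSON Lines
#'
#' One JSON object per line: a header (schema version, subject, seed,
#' config fingerprint), then per trial a `trial` object followed by its
#' `sample` and `event` objects. Numbers are written at full precision so
#' the write/read round trip is lossless.
#'
#' @param session a `session_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  emit <- function(x) writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null"), con)
  emit(list(type = "header", schema_version = SCHEMA_VERSION,
            subject_id = session$subject_id, seed = session$seed,
            config_fingerprint = session$config_fingerprint))
  for (tr in session$trials) {
    emit(list(type = "trial", trial_index = tr$trial_index,
              order = tr$protocol$order,
              time_limit = tr$protocol$time_limit,
              dt = tr$protocol$dt,
              overlay = unclass(tr$protocol$overlay),
              protocol_id = tr$protocol$id))
    s <- tr$samples
    # %.17g round-trips doubles exactly; vectorised for the sample stream
    writeLines(sprintf(
      paste0('{"type":"sample","trial_index":%d,"t":%.17g,',
             '"theta1":%.17g,"theta2":%.17g,"theta3":%.17g,',
             '"theta6":%.17g,"pedal":%s}'),
      tr$trial_index, s$t, s$theta1, s$theta2, s$theta3, s$theta6,
      ifelse(s$pedal != 0, "true", "false")), con)
    ev <- tr$events
    for (i in seq_len(nrow(ev)))
      emit(list(type = "event", trial_index = tr$trial_index,
                target_id = ev$target_id[i], t_press = ev$t_press[i],
                accuracy_at_press = ev$accuracy_at_press[i],
                roll_at_press = ev$roll_at_press[i],
                timed_out = ev$timed_out[i]))
  }
  invisible(path)
}

#' Read a JSONL session log
#'
#' @param path file written by [write_session()].
#' @return a `session_log`. Signals `scopeskill_malformed_line` (with the
#'   offending line number) on unparsable lines and
#'   `scopeskill_schema_mismatch` on an unsupported schema version.
#' @export
read_session <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0)
    stop_scopeskill("malformed_line", "empty session file", line = 1L)
  objs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    val <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(val) || is.null(val$type))
      stop_scopeskill("malformed_line",
                      sprintf("cannot parse line %d of %s", i, path), line = i)
    objs[[i]] <- val
  }
  hd <- objs[[1]]
  if (!identical(hd$type, "header"))
    stop_scopeskill("malformed_line", "first line must be the header", line = 1L)
  if (!identical(as.integer(hd$schema_version), SCHEMA_VERSION))
    stop_scopeskill("schema_mismatch",
                    sprintf("unsupported schema version %s (supported: %d)",
                            hd$schema_version, SCHEMA_VERSION),
                    found = hd$schema_version, supported = SCHEMA_VERSION)
  trials <- list()
  cur <- NULL
  flush_trial <- function(cur) {
    samples <- do.call(rbind, lapply(cur$samples, function(o)
      data.frame(t = o$t, theta1 = o$theta1, theta2 = o$theta2,
                 theta3 = o$theta3, theta6 = o$theta6,
                 pedal = as.numeric(o$pedal))))
    events <- do.call(rbind, lapply(cur$events, function(o)
      data.frame(target_id = o$target_id, t_press = o$t_press,
                 accuracy_at_press = o$accuracy_at_press,
                 roll_at_press = o$roll_at_press, timed_out = o$timed_out)))
    ov <- cur$meta$overlay
    structure(list(trial_index = as.integer(cur$meta$trial_index),
                   protocol = exercise_protocol(
                     cur$meta$order, time_limit = cur$meta$time_limit,
                     overlay = overlay_ellipse(ov$semi_major, ov$semi_minor,
                                               ov$orientation, ov$center),
                     dt = cur$meta$dt,
                     id = if (is.null(cur$meta$protocol_id)) NA_integer_
                          else cur$meta$protocol_id),
                   samples = samples, events = events),
              class = "trial_log")
  }
  for (i in seq_along(objs)[-1]) {
    o <- objs[[i]]
    if (o$type == "trial") {
      if (!is.null(cur)) trials[[length(trials) + 1]] <- flush_trial(cur)
      cur <- list(meta = o, samples = list(), events = list())
    } else if (o$type == "sample") {
      cur$samples[[length(cur$samples) + 1]] <- o
    } else if (o$type == "event") {
      cur$events[[length(cur$events) + 1]] <- o
    } else {
      stop_scopeskill("malformed_line",
                      sprintf("unknown record type '%s' at line %d", o$type, i),
                      line = i)
    }
  }
  if (!is.null(cur)) trials[[length(trials) + 1]] <- flush_trial(cur)
  structure(list(subject_id = hd$subject_id, seed = as.integer(hd$seed),
                 config_fingerprint = hd$config_fingerprint, trials = trials),
            class = "session_log")
}

#' Default run configuration
#'
#' The fully serialisable configuration of a study run: arm geometry,
#' camera, cavity/targets, protocol and cohort blocks plus the master
#' seed. Every pipeline stage receives its settings only through this
#' object.
#'
#' @param n_subjects cohort size.
#' @param n_trials trials per subject.
#' @param seed master seed.
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(n_subjects = 80, n_trials = 30, seed = 1) {
  structure(list(
    seed = seed,
    geometry = list(l1 = 150, l2 = 200, l3 = 200, tool_length = 350,
                    rcm_point = c(0, 0, 0), base_position = c(0, 0, -300),
                    optic_offset = 30),
    camera = list(fov = 70, image_size = c(640, 480), optic_offset = 30,
                  near_limit = 1),
    cavity = list(depth = 60, width = 40, ap = 25, ring_outer_radius = 6,
                  ring_inner_radius = 4, led_radius = 2, focus_distance = 30),
    protocol = list(time_limit = 30, dt = 0.01, n_orders = 5,
                    overlay = list(semi_major = 40, semi_minor = 28,
                                   orientation = 0)),
    cohort = list(n_subjects = n_subjects, n_trials = n_trials,
                  # a named list survives the YAML round trip as a map
                  proportions = list(novice = 0.4, intermediate = 0.4,
                                     expert = 0.2))
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_config` returns a validated `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (block in c("geometry", "camera", "cavity", "protocol", "cohort"))
    if (is.null(cfg[[block]]))
      stop_scopeskill("config_invalid",
                      sprintf("configuration is missing the '%s' block", block))
  if (is.null(cfg$seed)) cfg$seed <- 1
  structure(cfg, class = "run_config")
}

#' Configuration fingerprint
#'
#' MD5 digest of the canonical YAML serialisation; stored in session-log
#' headers so logs can be matched to the configuration that produced them.
#'
#' @param config a `run_config`.
#' @return hex digest string.
#' @export
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

# Scene objects from a config.
build_scene <- function(config) {
  g <- config$geometry
  geom <- arm_geometry(l1 = g$l1, l2 = g$l2, l3 = g$l3,
                       tool_length = g$tool_length,
                       rcm_point = unlist(g$rcm_point),
                       base_position = unlist(g$base_position),
                       optic_offset = g$optic_offset)
  cm <- config$camera
  cam <- camera_model(fov = cm$fov, image_size = unlist(cm$image_size),
                      optic_offset = cm$optic_offset,
                      near_limit = cm$near_limit)
  cv <- config$cavity
  cavity <- cavity_config(depth = cv$depth, width = cv$width, ap = cv$ap,
                          ring_outer_radius = cv$ring_outer_radius,
                          ring_inner_radius = cv$ring_inner_radius,
                          led_radius = cv$led_radius,
                          focus_distance = cv$focus_distance)
  targets <- make_target_layout(cavity, geom, cam)
  ovl <- config$protocol$overlay
  overlay <- overlay_ellipse(ovl$semi_major, ovl$semi_minor, ovl$orientation,
                             center = unlist(cm$image_size) / 2)
  list(geom = geom, cam = cam, cavity = cavity, targets = targets,
       overlay = overlay)
}

#' Simulate a cohort and score it
#'
#' Runs [simulate_session()] for every subject drawn by [sample_cohort()]
#' and reduces each session to its per-trial metrics on the fly (sessions
#' are large; they are written to `log_dir` as JSONL only when asked).
#'
#' @param config a `run_config` (see [default_config()]).
#' @param seed master seed overriding `config$seed`.
#' @param log_dir optional directory for per-subject JSONL session logs.
#' @param progress print one line per subject to stderr.
#' @return per-trial metrics data.frame for the whole cohort.
#' @export
simulate_cohort_metrics <- function(config = default_config(), seed = NULL,
                                    log_dir = NULL, progress = FALSE) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  scene <- build_scene(config)
  fp <- config_fingerprint(config)
  protocols <- session_protocols(seed = config$seed,
                                 n_trials = config$cohort$n_trials,
                                 n_orders = config$protocol$n_orders,
                                 time_limit = config$protocol$time_limit,
                                 overlay = scene$overlay,
                                 dt = config$protocol$dt)
  cohort <- sample_cohort(config$cohort$n_subjects,
                          default_cohort_priors(unlist(config$cohort$proportions)),
                          seed = config$seed)
  if (!is.null(log_dir) && !dir.exists(log_dir))
    dir.create(log_dir, recursive = TRUE)
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    if (progress)
      message(sprintf("[simulate] subject %d/%d", i, length(cohort)))
    sess <- simulate_session(cohort[[i]], protocols, scene$geom, scene$cam,
                             scene$targets, seed = config$seed * 1000L + i,
                             config_fingerprint = fp)
    if (!is.null(log_dir))
      write_session(sess, file.path(log_dir,
                                    paste0(cohort[[i]]$subject_id, ".jsonl")))
    out[[i]] <- compute_session_metrics(sess, scene$geom, scene$targets)
  }
  do.call(rbind, out)
}

#' Full analysis of a metrics table
#'
#' @param metrics per-trial metrics table.
#' @param alpha,target_power test settings (see [compare_subsets()]).
#' @return list with the three subset comparisons (`ini_vs_fin`,
#'   `ini_vs_mid`, `mid_vs_fin`), `correlation` and `curves` (one
#'   [learning_curve()] per metric).
#' @export
analyze_metrics <- function(metrics, alpha = 0.05, target_power = 0.8) {
  ini <- subset_spec("initial"); mid <- subset_spec("middle")
  fin <- subset_spec("final")
  curves <- lapply(metric_columns, function(mc) learning_curve(metrics, mc))
  names(curves) <- metric_columns
  list(ini_vs_fin = compare_subsets(metrics, ini, fin, alpha, target_power),
       ini_vs_mid = compare_subsets(metrics, ini, mid, alpha, target_power),
       mid_vs_fin = compare_subsets(metrics, mid, fin, alpha, target_power),
       correlation = correlation_matrix(metrics),
       curves = curves)
}

#' Plain-text study report
#'
#' @param analysis result of [analyze_metrics()].
#' @param path optional file to write to.
#' @return the report lines, invisibly.
#' @export
render_report <- function(analysis, path = NULL) {
  fmt_cmp <- function(cmp) {
    c(sprintf("== %s (n = %d subjects) ==", attr(cmp, "comparison"),
              attr(cmp, "n_subjects")),
      utils::capture.output(print(format(cmp, digits = 4), row.names = FALSE)))
  }
  lines <- c("Camera-navigation learning-curve report", "",
             fmt_cmp(analysis$ini_vs_fin), "",
             fmt_cmp(analysis$ini_vs_mid), "",
             fmt_cmp(analysis$mid_vs_fin), "",
             "== Pearson correlations (all trials) ==",
             utils::capture.output(print(analysis$correlation)), "",
             "== Learning-curve log fits ==",
             vapply(analysis$curves, function(lc)
               sprintf("%-22s a = %10.3f  b = %9.3f  R^2 = %.3f",
                       lc$metric, lc$a, lc$b, lc$r_squared), character(1)))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Run the whole pipeline: simulate, score, analyze, report
#'
#' @param config a `run_config`.
#' @param out_dir output directory for the CSV tables and report.
#' @param seed master seed overriding `config$seed`.
#' @param log_dir optional directory for JSONL session logs.
#' @param progress print progress to stderr.
#' @return list with `metrics` and the [analyze_metrics()] result,
#'   invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".",
                         seed = NULL, log_dir = NULL, progress = FALSE) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  metrics <- simulate_cohort_metrics(config, log_dir = log_dir,
                                     progress = progress)
  write_metrics(metrics, file.path(out_dir, "metrics.csv"))
  an <- analyze_metrics(metrics)
  utils::write.csv(an$ini_vs_fin, file.path(out_dir, "compare_initial_final.csv"),
                   row.names = FALSE)
  utils::write.csv(an$ini_vs_mid, file.path(out_dir, "compare_initial_middle.csv"),
                   row.names = FALSE)
  utils::write.csv(an$mid_vs_fin, file.path(out_dir, "compare_middle_final.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(an$correlation$r),
                   file.path(out_dir, "correlation.csv"))
  curves <- do.call(rbind, lapply(an$curves, function(lc)
    cbind(metric = lc$metric, lc$per_trial)))
  utils::write.csv(curves, file.path(out_dir, "learning_curves.csv"),
                   row.names = FALSE)
  render_report(an, file.path(out_dir, "report.txt"))
  invisible(list(metrics = metrics, analysis = an, config = config))
}
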