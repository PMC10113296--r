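# Shared fixtures: the default scene, built once per test run.

vnorm <- function(v) sqrt(sum(v^2))

default_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- arm_geometry()
      cam <- camera_model()
      targets <- make_target_layout(cavity_config(), geom, cam)
      cache <<- list(geom = geom, cam = cam, targets = targets,
                     overlay = overlay_ellipse())
    }
    cache
  }
})

# Random valid shaft parameters (polar, azimuth, depth, roll) inside the
# working envelope.
random_params <- function(n) {
  cbind(polar = runif(n, 0, 0.9),
        azimuth = runif(n, -pi, pi),
        depth = runif(n, 0, 45),
        roll = runif(n, -179, 179))
}

# Deterministic teleport agent: jumps straight to each target's ideal
# pose and presses immediately.
oracle_agent <- function(geom) {
  list(plan = function(current, target, trial_index, max_time) {
    p <- target$ideal_pose
    par <- matrix(c(acos(min(1, max(-1, p$shaft_dir[3]))),
                    atan2(p$shaft_dir[2], p$shaft_dir[1]),
                    p$insertion_depth, p$roll), 1, 4)
    list(par = par, press_idx = 1L)
  })
}

# Agent that holds the home pose and never presses.
statue_agent <- function(dt = 0.01, time_limit = 30) {
  n <- ceiling(time_limit / dt) + 5L
  list(plan = function(current, target, trial_index, max_time) {
    list(par = matrix(rep(current, each = n), n, 4), press_idx = NA_integer_)
  })
}
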