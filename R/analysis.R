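# Learning-curve statistical battery: trial-subset comparisons (paired
# t-test, post-hoc power, required sample size), the metric correlation
# matrix, and log-fit learning curves.

#' Trial subsets used in the learning-curve comparisons
#'
#' The study design compares the initial (trials 1-3), middle (14-16) and
#' final (28-30) stretches of the 30-trial session.
#'
#' @param name one of `"initial"`, `"middle"`, `"final"`.
#' @return a `subset_spec` list with `name` and `trial_indices`.
#' @export
subset_spec <- function(name = c("initial", "middle", "final")) {
  name <- match.arg(name)
  idx <- switch(name, initial = 1:3, middle = 14:16, final = 28:30)
  structure(list(name = name, trial_indices = idx), class = "subset_spec")
}

#' Per-subject means over a trial subset
#'
#' Reduces the per-trial metrics table to one value per subject and
#' metric: the mean over the subset's trials. This is the quantity that
#' feeds the paired tests (pairing is by subject).
#'
#' @param metrics per-trial metrics table (see [compute_trial_metrics()]).
#' @param subset a [subset_spec()].
#' @return data.frame with `subject_id` and one column per metric.
#' @export
subject_subset_means <- function(metrics, subset) {
  sub <- metrics[metrics$trial_index %in% subset$trial_indices, , drop = FALSE]
  counts <- table(sub$subject_id)
  want <- length(subset$trial_indices)
  bad <- names(counts)[counts != want]
  missing_subj <- setdiff(unique(metrics$subject_id), names(counts))
  if (length(bad) || length(missing_subj))
    stop_scopeskill("missing_trials",
                    paste("subjects lacking subset trials:",
                          paste(c(missing_subj, bad), collapse = ", ")),
                    subjects = c(missing_subj, bad))
  agg <- stats::aggregate(sub[, metric_columns],
                          by = list(subject_id = sub$subject_id), FUN = mean)
  agg[order(agg$subject_id), , drop = FALSE]
}

#' Gain ratio and difference between two subset means
#'
#' @param mean_a,mean_b subset means (e.g. initial and final).
#' @return list with `ratio = mean_a / mean_b` and
#'   `diff = mean_a - mean_b`.
#' @export
effect_summary <- function(mean_a, mean_b) {
  if (any(mean_b == 0))
    stop_scopeskill("div_zero", "cannot form a gain ratio with a zero mean")
  list(ratio = mean_a / mean_b, diff = mean_a - mean_b)
}

#' Post-hoc power of the paired t-test
#'
#' Probability that a two-sided paired t-test at level `alpha` on `n`
#' pairs detects a standardized paired effect `effect` (mean difference
#' over the SD of differences), computed from the noncentral-t
#' distribution of the test statistic.
#'
#' @param n number of pairs (>= 2).
#' @param effect standardized effect size d = mean(diff)/sd(diff).
#' @param alpha significance level.
#' @return power in `[0, 1]`.
#' @export
paired_t_power <- function(n, effect, alpha = 0.05) {
  if (n < 2) return(NA_real_)
  df <- n - 1
  ncp <- abs(effect) * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp = ncp) + stats::pt(-tcrit, df, ncp = ncp)
}

#' Sample size for the paired t-test
#'
#' Smallest number of pairs achieving `target_power` for a standardized
#' paired effect `effect` at level `alpha` (integer search on
#' [paired_t_power()]).
#'
#' @param effect standardized effect size.
#' @param target_power desired power.
#' @param alpha significance level.
#' @param n_max search cap.
#' @return integer sample size, or `NA` if the effect is zero or the cap
#'   is exceeded.
#' @export
paired_t_sample_size <- function(effect, target_power = 0.8, alpha = 0.05,
                                 n_max = 1e7) {
  if (!is.finite(effect) || effect == 0) return(NA_integer_)
  lo <- 2; hi <- 2
  while (paired_t_power(hi, effect, alpha) < target_power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) return(NA_integer_)
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (paired_t_power(mid, effect, alpha) >= target_power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Compare two trial subsets metric by metric
#'
#' For each evaluation metric: means and SDs of the per-subject subset
#' means, gain ratio and difference, two-sided paired t-test on the
#' per-subject differences with its 95% CI, post-hoc power at the
#' observed standardized effect, the sample size required for the target
#' power, and the rejection flag `h` at level `alpha`.
#'
#' @param metrics per-trial metrics table.
#' @param subset_a,subset_b two [subset_spec()]s over the same subjects.
#' @param alpha significance level.
#' @param target_power power used for the sample-size column.
#' @param p_adjust `"none"` (default: raw p per row, as reported) or
#'   `"holm"`.
#' @return data.frame with one row per metric and columns `metric`,
#'   `mean_ini`, `std_ini`, `mean_end`, `std_end`, `ratio`, `diff`,
#'   `t_stat`, `p_value`, `ci_low`, `ci_high`, `power`, `sample_size`, `h`.
#' @export
compare_subsets <- function(metrics, subset_a = subset_spec("initial"),
                            subset_b = subset_spec("final"),
                            alpha = 0.05, target_power = 0.8,
                            p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  ma <- subject_subset_means(metrics, subset_a)
  mb <- subject_subset_means(metrics, subset_b)
  if (!identical(ma$subject_id, mb$subject_id))
    stop_scopeskill("missing_trials", "subject sets differ between subsets")
  n <- nrow(ma)
  if (n < 3)
    stop_scopeskill("n_too_small", "need at least 3 subjects for the paired test")
  rows <- lapply(metric_columns, function(mc) {
    a <- ma[[mc]]; b <- mb[[mc]]
    d <- a - b
    if (stats::sd(d) > 0) {
      tt <- stats::t.test(a, b, paired = TRUE, conf.level = 1 - alpha)
    } else {
      # degenerate paired data: identical differences for every subject
      tt <- list(statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
                 p.value = if (mean(d) == 0) 1 else 0,
                 conf.int = c(mean(d), mean(d)))
    }
    es <- effect_summary(mean(a), mean(b))
    eff <- if (stats::sd(d) > 0) mean(d) / stats::sd(d) else 0
    data.frame(metric = mc,
               mean_ini = mean(a), std_ini = stats::sd(a),
               mean_end = mean(b), std_end = stats::sd(b),
               ratio = es$ratio, diff = es$diff,
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               power = paired_t_power(n, eff, alpha),
               sample_size = paired_t_sample_size(eff, target_power, alpha))
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$h <- as.integer(out$p_value < alpha)
  attr(out, "comparison") <- paste(subset_a$name, "vs", subset_b$name)
  attr(out, "n_subjects") <- n
  out
}

#' Pearson correlation matrix of the evaluation metrics
#'
#' Correlates the five evaluation indices (ET execution time, AC
#' accuracy, EO orientation error, TT trajectory translation, TR
#' trajectory rotation) over all (subject, trial) rows.
#'
#' @param metrics per-trial metrics table (>= 3 rows).
#' @return list of class `correlation_report` with `r` (5x5 matrix),
#'   `p` (two-sided p-values, NA on the diagonal) and `n`.
#' @export
correlation_matrix <- function(metrics) {
  cols <- c(ET = "exec_time_s", AC = "accuracy_pct",
            EO = "orientation_error_deg", TT = "traj_length_mm",
            TR = "total_rotation_deg")
  x <- as.matrix(metrics[, cols])
  colnames(x) <- names(cols)
  if (nrow(x) < 3)
    stop_scopeskill("n_too_small", "need at least 3 rows for correlations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_scopeskill("zero_variance",
                    paste("constant metric(s):",
                          paste(names(cols)[sds == 0], collapse = ", ")))
  r <- stats::cor(x)
  p <- matrix(NA_real_, 5, 5, dimnames = dimnames(r))
  for (i in 1:4) for (j in (i + 1):5) {
    pv <- stats::cor.test(x[, i], x[, j])$p.value
    p[i, j] <- p[j, i] <- pv
  }
  structure(list(r = r, p = p, n = nrow(x)), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations over %d trial rows\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' Learning-curve summary for one metric
#'
#' Per-trial descriptive statistics across subjects (mean, median,
#' quartiles, IQR) and a least-squares fit of the per-trial means to
#' `a + b * log(trial)`; the sign of `b` is the headline trend.
#'
#' @param metrics per-trial metrics table.
#' @param metric one of the seven metric column names.
#' @return list of class `learning_curve` with `metric`, `per_trial`
#'   (data.frame trial, mean, median, q1, q3, iqr), `a`, `b`,
#'   `r_squared`.
#' @export
learning_curve <- function(metrics, metric = "exec_time_s") {
  if (!metric %in% names(metrics))
    stop_scopeskill("config_invalid", paste("no metric column", metric))
  trials <- sort(unique(metrics$trial_index))
  if (length(trials) < 2)
    stop_scopeskill("n_too_small", "need >= 2 distinct trial indices")
  per_trial <- do.call(rbind, lapply(trials, function(ti) {
    v <- metrics[[metric]][metrics$trial_index == ti]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(trial = ti, mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
  }))
  fit <- stats::lm(mean ~ log(trial), data = per_trial)
  structure(list(metric = metric, per_trial = per_trial,
                 a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 # suppress the "essentially perfect fit" warning on
                 # degenerate (constant or exactly logarithmic) series
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve for %s: mean ~ %.3f %+.3f * log(trial), R^2 = %.3f\n",
              x$metric, x$a, x$b, x$r_squared))
  invisible(x)
}

#' Base-graphics plot of a learning curve
#'
#' @param x a `learning_curve`.
#' @param ... passed to [plot()].
#' @export
plot.learning_curve <- function(x, ...) {
  pt <- x$per_trial
  plot(pt$trial, pt$mean, type = "b", pch = 16,
       xlab = "trial", ylab = x$metric,
       ylim = range(pt$q1, pt$q3), ...)
  graphics::arrows(pt$trial, pt$q1, pt$trial, pt$q3,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  graphics::curve(x$a + x$b * log(t), xname = "t", add = TRUE,
                  col = "red3", lwd = 2)
  invisible(x)
}
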