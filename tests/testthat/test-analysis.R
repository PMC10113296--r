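# Synthetic metrics tables for exercising the statistics without running
# the simulator.
make_metrics_table <- function(n_subj, n_trials, gen) {
  rows <- expand.grid(subject_id = sprintf("S%03d", seq_len(n_subj)),
                      trial_index = seq_len(n_trials),
                      stringsAsFactors = FALSE)
  for (mc in scopeskill:::metric_columns) rows[[mc]] <- gen(nrow(rows), mc)
  rows
}

test_that("per-subject subset means reduce exactly as a group-by mean", {
  withr::with_seed(5, {
    m <- make_metrics_table(12, 30, function(n, mc) rnorm(n, 50, 10))
    sm <- subject_subset_means(m, subset_spec("middle"))
    expect_equal(nrow(sm), 12)
    # brute force for one subject and metric
    s <- "S007"
    manual <- mean(m$exec_time_s[m$subject_id == s & m$trial_index %in% 14:16])
    expect_equal(sm$exec_time_s[sm$subject_id == s], manual)
    # constant metric and arithmetic-progression checks
    m2 <- make_metrics_table(3, 30, function(n, mc) rep(5, n))
    expect_equal(subject_subset_means(m2, subset_spec("initial"))$accuracy_pct,
                 rep(5, 3))
    m3 <- make_metrics_table(1, 30, function(n, mc) 1)
    m3$exec_time_s <- m3$trial_index
    expect_equal(subject_subset_means(m3, subset_spec("middle"))$exec_time_s, 15)
    # a missing trial is reported with the offending subject
    m4 <- m[!(m$subject_id == "S002" & m$trial_index == 15), ]
    expect_error(subject_subset_means(m4, subset_spec("middle")),
                 class = "scopeskill_missing_trials")
  })
})

test_that("gain ratios and differences follow the subset means", {
  es <- effect_summary(157.984, 81.648)
  expect_equal(es$ratio, 1.935, tolerance = 5e-4)
  expect_equal(es$diff, 76.336, tolerance = 1e-9)
  expect_equal(effect_summary(78.553, 87.965)$ratio, 0.893, tolerance = 5e-4)
  expect_equal(effect_summary(3, 3), list(ratio = 1, diff = 0))
  expect_error(effect_summary(1, 0), class = "scopeskill_div_zero")
})

test_that("paired comparison matches hand computation and handles degenerate data", {
  # all differences exactly zero
  m0 <- make_metrics_table(6, 30, function(n, mc) rep(7, n))
  cmp0 <- compare_subsets(m0)
  expect_equal(cmp0$t_stat, rep(0, 7))
  expect_equal(cmp0$p_value, rep(1, 7))
  expect_equal(cmp0$h, rep(0L, 7))
  expect_true(all(cmp0$ci_low <= cmp0$diff & cmp0$diff <= cmp0$ci_high))

  # hand-computed t statistic on a 5-subject table
  withr::with_seed(8, {
    m <- make_metrics_table(5, 30, function(n, mc) rnorm(n, 20, 4))
    cmp <- compare_subsets(m)
    a <- subject_subset_means(m, subset_spec("initial"))$exec_time_s
    b <- subject_subset_means(m, subset_spec("final"))$exec_time_s
    d <- a - b
    t_hand <- mean(d) / (sd(d) / sqrt(5))
    row <- cmp[cmp$metric == "exec_time_s", ]
    expect_equal(row$t_stat, t_hand, tolerance = 1e-12)
    expect_equal(row$mean_ini, mean(a))
    expect_equal(row$ratio, mean(a) / mean(b))
  })

  # a known planted effect at n = 80: paired differences ~ N(3, ~0.8)
  withr::with_seed(9, {
    m <- make_metrics_table(80, 30, function(n, mc) rnorm(n, 50, 1))
    shift <- m$trial_index %in% 1:3
    for (mc in scopeskill:::metric_columns)
      m[[mc]] <- m[[mc]] + ifelse(shift, 3, 0)
    cmp <- compare_subsets(m)
    expect_true(all(cmp$p_value < 0.001))
    expect_true(all(cmp$h == 1L))
    expect_true(all(cmp$power > 0.99))
    expect_true(all(cmp$diff > 2 & cmp$diff < 4))
  })

  # order invariance under subject permutation
  withr::with_seed(10, {
    m <- make_metrics_table(10, 30, function(n, mc) rnorm(n, 30, 6))
    cmp1 <- compare_subsets(m)
    cmp2 <- compare_subsets(m[sample.int(nrow(m)), ])
    expect_equal(cmp1, cmp2, ignore_attr = TRUE)
  })

  expect_error(compare_subsets(make_metrics_table(2, 30, function(n, mc) rnorm(n))),
               class = "scopeskill_n_too_small")
})

test_that("noncentral-t power agrees with power.t.test and is monotone", {
  # power.t.test counts only the correct-sign rejection region, so the
  # full two-sided power exceeds it by at most alpha/2
  for (n in c(5, 20, 80)) for (eff in c(0.2, 0.5, 1)) {
    ref <- stats::power.t.test(n = n, delta = eff, sd = 1,
                               type = "paired")$power
    got <- paired_t_power(n, eff)
    expect_gte(got, ref - 1e-9)
    expect_lt(got - ref, 0.025)
  }
  # at a solid effect the wrong-sign tail is negligible: near-exact match
  expect_equal(paired_t_power(30, 1),
               stats::power.t.test(n = 30, delta = 1, sd = 1,
                                   type = "paired")$power, tolerance = 1e-6)
  # monotone in n and in effect size
  grid_n <- c(4, 8, 16, 32, 64, 128)
  pw_n <- vapply(grid_n, paired_t_power, numeric(1), effect = 0.4)
  expect_true(all(diff(pw_n) > 0))
  grid_e <- seq(0.1, 1.5, by = 0.2)
  pw_e <- vapply(grid_e, function(e) paired_t_power(30, e), numeric(1))
  expect_true(all(diff(pw_e) > 0))

  # sample size: smallest n reaching the target power
  for (eff in c(0.3, 0.6, 1)) {
    n_req <- paired_t_sample_size(eff)
    expect_gte(paired_t_power(n_req, eff), 0.8)
    expect_lt(paired_t_power(n_req - 1, eff), 0.8)
    n_ref <- ceiling(stats::power.t.test(delta = eff, sd = 1, power = 0.8,
                                         type = "paired")$n)
    expect_lte(abs(n_req - n_ref), 1)
  }
  expect_true(is.na(paired_t_sample_size(0)))
})

test_that("correlation report is symmetric with exact trivial cases", {
  withr::with_seed(12, {
    m <- make_metrics_table(10, 30, function(n, mc) rnorm(n))
    m$traj_length_mm <- m$exec_time_s          # duplicated metric: r = 1
    m$total_rotation_deg <- -m$accuracy_pct    # anti-correlated: r = -1
    rep_ <- correlation_matrix(m)
    expect_equal(rep_$r["ET", "TT"], 1)
    expect_equal(rep_$r["AC", "TR"], -1)
    expect_equal(rep_$r, t(rep_$r))
    expect_equal(diag(rep_$r), rep(1, 5), ignore_attr = TRUE)
    expect_true(all(abs(rep_$r) <= 1))
    # independent columns at n = 2400: near-zero correlations
    m2 <- make_metrics_table(80, 30, function(n, mc) rnorm(n))
    r2 <- correlation_matrix(m2)$r
    expect_lt(max(abs(r2[upper.tri(r2)])), 0.07)
    # constant metric flagged
    m3 <- m2; m3$accuracy_pct <- 1
    expect_error(correlation_matrix(m3), class = "scopeskill_zero_variance")
  })
})

test_that("learning-curve fits recover exact logarithmic and constant series", {
  m <- make_metrics_table(4, 30, function(n, mc) 0)
  for (mc in scopeskill:::metric_columns)
    m[[mc]] <- 10 - 2 * log(m$trial_index)
  lc <- learning_curve(m, "exec_time_s")
  expect_equal(lc$a, 10, tolerance = 1e-9)
  expect_equal(lc$b, -2, tolerance = 1e-9)
  expect_equal(lc$r_squared, 1, tolerance = 1e-9)
  expect_true(all(lc$per_trial$q1 <= lc$per_trial$median &
                    lc$per_trial$median <= lc$per_trial$q3))
  m2 <- make_metrics_table(4, 30, function(n, mc) 3)
  expect_equal(learning_curve(m2, "accuracy_pct")$b, 0, tolerance = 1e-12)
  expect_error(learning_curve(m, "nope"), class = "scopeskill_config_invalid")
  expect_error(learning_curve(m[m$trial_index == 1, ], "exec_time_s"),
               class = "scopeskill_n_too_small")
})

test_that("the paired pipeline keeps its nominal type-I error under the null", {
  # 400 null cohorts of 20 subjects: exec_time rejections should occur at
  # about the alpha = 0.05 rate (checked generously here; the full-rate
  # check over 1000 cohorts runs with the acceptance suite)
  withr::with_seed(14, {
    rej <- 0; total <- 0
    for (b in 1:400) {
      vals <- matrix(rnorm(20 * 6, 100, 10), 20, 6)
      a <- rowMeans(vals[, 1:3]); bb <- rowMeans(vals[, 4:6])
      p <- stats::t.test(a, bb, paired = TRUE)$p.value
      rej <- rej + (p < 0.05); total <- total + 1
    }
    expect_gt(rej / total, 0.02)
    expect_lt(rej / total, 0.09)
  })
})
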