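test_that("seconds per tablet divides pause-free time by correct selections", {
  r <- make_rep(start_s = 0, spt = 1.75, n = 12)
  expect_equal(seconds_per_tablet(r), 1.75)

  r2 <- make_rep("exercise", start_s = 0, spt = 2.0, n = 12, pause_s = 6)
  expect_equal(r2$end_s - r2$start_s, 30)
  expect_equal(seconds_per_tablet(r2), 2.0)
  expect_equal(seconds_per_tablet(r2, pause_exclusion = FALSE), 2.5)

  r3 <- make_rep("stroop", start_s = 0, spt = 2.06, n = 8)
  expect_equal(seconds_per_tablet(r3), 2.06)

  none <- r; none$taps$correct <- FALSE
  expect_true(is.na(seconds_per_tablet(none)))
})

test_that("errors count incorrect selections without touching the denominator", {
  r <- make_rep(spt = 2, n = 12, n_errors = 3)
  expect_identical(rep_errors(r), 3L)
  expect_equal(seconds_per_tablet(r), 2)
})

test_that("best_of takes the per-metric minimum, skipping undefined values", {
  expect_equal(best_of(c(1.8, 1.7)), 1.7)
  expect_equal(best_of(c(0, 2)), 0)
  expect_equal(best_of(c(NA, 142)), 142)
  expect_true(is.na(best_of(c(NA_real_, NA_real_))))
})

test_that("cost_score reproduces the worked percent-change examples", {
  expect_equal(as.numeric(cost_score(1.75, 1.94)), 10.86)
  expect_equal(as.numeric(cost_score(1.65, 1.74)), 5.45)
  expect_equal(as.numeric(cost_score(1.68, 2.06)), 22.62)
  expect_equal(as.numeric(cost_score(1.66, 1.81)), 9.04)
  expect_equal(as.numeric(cost_score(1.18, 1.44)), 22.03)
  expect_equal(as.numeric(cost_score(0.83, 0.93)), 12.05)
  expect_equal(as.numeric(cost_score(1.3, 1.3)), 0)

  z <- cost_score(0, 4)
  expect_true(is.na(z))
  expect_identical(attr(z, "reason"), "zero_baseline")
})

test_that("cost_score satisfies the scaled antisymmetry identity", {
  # (c-b)/b = -(b-c)/c * (c/b); checked against a brute-force re-derivation
  set.seed(17)
  for (i in 1:200) {
    b <- runif(1, 0.2, 5); c_ <- runif(1, 0.2, 5)
    lhs <- (c_ - b) / b * 100
    rhs <- -((b - c_) / c_ * 100) * (c_ / b)
    expect_equal(lhs, rhs)
    expect_equal(as.numeric(cost_score(b, c_)), round(lhs + 1e-9, 2),
                 tolerance = 0.011)
  }
})

test_that("the six cost scores wire the right baselines to the right challenges", {
  s <- make_session(
    spts = list(motor_pre = c(0.83, 0.85), number_letter = c(1.75, 1.80),
                exercise = c(1.94, 1.96), go_no_go = c(1.9, 1.86),
                stroop = c(2.1, 2.06), motor_post = c(0.93, 0.95)))
  costs <- compute_cost_scores(s)
  val <- function(cost) costs$value[costs$cost == cost & costs$metric == "time"]
  expect_equal(val("exertion"), 10.86)       # 1.75 vs 1.94 (best of two each)
  expect_equal(val("cognitive_high"), 17.71) # 1.75 vs 2.06
  expect_equal(val("fatigue"), 12.05)        # 0.83 vs 0.93
  expect_equal(val("cognitive_moderate"),
               as.numeric(cost_score(1.75, 1.86)))
})

test_that("auditory and scramble costs average the per-level standard bests", {
  s <- make_session(
    spts = list(motor_pre = c(0.9, 0.9),
                number_letter = c(1.00, 1.10), exercise = c(1.20, 1.30),
                go_no_go = c(1.20, 1.40), stroop = c(1.32, 1.50),
                motor_post = c(0.9, 0.9)),
    aud_spt = list(number_letter = 1.2, exercise = 1.3, go_no_go = 1.4, stroop = 1.5),
    scr_spt = list(number_letter = 1.3, exercise = 1.4, go_no_go = 1.5, stroop = 1.56))
  costs <- compute_cost_scores(s)
  base <- mean(c(1.00, 1.20, 1.20, 1.32))   # best-of-two per core level
  expect_equal(costs$value[costs$cost == "auditory" & costs$metric == "time"],
               as.numeric(cost_score(base, mean(c(1.2, 1.3, 1.4, 1.5)))))
  expect_equal(costs$value[costs$cost == "scramble" & costs$metric == "time"],
               as.numeric(cost_score(base, mean(c(1.3, 1.4, 1.5, 1.56)))))
})

test_that("identical metrics yield all-zero defined costs", {
  s <- make_session(
    spts = list(motor_pre = c(1.5, 1.5), number_letter = c(1.5, 1.5),
                exercise = c(1.5, 1.5), go_no_go = c(1.5, 1.5),
                stroop = c(1.5, 1.5), motor_post = c(1.5, 1.5)),
    aud_spt = list(number_letter = 1.5, exercise = 1.5, go_no_go = 1.5, stroop = 1.5),
    scr_spt = list(number_letter = 1.5, exercise = 1.5, go_no_go = 1.5, stroop = 1.5))
  costs <- compute_cost_scores(s)
  tc <- costs[costs$metric == "time", ]
  expect_true(all(tc$value == 0))
})

test_that("undefined costs carry machine-readable reasons", {
  s <- make_session()  # no HR stream, no errors, no auditory/scramble reps
  costs <- compute_cost_scores(s)
  expect_true(all(costs$reason[costs$metric == "errors" &
                                 costs$cost == "exertion"] == "zero_baseline"))
  expect_true(all(costs$reason[costs$metric == "hr"] == "missing_hr"))
  expect_true(all(costs$reason[costs$cost == "auditory" &
                                 costs$metric == "time"] == "missing_level"))
  expect_true(is.na(costs$reason[costs$cost == "fatigue" & costs$metric == "time"]))
})

test_that("cohort summaries match hand-checked descriptive statistics", {
  peaks <- c(184, 155, 196, 156, 155, 152, 184, 132, 158, 163)
  s <- summarize_cohort(peaks)
  expect_equal(s$n, 10L)
  expect_equal(round(s$mean, 1), 163.5)
  expect_equal(round(s$sd, 1), 19.0)
  expect_equal(round(unname(s$ci95), 1), c(151.7, 175.3))

  durs <- pilot_durations()
  expect_equal(summarize_cohort(durs$configuration_min)$median, 6.01)

  one <- summarize_cohort(5)
  expect_equal(one$mean, 5); expect_equal(one$median, 5)
  expect_true(is.na(one$sd)); expect_true(all(is.na(one$ci95)))

  expect_error(summarize_cohort(numeric()), class = "r2play_computation_error")
})

test_that("quartile conventions are selectable", {
  x <- c(1, 2, 3, 4, 10)
  lin <- summarize_cohort(x, quartile = "linear")
  tuk <- summarize_cohort(x, quartile = "tukey")
  expect_equal(lin$iqr, unname(diff(quantile(x, c(0.25, 0.75), type = 7))))
  expect_equal(tuk$iqr, diff(fivenum(x)[c(2, 4)]))
})

test_that("average repetition heart rate is time-weighted", {
  hr <- data.frame(t_s = c(0, 10, 20), bpm = c(100, 100, 160))
  r <- list(start_s = 0, end_s = 20, pause_intervals = NULL,
            taps = data.frame(t_s = 1:12, tablet_id = "T1",
                              displayed_character = "1", correct = TRUE))
  # trapezoid: 100 over [0,10], ramp 100->160 over [10,20] => (100*10+130*10)/20
  expect_equal(rep_avg_hr(r, hr), 115)
  expect_equal(rep_avg_hr(r, hr, method = "mean"), 120)
  expect_true(is.na(rep_avg_hr(r, data.frame(t_s = 100, bpm = 100))))
})
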