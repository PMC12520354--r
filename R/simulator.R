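#' @title Session simulation
#' @description
#' Generates synthetic session records over a protocol so the scoring
#' pipeline can be exercised end-to-end and injected demand-loading effects
#' recovered. Per-tap intervals are lognormal (positive, right-skewed,
#' CV-parameterized) with means proportional to the segment distance, scaled
#' so a repetition's expected seconds-per-tablet equals the baseline speed
#' times the product of the applicable level/condition time factors. Heart
#' rate follows a first-order exponential relaxation (time constant `tau_s`)
#' toward level-dependent steady-state targets -- rising during repetitions,
#' decaying toward rest during breaks -- sampled at 1 Hz. Taps are marked
#' incorrect via a per-tap error model with odds multipliers per challenge.
#' @name simulator
NULL

#' Participant profile for simulation
#'
#' @param age_years age in years.
#' @param wheelchair wheelchair-user flag (metadata only).
#' @param base_spt baseline seconds per tablet on the number-letter level.
#' @param hr_rest_bpm resting heart rate.
#' @param hr_gain scaling of the rest-to-target heart-rate response
#'   (1 = reaches the nominal steady-state target).
#' @param tau_s heart-rate time constant in seconds.
#' @param error_rate_base per-tap probability of an incorrect selection under
#'   no added challenge.
#' @param rpe_slope maps percent-of-max heart rate to the 0-10 OMNI RPE as
#'   `clamp(round(rpe_slope * pct_max / 10), 0, 10)`.
#' @return list of class `r2p_profile`.
#' @export
participant_profile <- function(age_years = 14, wheelchair = FALSE,
                                base_spt = 1.6, hr_rest_bpm = 70,
                                hr_gain = 1.0, tau_s = 30,
                                error_rate_base = 0.02, rpe_slope = 0.55) {
  stopifnot(base_spt > 0, tau_s > 0,
            error_rate_base >= 0, error_rate_base <= 1)
  structure(list(age_years = age_years, wheelchair = wheelchair,
                 base_spt = base_spt, hr_rest_bpm = hr_rest_bpm,
                 hr_gain = hr_gain, tau_s = tau_s,
                 error_rate_base = error_rate_base, rpe_slope = rpe_slope),
            class = "r2p_profile")
}

#' Demand-loading effect configuration
#'
#' Multiplicative completion-time factors and error-odds multipliers per
#' challenge, heart-rate intensity offsets per level, and the
#' coefficient of variation of the lognormal per-tap timing noise. A time
#' factor f makes the affected repetitions f times slower, so the matching
#' time cost score recovers `100 * (f - 1)` in expectation. The default time
#' factors encode the demand loading observed in the instrument's
#' proof-of-concept cohort (Stroop and scramble slowest, auditory
#' intermediate, exercise/go-no-go/post-motor slightly faster than baseline);
#' `motor_f` sets the pace of the short motor task relative to the
#' number-letter baseline and cancels out of the fatigue cost.
#'
#' @param exercise_f,gng_f,stroop_f,auditory_f,scramble_f,fatigue_f
#'   multiplicative completion-time factors (> 0).
#' @param motor_f time factor of the motor task relative to baseline.
#' @param error_odds named numeric of per-challenge error-odds multipliers
#'   (names among `exercise`, `go_no_go`, `stroop`, `auditory`, `scramble`,
#'   `fatigue`).
#' @param hr_offsets named numeric of additive steady-state intensity offsets
#'   per level (fractions of predicted max).
#' @param noise_cv lognormal coefficient of variation of per-tap intervals
#'   (>= 0; 0 gives deterministic timing).
#' @return list of class `r2p_effects`.
#' @export
effect_config <- function(exercise_f = 0.93, gng_f = 0.97, stroop_f = 1.20,
                          auditory_f = 1.09, scramble_f = 1.21,
                          fatigue_f = 0.88, motor_f = 0.55,
                          error_odds = c(exercise = 1, go_no_go = 2, stroop = 3,
                                         auditory = 1.5, scramble = 2, fatigue = 1),
                          hr_offsets = NULL, noise_cv = 0.05) {
  fac <- c(exercise_f, gng_f, stroop_f, auditory_f, scramble_f, fatigue_f, motor_f)
  stopifnot(all(fac > 0), noise_cv >= 0)
  structure(list(exercise_f = exercise_f, gng_f = gng_f, stroop_f = stroop_f,
                 auditory_f = auditory_f, scramble_f = scramble_f,
                 fatigue_f = fatigue_f, motor_f = motor_f,
                 error_odds = error_odds,
                 hr_offsets = hr_offsets %||% stats::setNames(numeric(6), LEVEL_KINDS),
                 noise_cv = noise_cv),
            class = "r2p_effects")
}

# steady-state heart-rate intensity (fraction of predicted max) per level
LEVEL_INTENSITY <- c(motor_pre = 0.75, number_letter = 0.78, exercise = 0.92,
                     go_no_go = 0.80, stroop = 0.84, motor_post = 0.78)
COND_INTENSITY <- c(standard = 0, auditory = 0.01, scramble = 0.03)

level_time_factor <- function(effects, level_kind) {
  switch(level_kind,
         motor_pre = effects$motor_f,
         number_letter = 1,
         exercise = effects$exercise_f,
         go_no_go = effects$gng_f,
         stroop = effects$stroop_f,
         motor_post = effects$motor_f * effects$fatigue_f)
}

level_error_mult <- function(effects, level_kind) {
  eo <- effects$error_odds
  switch(level_kind,
         exercise = eo[["exercise"]], go_no_go = eo[["go_no_go"]],
         stroop = eo[["stroop"]], motor_post = eo[["fatigue"]], 1)
}

cond_time_factor <- function(effects, condition) {
  switch(condition, auditory = effects$auditory_f,
         scramble = effects$scramble_f, 1)
}

cond_error_mult <- function(effects, condition) {
  eo <- effects$error_odds
  switch(condition, auditory = eo[["auditory"]], scramble = eo[["scramble"]], 1)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

odds_scale <- function(p, mult) {
  if (p == 0) return(0)
  o <- p / (1 - p) * mult
  o / (1 + o)
}

# first-order relaxation toward piecewise-constant targets, sampled at 1 Hz
simulate_hr_trace <- function(segments, t_end, rest, hrmax, tau,
                              noise_sd = 1.5) {
  ts <- seq(0, ceiling(t_end))
  targets <- rep(rest, length(ts))
  for (s in segments) {
    idx <- ts >= s$t0 & ts < s$t1
    targets[idx] <- s$target
  }
  bpm <- numeric(length(ts))
  h <- rest
  for (i in seq_along(ts)) {
    h <- targets[i] + (h - targets[i]) * exp(-1 / tau)
    bpm[i] <- h
  }
  bpm <- bpm + stats::rnorm(length(bpm), 0, noise_sd)
  data.frame(t_s = ts, bpm = round(pmin(hrmax, pmax(rest, bpm)), 1))
}

#' Simulate one assessment session
#'
#' Walks the protocol in order -- configuration phase, per-level orientation,
#' repetitions with inter-repetition breaks, post-level check-ins -- emitting
#' tap events, exercise pauses at the exercise trigger, a 1 Hz heart-rate
#' stream, and check-in records. With `noise_cv = 0` in `effects`, every
#' repetition's seconds-per-tablet equals `base_spt` times the applicable
#' time factors exactly. Deterministic given `seed`.
#'
#' @param protocol an `r2p_protocol`.
#' @param profile an [participant_profile()].
#' @param effects an [effect_config()].
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param participant_id identifier stored in the record.
#' @param timing list of phase durations in seconds: `configuration` (setup
#'   and baseline measures), `orientation` (per-level instructions, video
#'   demonstration, practice), `rep_break` (rest between repetitions),
#'   `checkin` (post-level RPE/symptom check-in), `exercise_pause` (three
#'   exercise repetitions at the beep). Partial lists are merged with the
#'   defaults.
#' @return an `r2p_session`.
#' @export
simulate_session <- function(protocol, profile = participant_profile(),
                             effects = effect_config(), seed = NULL,
                             participant_id = "sim",
                             timing = list()) {
  stopifnot(inherits(protocol, "r2p_protocol"))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  timing <- utils::modifyList(list(configuration = 360, orientation = 75,
                                   rep_break = 40, checkin = 45,
                                   exercise_pause = 15), timing)
  hrmax <- tanaka_hrmax(profile$age_years)
  rest <- profile$hr_rest_bpm
  cv <- effects$noise_cv
  offset_for <- function(lk) {
    off <- effects$hr_offsets
    if (!is.null(names(off)) && lk %in% names(off)) off[[lk]] else 0
  }
  steady <- function(level_kind, condition, spike = 0) {
    inten <- LEVEL_INTENSITY[[level_kind]] + COND_INTENSITY[[condition]] +
      offset_for(level_kind) + spike
    min(hrmax, max(rest, rest + profile$hr_gain * (inten * hrmax - rest)))
  }

  t <- rlnorm_mean_cv(1, timing$configuration, cv)
  config_interval <- c(0, t)
  hr_segments <- list()
  levels_out <- list()
  checkins <- list()

  for (lv in protocol$levels) {
    t <- t + timing$orientation
    level_rep_spans <- list()
    reps_out <- list()
    for (plan in lv$reps) {
      items <- plan$items[!plan$items$is_distractor, , drop = FALSE]
      n <- nrow(items)
      path <- c(".start", items$tablet_id)
      seg_d <- protocol$layout$dist[cbind(path[-length(path)], path[-1])]
      spt_target <- profile$base_spt *
        level_time_factor(effects, plan$level_kind) *
        cond_time_factor(effects, plan$condition)
      # distance-proportional interval means that sum exactly to n * spt
      means <- spt_target * n * seg_d / sum(seg_d)
      intervals <- vapply(means, function(m) rlnorm_mean_cv(1, m, cv), 0)

      p_err <- odds_scale(profile$error_rate_base,
                          level_error_mult(effects, plan$level_kind) *
                            cond_error_mult(effects, plan$condition))
      err <- stats::runif(n) < p_err

      start_s <- t
      taps <- list()
      pauses <- empty_intervals()
      for (i in seq_len(n)) {
        if (err[i]) {
          wrong <- sample(setdiff(protocol$layout$tablets$tablet_id,
                                  items$tablet_id[i]), 1L)
          taps[[length(taps) + 1L]] <- data.frame(
            t_s = t + 0.6 * intervals[i], tablet_id = wrong,
            displayed_character = items$character[i], correct = FALSE)
        }
        t <- t + intervals[i]
        taps[[length(taps) + 1L]] <- data.frame(
          t_s = t, tablet_id = items$tablet_id[i],
          displayed_character = items$character[i], correct = TRUE)
        if (!is.null(plan$exercise_trigger) && i == plan$exercise_trigger + 1L) {
          pause_len <- timing$exercise_pause
          pauses <- rbind(pauses, data.frame(start_s = t, end_s = t + pause_len))
          hr_segments[[length(hr_segments) + 1L]] <-
            list(t0 = t, t1 = t + pause_len,
                 target = steady(plan$level_kind, plan$condition, spike = 0.08))
          t <- t + pause_len
        }
      }
      end_s <- t
      hr_segments[[length(hr_segments) + 1L]] <-
        list(t0 = start_s, t1 = end_s,
             target = steady(plan$level_kind, plan$condition))
      reps_out[[length(reps_out) + 1L]] <- list(
        level_kind = plan$level_kind, condition = plan$condition,
        rep_number = plan$rep_number %||% (length(reps_out) + 1L),
        start_s = start_s, end_s = end_s,
        taps = do.call(rbind, taps), pause_intervals = pauses)
      level_rep_spans[[length(level_rep_spans) + 1L]] <- c(start_s, end_s)
      t <- t + timing$rep_break
    }
    levels_out[[length(levels_out) + 1L]] <-
      list(level_kind = lv$level_kind, reps = reps_out)

    # check-in after the level: RPE from achieved intensity over its reps
    inten <- steady(lv$level_kind, "standard") / hrmax * 100
    rpe <- max(0L, min(10L, as.integer(round(profile$rpe_slope * inten / 10))))
    checkins[[length(checkins) + 1L]] <- data.frame(
      after_level = lv$level_kind, rpe = rpe,
      symptom_response = sample(1:2, 1L, prob = c(0.7, 0.3)))
    t <- t + timing$checkin
  }

  hr <- simulate_hr_trace(hr_segments, t + 15, rest, hrmax, profile$tau_s)

  sus <- integer(10)
  odd <- seq(1, 9, by = 2)
  sus[odd] <- sample(3:5, 5L, replace = TRUE)   # positively worded: agree
  sus[-odd] <- sample(1:3, 5L, replace = TRUE)  # negatively worded: disagree

  new_session(
    participant = list(id = participant_id, age_years = profile$age_years,
                       wheelchair = profile$wheelchair),
    configuration_interval = config_interval,
    levels = levels_out,
    hr_stream = hr,
    checkins = do.call(rbind, checkins),
    baseline_pcsi_total = stats::rbinom(1L, 11L, 0.35),
    sus_responses = sus,
    resting_hr_bpm = rest)
}

#' Simulate a cohort of sessions
#'
#' Draws independent participant profiles (integer ages uniform over
#' `age_range`, baseline speed, resting heart rate, heart-rate kinetics) and
#' simulates one session per participant, each over a freshly generated
#' protocol. Fully reproducible from `seed`.
#'
#' @param n number of sessions (>= 1).
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @param age_range inclusive integer age range to draw from.
#' @param protocol optional fixed `r2p_protocol`; when `NULL` each session
#'   gets its own seed-derived protocol.
#' @return list of `r2p_session` objects.
#' @export
simulate_cohort <- function(n, effects = effect_config(), seed = 1L,
                            age_range = c(10L, 22L), protocol = NULL) {
  if (!is_scalar_number(n) || n < 1)
    stop_r2p("n must be at least 1", class = "r2play_config_error")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  lapply(seq_len(n), function(i) {
    profile <- participant_profile(
      age_years = sample(seq(age_range[1], age_range[2]), 1L),
      wheelchair = stats::runif(1) < 0.1,
      base_spt = stats::runif(1, 1.3, 2.0),
      hr_rest_bpm = stats::runif(1, 60, 80),
      hr_gain = stats::runif(1, 0.9, 1.05),
      tau_s = stats::runif(1, 25, 40),
      error_rate_base = 0.02,
      rpe_slope = 0.55)
    prot <- protocol %||% build_protocol(protocol_config(seed = sub_seeds[2 * i - 1L]))
    simulate_session(prot, profile, effects, seed = sub_seeds[2 * i],
                     participant_id = sprintf("S%03d", i))
  })
}

#' Recover injected effects from a scored cohort
#'
#' Scores every session and summarizes each cost x metric across the cohort
#' (median/IQR plus mean/SD/CI), the shape used for cohort cost-score
#' reporting. With a single injected time factor f, the recovered median time
#' cost converges on `100 * (f - 1)` as the timing noise goes to zero.
#'
#' @param sessions list of `r2p_session` objects.
#' @param metrics which metrics to summarize.
#' @param quartile quartile convention for the IQR (see [summarize_cohort()]).
#' @param pause_exclusion passed to [compute_cost_scores()].
#' @return data frame: `cost`, `metric`, `n` (sessions with the cost
#'   defined), `median`, `iqr`, `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
recover_effects <- function(sessions, metrics = c("time", "hr"),
                            quartile = "linear", pause_exclusion = TRUE) {
  scored <- lapply(sessions, compute_cost_scores, pause_exclusion = pause_exclusion)
  out <- list()
  for (cost in COSTS) for (metric in metrics) {
    vals <- vapply(scored, function(s)
      s$value[s$cost == cost & s$metric == metric], 0)
    vals <- vals[!is.na(vals)]
    row <- data.frame(cost = cost, metric = metric, n = length(vals),
                      median = NA_real_, iqr = NA_real_, mean = NA_real_,
                      sd = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
    if (length(vals)) {
      s <- summarize_cohort(vals, quartile = quartile)
      row$median <- s$median; row$iqr <- s$iqr
      row$mean <- s$mean; row$sd <- s$sd
      row$ci_lo <- s$ci95[["lo"]]; row$ci_hi <- s$ci95[["hi"]]
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
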