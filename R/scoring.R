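#' @title Multi-domain cost scoring
#' @description
#' Performance on each repetition is summarized by three metrics: completion
#' time standardized as seconds per correct tablet selection, error count
#' (incorrect tablet selections), and average heart rate over the repetition.
#' Multi-domain cost scores generalize the dual-task cost statistic: the
#' percent change in a metric between a baseline level/condition and a more
#' demanding one, with positive values indicating a performance cost. Where a
#' level or condition is duplicated (the standard condition and the motor
#' task), the better of the two repetitions -- shortest time, fewest errors,
#' lowest average heart rate -- serves as the comparison value.
#' @name scoring
NULL

COSTS <- c("exertion", "cognitive_moderate", "cognitive_high",
           "auditory", "scramble", "fatigue")
METRICS <- c("time", "errors", "hr")
CORE_LEVELS <- c("number_letter", "exercise", "go_no_go", "stroop")

#' Seconds per tablet
#'
#' Standardized completion-time metric: repetition duration, minus any
#' exercise-beep pause time when `pause_exclusion` is on, divided by the
#' number of correct tablet selections. Standardizing by correct selections
#' makes the 8-selection go/no-go and Stroop repetitions comparable with the
#' 12-selection levels.
#'
#' @param rep a repetition record (see [new_session()]).
#' @param pause_exclusion subtract exercise-pause time from the span.
#' @return seconds per correct selection, or `NA` if the repetition has no
#'   correct taps.
#' @examples
#' rep <- list(start_s = 0, end_s = 21, pause_intervals = NULL,
#'             taps = data.frame(t_s = 1:12, tablet_id = "T1",
#'                               displayed_character = "1", correct = TRUE))
#' seconds_per_tablet(rep) # 1.75
#' @export
seconds_per_tablet <- function(rep, pause_exclusion = TRUE) {
  n_correct <- sum(rep$taps$correct)
  if (n_correct == 0L) return(NA_real_)
  pause_s <- if (pause_exclusion && !is.null(rep$pause_intervals) &&
                 nrow(rep$pause_intervals)) {
    sum(rep$pause_intervals$end_s - rep$pause_intervals$start_s)
  } else 0
  (rep$end_s - rep$start_s - pause_s) / n_correct
}

#' Error count of a repetition
#'
#' @param rep a repetition record.
#' @return number of incorrect tablet selections.
#' @export
rep_errors <- function(rep) sum(!rep$taps$correct)

# time-weighted (trapezoidal) mean of a piecewise-linear HR trace over
# [t0, t1], interpolating at the interval edges; NA when no sample falls
# inside the interval.
hr_weighted_mean <- function(hr, t0, t1, method = c("trapezoid", "mean")) {
  method <- match.arg(method)
  inside <- hr$t_s >= t0 & hr$t_s <= t1
  if (!any(inside)) return(NA_real_)
  if (method == "mean") return(mean(hr$bpm[inside]))
  ts <- hr$t_s[inside]; bpm <- hr$bpm[inside]
  if (min(ts) > t0 && any(hr$t_s < t0)) {
    ts <- c(t0, ts); bpm <- c(stats::approx(hr$t_s, hr$bpm, t0, ties = "ordered")$y, bpm)
  }
  if (max(ts) < t1 && any(hr$t_s > t1)) {
    ts <- c(ts, t1); bpm <- c(bpm, stats::approx(hr$t_s, hr$bpm, t1, ties = "ordered")$y)
  }
  if (length(ts) == 1L) return(bpm)
  dt <- diff(ts)
  sum((bpm[-1] + bpm[-length(bpm)]) / 2 * dt) / sum(dt)
}

#' Average heart rate of a repetition
#'
#' Time-weighted mean of the heart-rate stream over the repetition span
#' (pauses included: the heart keeps beating through an exercise bout).
#'
#' @param rep repetition record.
#' @param hr_stream data frame `t_s`, `bpm`.
#' @param method `"trapezoid"` (time-weighted, default) or `"mean"` (simple
#'   sample mean).
#' @return bpm, or `NA` when no sample covers the repetition.
#' @export
rep_avg_hr <- function(rep, hr_stream, method = "trapezoid") {
  if (is.null(hr_stream) || !nrow(hr_stream)) return(NA_real_)
  hr_weighted_mean(hr_stream, rep$start_s, rep$end_s, method)
}

#' Per-repetition metrics table
#'
#' @param session an `r2p_session`.
#' @param pause_exclusion passed to [seconds_per_tablet()].
#' @param hr_method passed to [rep_avg_hr()].
#' @return data frame with one row per repetition: `level_kind`, `condition`,
#'   `rep_number`, `seconds_per_tablet`, `errors`, `avg_hr_bpm`.
#' @export
rep_metrics <- function(session, pause_exclusion = TRUE, hr_method = "trapezoid") {
  reps <- session_reps(session)
  out <- lapply(reps, function(r) data.frame(
    level_kind = r$level_kind,
    condition = r$condition,
    rep_number = r$rep_number %||% NA_integer_,
    seconds_per_tablet = seconds_per_tablet(r, pause_exclusion),
    errors = rep_errors(r),
    avg_hr_bpm = rep_avg_hr(r, session$hr_stream, hr_method),
    stringsAsFactors = FALSE))
  if (!length(out)) return(data.frame(
    level_kind = character(), condition = character(), rep_number = integer(),
    seconds_per_tablet = numeric(), errors = numeric(), avg_hr_bpm = numeric()))
  do.call(rbind, out)
}

#' Best of duplicated repetitions
#'
#' The best-of-two baseline rule, applied per metric independently: minimum
#' over the supplied values (shortest time, fewest errors, lowest average
#' heart rate), skipping undefined (`NA`) values.
#'
#' @param values numeric vector of one metric across repetitions.
#' @return the best value, or `NA` if none is defined.
#' @export
best_of <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  min(values)
}

#' Cost score
#'
#' Percent change from a baseline to a more demanding challenge value:
#' `(challenge - baseline) / baseline * 100`, reported to 2 decimals
#' (half-up). A zero baseline leaves the cost undefined -- the reason
#' error-based costs are typically incomputable in error-free cohorts.
#'
#' @param baseline baseline metric value.
#' @param challenge challenge metric value.
#' @return percent cost; `NA` with attribute `reason` (`"zero_baseline"` or
#'   `"missing_value"`) when undefined.
#' @examples
#' cost_score(1.75, 1.94) # 10.86
#' cost_score(0.83, 0.93) # 12.05
#' @export
cost_score <- function(baseline, challenge) {
  if (is.na(baseline) || is.na(challenge))
    return(structure(NA_real_, reason = "missing_value"))
  if (baseline == 0)
    return(structure(NA_real_, reason = "zero_baseline"))
  round_half_up((challenge - baseline) / baseline * 100, 2)
}

cost_row <- function(cost, metric, baseline, challenge,
                     reason = NA_character_) {
  value <- NA_real_
  if (is.na(reason)) {
    v <- cost_score(baseline, challenge)
    value <- as.numeric(v)
    if (is.na(value)) reason <- attr(v, "reason")
  }
  data.frame(cost = cost, metric = metric,
             baseline = as.numeric(baseline), challenge = as.numeric(challenge),
             value = value, reason = reason, stringsAsFactors = FALSE)
}

metric_col <- c(time = "seconds_per_tablet", errors = "errors", hr = "avg_hr_bpm")

#' Compute the six multi-domain cost scores
#'
#' For each of the three metrics (completion time as seconds/tablet, errors,
#' average heart rate):
#' \describe{
#'   \item{exertion}{number-letter standard (best of two) vs exercise
#'     standard (best of two) -- physical load.}
#'   \item{cognitive_moderate}{number-letter vs go/no-go standard -- response
#'     inhibition.}
#'   \item{cognitive_high}{number-letter vs Stroop standard -- rule reversal.}
#'   \item{auditory}{mean across the four core levels of the per-level
#'     standard best vs mean of the per-level auditory-interference
#'     repetition -- perceptual load.}
#'   \item{scramble}{as auditory, with the scramble repetition --
#'     perception-action switching.}
#'   \item{fatigue}{pre-motor task (best of two) vs post-motor task (best of
#'     two).}
#' }
#' Undefined entries carry a machine-readable reason: `missing_level` (a
#' required level/repetition absent or without a defined metric),
#' `missing_hr` (no heart-rate coverage), or `zero_baseline`.
#'
#' @param session an `r2p_session`.
#' @param pause_exclusion exclude exercise-pause time from completion times.
#' @param hr_method heart-rate averaging method (see [rep_avg_hr()]).
#' @return data frame of class `r2p_cost_scores`: one row per cost x metric
#'   with `baseline`, `challenge`, `value` (percent, 2 decimals) and `reason`.
#' @export
compute_cost_scores <- function(session, pause_exclusion = TRUE,
                                hr_method = "trapezoid") {
  m <- rep_metrics(session, pause_exclusion, hr_method)

  get_vals <- function(level, cond, col) {
    m[m$level_kind == level & m$condition == cond, col]
  }
  std_best <- function(level, col) best_of(get_vals(level, "standard", col))

  out <- list()
  for (metric in METRICS) {
    col <- metric_col[[metric]]
    miss_reason <- function(b, c_, levels_needed) {
      have <- all(levels_needed %in% m$level_kind)
      if (!have) return("missing_level")
      if (is.na(b) || is.na(c_))
        return(if (metric == "hr") "missing_hr" else "missing_level")
      NA_character_
    }
    pair <- function(cost, b_level, c_level) {
      b <- std_best(b_level, col); c_ <- std_best(c_level, col)
      out[[length(out) + 1L]] <<- cost_row(
        cost, metric, b, c_, miss_reason(b, c_, c(b_level, c_level)))
    }
    pair("exertion", "number_letter", "exercise")
    pair("cognitive_moderate", "number_letter", "go_no_go")
    pair("cognitive_high", "number_letter", "stroop")

    for (cond in c("auditory", "scramble")) {
      bases <- vapply(CORE_LEVELS, std_best, 0, col = col)
      chals <- vapply(CORE_LEVELS, function(lv) {
        v <- get_vals(lv, cond, col)
        if (!length(v)) NA_real_ else mean(v)
      }, 0)
      b <- if (anyNA(bases)) NA_real_ else mean(bases)
      c_ <- if (anyNA(chals)) NA_real_ else mean(chals)
      reason <- if (!all(CORE_LEVELS %in% m$level_kind)) "missing_level"
      else if (is.na(b) || is.na(c_)) {
        if (metric == "hr") "missing_hr" else "missing_level"
      } else NA_character_
      out[[length(out) + 1L]] <- cost_row(cond, metric, b, c_, reason)
    }
    pair("fatigue", "motor_pre", "motor_post")
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$cost, COSTS), match(res$metric, METRICS)), ]
  rownames(res) <- NULL
  class(res) <- c("r2p_cost_scores", "data.frame")
  res
}

#' Cohort descriptive summary
#'
#' The descriptive block used for cohort reporting: n, mean, sample SD
#' (n - 1 denominator), a normal-approximation 95% CI
#' (mean +/- 1.96 * SD / sqrt(n)), median (midpoint of the middle two for
#' even n), IQR, min and max. Quartiles use linear interpolation by default;
#' `quartile = "tukey"` switches to Tukey hinges.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @param quartile `"linear"` (type-7 quantiles) or `"tukey"` (hinges).
#' @return list of class `r2p_cohort_summary` with fields `n`, `mean`, `sd`,
#'   `ci95` (`lo`, `hi`), `median`, `iqr`, `min`, `max`. `sd` and `ci95` are
#'   `NA` for n = 1.
#' @examples
#' s <- summarize_cohort(c(184, 155, 196, 156, 155, 152, 184, 132, 158, 163))
#' round(s$mean, 1); round(s$sd, 1)
#' @export
summarize_cohort <- function(values, quartile = c("linear", "tukey")) {
  quartile <- match.arg(quartile)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop_r2p("no defined values to summarize", class = "r2play_computation_error")
  mu <- mean(values)
  sdv <- if (n >= 2L) stats::sd(values) else NA_real_
  half <- if (n >= 2L) 1.96 * sdv / sqrt(n) else NA_real_
  q <- if (quartile == "linear") {
    stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  } else {
    f <- stats::fivenum(values); f[c(2, 4)]
  }
  structure(
    list(n = n, mean = mu, sd = sdv,
         ci95 = c(lo = mu - half, hi = mu + half),
         median = stats::median(values), iqr = q[2] - q[1],
         min = min(values), max = max(values)),
    class = "r2p_cohort_summary")
}

#' @export
print.r2p_cohort_summary <- function(x, digits = 2, ...) {
  cat(sprintf("n = %d; mean %s +/- %s (95%% CI %s, %s); median %s (IQR %s); range %s-%s\n",
              x$n, round_half_up(x$mean, digits), round_half_up(x$sd, digits),
              round_half_up(x$ci95[["lo"]], digits), round_half_up(x$ci95[["hi"]], digits),
              round_half_up(x$median, digits), round_half_up(x$iqr, digits),
              round_half_up(x$min, digits), round_half_up(x$max, digits)))
  invisible(x)
}
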