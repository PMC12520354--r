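#' Age-predicted maximal heart rate (Tanaka)
#'
#' The Tanaka prediction `208 - 0.7 * age`, the standard age-based HRmax
#' estimate used to express exercise heart rates as a percentage of maximum.
#'
#' @param age_years age in years, within 5-80.
#' @return predicted maximal heart rate in bpm.
#' @examples
#' tanaka_hrmax(10) # 201
#' @export
tanaka_hrmax <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 5) || any(age_years > 80))
    stop_r2p("age_years must lie in [5, 80]", class = "r2play_validation_error")
  208 - 0.7 * age_years
}

#' Exertion summary of a session
#'
#' Average and peak heart rate over the active assessment windows (each
#' repetition plus the 10 s that follow it; see [active_windows()]), raw and
#' as a percentage of the age-predicted maximum ([tanaka_hrmax()]), plus the
#' highest rating of perceived exertion reported at check-ins. The average is
#' a time-weighted (trapezoidal) mean so irregular sampling does not bias it;
#' `hr_method = "mean"` gives the simple sample mean instead. Sessions whose
#' heart-rate stream does not cover any active window (e.g. a lost
#' sensor-to-event synchronization) get `NA` heart-rate fields rather than
#' imputed values.
#'
#' @param session an `r2p_session`.
#' @param hr_method `"trapezoid"` or `"mean"`.
#' @param after_s post-repetition tail in seconds.
#' @return list of class `r2p_exertion_summary`: `avg_hr_bpm`, `peak_hr_bpm`,
#'   `avg_pct_max`, `peak_pct_max`, `peak_rpe`, `hrmax_predicted_bpm`.
#' @export
exertion_summary <- function(session, hr_method = "trapezoid", after_s = 10) {
  win <- active_windows(session, after_s = after_s)
  hr <- session$hr_stream
  hrmax <- tanaka_hrmax(session$participant$age_years)

  avg <- peak <- NA_real_
  if (!is.null(hr) && nrow(hr) && nrow(win)) {
    means <- durs <- numeric(0)
    peak_seen <- -Inf
    for (i in seq_len(nrow(win))) {
      m <- hr_weighted_mean(hr, win$start_s[i], win$end_s[i], hr_method)
      if (!is.na(m)) {
        means <- c(means, m)
        durs <- c(durs, win$end_s[i] - win$start_s[i])
        inside <- hr$t_s >= win$start_s[i] & hr$t_s <= win$end_s[i]
        peak_seen <- max(peak_seen, hr$bpm[inside])
      }
    }
    if (length(means)) {
      avg <- sum(means * durs) / sum(durs)
      peak <- peak_seen
    }
  }
  rpe <- if (nrow(session$checkins)) max(session$checkins$rpe) else NA_integer_

  structure(
    list(avg_hr_bpm = avg, peak_hr_bpm = peak,
         avg_pct_max = 100 * avg / hrmax, peak_pct_max = 100 * peak / hrmax,
         peak_rpe = rpe, hrmax_predicted_bpm = hrmax),
    class = "r2p_exertion_summary")
}

#' System Usability Scale score
#'
#' Brooke's SUS: 10 statements rated 1 (strongly disagree) to 5 (strongly
#' agree). Odd-numbered (positively worded) items contribute `response - 1`,
#' even-numbered (negatively worded) items contribute `5 - response`; the
#' total is 2.5 times the summed contributions, giving 0-100 in 2.5-point
#' steps. Interpretation bands: below 68 below average, 68 to below 80
#' average-to-good, 80 and above good-to-excellent.
#'
#' @param responses integer vector of exactly 10 values in 1-5.
#' @return list of class `r2p_sus` with `responses`, `item_contributions`,
#'   `total` and `band`.
#' @examples
#' sus_score(rep(3, 10))$total # 50
#' @export
sus_score <- function(responses) {
  if (length(responses) != 10L || any(!responses %in% 1:5))
    stop_r2p("SUS needs exactly 10 responses, each in 1-5",
             class = "r2play_validation_error")
  responses <- as.integer(responses)
  odd <- seq(1, 9, by = 2)
  contrib <- integer(10)
  contrib[odd] <- responses[odd] - 1L
  contrib[-odd] <- 5L - responses[-odd]
  total <- 2.5 * sum(contrib)
  band <- if (total < 68) "below_average"
  else if (total < 80) "average_to_good"
  else "good_to_excellent"
  structure(list(responses = responses, item_contributions = contrib,
                 total = total, band = band),
            class = "r2p_sus")
}

#' Symptom stop rule
#'
#' Post-level symptom check-ins use four response options: (1) no symptoms,
#' (2) some symptoms but not worse, (3) symptoms got worse, (4) symptoms so
#' much worse the participant had to stop. The assessment stops at the first
#' response of 4; a response of 3 raises a worsened flag without stopping.
#'
#' @param checkins either the `checkins` data frame of a session or a bare
#'   integer vector of symptom responses in 1-4.
#' @return list with `stop` (logical), `at_level` (1-based check-in index, or
#'   the `after_level` label when available; `NA` if no stop) and `worsened`.
#' @export
symptom_stop_flag <- function(checkins) {
  if (is.data.frame(checkins)) {
    resp <- checkins$symptom_response
    labels <- checkins$after_level
  } else {
    resp <- checkins
    labels <- NULL
  }
  if (length(resp) && any(!resp %in% 1:4))
    stop_r2p("symptom responses must be in 1-4", class = "r2play_validation_error")
  hit <- which(resp == 4L)
  stop <- length(hit) > 0L
  at <- if (!stop) NA else if (!is.null(labels)) labels[hit[1]] else hit[1]
  list(stop = stop, at_level = at, worsened = any(resp == 3L))
}
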