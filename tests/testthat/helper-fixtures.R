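# fixtures are built in code; no binary data

make_rep <- function(level_kind = "number_letter", condition = "standard",
                     rep_number = 1L, start_s = 0, spt = 1.5, n = 12L,
                     n_errors = 0L, pause_s = 0) {
  tap_times <- start_s + cumsum(rep(spt, n))
  if (pause_s > 0) {
    half <- n %/% 2
    tap_times[(half + 1):n] <- tap_times[(half + 1):n] + pause_s
    pauses <- data.frame(start_s = tap_times[half], end_s = tap_times[half] + pause_s)
  } else pauses <- data.frame(start_s = numeric(), end_s = numeric())
  taps <- data.frame(t_s = tap_times, tablet_id = "T1",
                     displayed_character = rep_len(c("1","A","2","B","3","C"), n),
                     correct = TRUE, stringsAsFactors = FALSE)
  if (n_errors > 0) {
    err <- data.frame(t_s = tap_times[seq_len(n_errors)] - 0.3, tablet_id = "T2",
                      displayed_character = "1", correct = FALSE)
    taps <- rbind(taps, err)
    taps <- taps[order(taps$t_s), ]
  }
  list(level_kind = level_kind, condition = condition, rep_number = rep_number,
       start_s = start_s, end_s = max(taps$t_s),
       taps = taps, pause_intervals = pauses)
}

# session with controllable per-level seconds-per-tablet; reps laid out
# sequentially with 30 s gaps
make_session <- function(spts = list(
                           motor_pre = c(0.9, 0.9), number_letter = c(1.5, 1.5),
                           exercise = c(1.5, 1.5), go_no_go = c(1.5, 1.5),
                           stroop = c(1.5, 1.5), motor_post = c(0.9, 0.9)),
                         aud_spt = NULL, scr_spt = NULL,
                         age = 14, hr_stream = NULL) {
  t <- 400
  levels <- list()
  for (lk in names(spts)) {
    n <- if (lk %in% c("go_no_go", "stroop")) 8L else
         if (grepl("motor", lk)) 6L else 12L
    reps <- list()
    conds <- rep("standard", length(spts[[lk]]))
    vals <- spts[[lk]]
    if (!grepl("motor", lk)) {
      if (!is.null(aud_spt)) { conds <- c(conds, "auditory"); vals <- c(vals, aud_spt[[lk]]) }
      if (!is.null(scr_spt)) { conds <- c(conds, "scramble"); vals <- c(vals, scr_spt[[lk]]) }
    }
    for (i in seq_along(vals)) {
      r <- make_rep(lk, conds[i], i, start_s = t, spt = vals[i], n = n)
      reps[[i]] <- r
      t <- r$end_s + 30
    }
    levels[[length(levels) + 1L]] <- list(level_kind = lk, reps = reps)
  }
  new_session(participant = list(id = "F1", age_years = age, wheelchair = FALSE),
              configuration_interval = c(0, 360),
              levels = levels,
              hr_stream = hr_stream,
              checkins = data.frame(after_level = names(spts),
                                    rpe = 3L, symptom_response = 1L),
              resting_hr_bpm = 70)
}

pilot_exertion <- function() {
  utils::read.csv(system.file("extdata", "pilot_exertion.csv", package = "r2play"))
}

pilot_durations <- function() {
  utils::read.csv(system.file("extdata", "pilot_durations.csv", package = "r2play"))
}
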