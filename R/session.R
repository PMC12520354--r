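#' @title Session event logs
#' @description
#' A session record is the complete machine log of one assessment: tap events
#' per repetition, a 1 Hz-ish heart-rate stream, post-level check-ins (OMNI
#' RPE 0-10 and a 4-option symptom-change response), the configuration
#' interval preceding the first repetition, and participant metadata. The
#' on-disk format is a single JSON document, schema `r2play-session/1`; the
#' heart-rate stream may live inline or in a sidecar CSV (`t_s,bpm`). All
#' timestamps are seconds from session start.
#' @name session_log
NULL

SESSION_SCHEMA <- "r2play-session/1"

empty_taps <- function() {
  data.frame(t_s = numeric(), tablet_id = character(),
             displayed_character = character(), correct = logical(),
             stringsAsFactors = FALSE)
}

empty_intervals <- function() data.frame(start_s = numeric(), end_s = numeric())

empty_checkins <- function() {
  data.frame(after_level = character(), rpe = integer(),
             symptom_response = integer(), stringsAsFactors = FALSE)
}

#' Construct a session record
#'
#' @param participant list with `id`, `age_years`, `wheelchair`.
#' @param configuration_interval numeric `(start_s, end_s)` of the
#'   configuration phase (setup, customization, baseline measures).
#' @param levels ordered list of `list(level_kind, reps)`; each repetition is
#'   a `list(level_kind, condition, rep_number, start_s, end_s, taps,
#'   pause_intervals)` where `taps` has columns `t_s`, `tablet_id`,
#'   `displayed_character`, `correct` and `pause_intervals` has `start_s`,
#'   `end_s` (exercise-beep pauses).
#' @param hr_stream data frame `t_s`, `bpm`.
#' @param checkins data frame `after_level`, `rpe`, `symptom_response`.
#' @param baseline_pcsi_total non-negative integer symptom-inventory total.
#' @param sus_responses optional 10 usability-item responses (1-5).
#' @param resting_hr_bpm resting heart rate measured pre-assessment.
#' @param break_intervals optional data frame of explicit rest breaks
#'   (`start_s`, `end_s`) excluded from active assessment time.
#' @return object of class `r2p_session`.
#' @export
new_session <- function(participant, configuration_interval, levels,
                        hr_stream = NULL, checkins = NULL,
                        baseline_pcsi_total = 0L, sus_responses = NULL,
                        resting_hr_bpm = NA_real_, break_intervals = NULL) {
  structure(
    list(schema = SESSION_SCHEMA,
         participant = list(id = as.character(participant$id),
                            age_years = as.numeric(participant$age_years),
                            wheelchair = isTRUE(participant$wheelchair)),
         configuration_interval = as.numeric(configuration_interval),
         levels = levels,
         break_intervals = break_intervals %||% empty_intervals(),
         hr_stream = hr_stream %||% data.frame(t_s = numeric(), bpm = numeric()),
         checkins = checkins %||% empty_checkins(),
         baseline_pcsi_total = as.integer(baseline_pcsi_total),
         sus_responses = if (!is.null(sus_responses)) as.integer(sus_responses),
         resting_hr_bpm = as.numeric(resting_hr_bpm)),
    class = "r2p_session"
  )
}

#' Flatten a session's repetitions
#'
#' @param session an `r2p_session`.
#' @return list of repetition records in session order.
#' @export
session_reps <- function(session) {
  do.call(c, lapply(session$levels, `[[`, "reps")) %||% list()
}

#' Validate a session record
#'
#' Checks every structural invariant of the event-log format and returns the
#' violations as data, not exceptions: tap times non-negative and strictly
#' increasing within a repetition, taps inside their repetition interval,
#' repetition intervals well-ordered and non-overlapping, pauses inside their
#' repetition and disjoint, heart-rate samples in a physiological range
#' (30-250 bpm) with non-decreasing timestamps, RPE in 0-10, symptom
#' responses in 1-4, SUS responses (if present) exactly 10 values in 1-5,
#' and the configuration interval preceding the first repetition.
#'
#' @param session an `r2p_session`.
#' @return data frame with columns `location` and `message`; zero rows when
#'   the session is well formed.
#' @export
validate_session <- function(session) {
  bad <- list()
  note <- function(location, message)
    bad[[length(bad) + 1L]] <<- data.frame(location = location, message = message)

  ci <- session$configuration_interval
  if (length(ci) != 2L || !all(is.finite(ci)) || ci[1] > ci[2])
    note("configuration_interval", "configuration interval missing or inverted")

  reps <- session_reps(session)
  prev_end <- -Inf
  for (i in seq_along(reps)) {
    r <- reps[[i]]
    loc <- sprintf("repetition %d (%s/%s)", i, r$level_kind, r$condition)
    if (!is.finite(r$start_s) || !is.finite(r$end_s) || r$start_s >= r$end_s)
      note(loc, "repetition interval inverted")
    if (is.finite(r$start_s) && r$start_s < prev_end)
      note(loc, "repetition intervals overlap or are out of order")
    prev_end <- max(prev_end, r$end_s)
    taps <- r$taps
    if (nrow(taps)) {
      if (any(taps$t_s < 0)) note(loc, "tap time negative")
      if (any(diff(taps$t_s) <= 0)) note(loc, "tap times not strictly increasing")
      if (any(taps$t_s < r$start_s | taps$t_s > r$end_s))
        note(loc, "tap outside repetition interval")
    }
    pz <- r$pause_intervals
    if (!is.null(pz) && nrow(pz)) {
      if (any(pz$start_s >= pz$end_s)) note(loc, "pause interval inverted")
      if (any(pz$start_s < r$start_s | pz$end_s > r$end_s))
        note(loc, "pause outside repetition interval")
      if (nrow(pz) > 1L && any(pz$start_s[-1] < pz$end_s[-nrow(pz)]))
        note(loc, "pause intervals overlap")
    }
  }
  if (length(reps) && length(ci) == 2L && is.finite(ci[2]) &&
      ci[2] > reps[[1]]$start_s)
    note("configuration_interval", "configuration interval overlaps first repetition")

  hr <- session$hr_stream
  if (nrow(hr)) {
    if (any(hr$bpm < 30 | hr$bpm > 250))
      note("hr_stream", "bpm out of physiological range [30, 250]")
    if (any(diff(hr$t_s) < 0)) note("hr_stream", "HR timestamps decrease")
  }
  ck <- session$checkins
  if (nrow(ck)) {
    if (any(ck$rpe < 0 | ck$rpe > 10)) note("checkins", "rpe outside 0-10")
    if (any(!ck$symptom_response %in% 1:4))
      note("checkins", "symptom_response outside 1-4")
  }
  if (!is.null(session$sus_responses)) {
    s <- session$sus_responses
    if (length(s) != 10L || any(!s %in% 1:5))
      note("sus_responses", "SUS needs exactly 10 responses in 1-5")
  }
  if (is.na(session$baseline_pcsi_total) || session$baseline_pcsi_total < 0)
    note("baseline_pcsi_total", "baseline PCSI total must be a non-negative integer")

  if (length(bad)) do.call(rbind, bad) else
    data.frame(location = character(), message = character())
}

rep_to_list <- function(r) {
  list(level_kind = r$level_kind, condition = r$condition,
       rep_number = r$rep_number, start_s = r$start_s, end_s = r$end_s,
       taps = r$taps, pause_intervals = r$pause_intervals %||% empty_intervals())
}

#' Write / read a session record
#'
#' Serialization is canonical (fixed key order, full numeric precision) so
#' that write -> read -> write is byte-identical. With `hr_csv`, the
#' heart-rate stream is written to a sidecar CSV (header `t_s,bpm`) and
#' referenced by relative path from the JSON document.
#'
#' @param session an `r2p_session`.
#' @param path JSON file path.
#' @param hr_csv optional sidecar CSV path (relative paths resolve against
#'   the JSON file's directory).
#' @return `write_session` returns `path` invisibly; `read_session` an
#'   `r2p_session`.
#' @export
write_session <- function(session, path, hr_csv = NULL) {
  stopifnot(inherits(session, "r2p_session"))
  doc <- list(
    schema = SESSION_SCHEMA,
    participant = session$participant,
    configuration_interval = session$configuration_interval,
    levels = lapply(session$levels, function(lv)
      list(level_kind = lv$level_kind, reps = lapply(lv$reps, rep_to_list))),
    break_intervals = session$break_intervals,
    checkins = session$checkins,
    baseline_pcsi_total = session$baseline_pcsi_total,
    sus_responses = session$sus_responses,
    resting_hr_bpm = session$resting_hr_bpm
  )
  if (is.null(hr_csv)) {
    doc$hr_stream <- session$hr_stream
  } else {
    abs <- if (grepl("^/", hr_csv)) hr_csv else file.path(dirname(path), hr_csv)
    utils::write.csv(session$hr_stream, abs, row.names = FALSE, quote = FALSE)
    doc$hr_csv <- hr_csv
  }
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                              na = "null", pretty = TRUE), path)
  invisible(path)
}

as_df <- function(x, template) {
  if (is.null(x) || (is.list(x) && !length(x)) ||
      (is.data.frame(x) && !nrow(x))) return(template)
  as.data.frame(x)
}

require_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop_r2p("missing required field '", field, "' in ", where,
             class = "r2play_parse_error")
  x[[field]]
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(doc$schema, SESSION_SCHEMA))
    stop_r2p("not an ", SESSION_SCHEMA, " document", class = "r2play_parse_error")
  for (f in c("participant", "configuration_interval", "levels"))
    require_field(doc, f, "session")

  lv_raw <- doc$levels
  levels <- lapply(seq_len(nrow(lv_raw)), function(i) {
    reps_raw <- lv_raw$reps[[i]]
    reps <- lapply(seq_len(nrow(reps_raw)), function(j) {
      r <- lapply(reps_raw, function(col) if (is.data.frame(col)) col[j, ] else col[[j]])
      for (f in c("level_kind", "condition", "start_s", "end_s"))
        require_field(r, f, sprintf("repetition %d of level %d", j, i))
      list(level_kind = r$level_kind, condition = r$condition,
           rep_number = r$rep_number, start_s = r$start_s, end_s = r$end_s,
           taps = as_df(r$taps, empty_taps()),
           pause_intervals = as_df(r$pause_intervals, empty_intervals()))
    })
    list(level_kind = lv_raw$level_kind[i], reps = reps)
  })

  hr <- if (!is.null(doc$hr_csv)) {
    abs <- if (grepl("^/", doc$hr_csv)) doc$hr_csv else file.path(dirname(path), doc$hr_csv)
    utils::read.csv(abs)
  } else as_df(doc$hr_stream, data.frame(t_s = numeric(), bpm = numeric()))

  ck <- as_df(doc$checkins, empty_checkins())
  if (nrow(ck)) {
    for (f in c("after_level", "rpe", "symptom_response"))
      if (is.null(ck[[f]]) || anyNA(ck[[f]]))
        stop_r2p("missing required field '", f, "' in checkins",
                 class = "r2play_parse_error")
  }

  new_session(
    participant = as.list(doc$participant),
    configuration_interval = doc$configuration_interval,
    levels = levels,
    hr_stream = hr,
    checkins = ck,
    baseline_pcsi_total = doc$baseline_pcsi_total %||% 0L,
    sus_responses = doc$sus_responses,
    resting_hr_bpm = doc$resting_hr_bpm %||% NA_real_,
    break_intervals = as_df(doc$break_intervals, empty_intervals())
  )
}

#' Active assessment windows
#'
#' One window per repetition, spanning the repetition plus the `after_s`
#' seconds that follow it (heart rate keeps reflecting the effort just
#' completed); overlapping windows are merged by default.
#'
#' @param session an `r2p_session`.
#' @param after_s post-repetition tail in seconds.
#' @param merge merge overlapping windows into maximal disjoint spans.
#' @return data frame `start_s`, `end_s`, sorted and (when merged) disjoint.
#' @export
active_windows <- function(session, after_s = 10, merge = TRUE) {
  reps <- session_reps(session)
  if (!length(reps)) return(empty_intervals())
  w <- data.frame(start_s = vapply(reps, `[[`, 0, "start_s"),
                  end_s = vapply(reps, `[[`, 0, "end_s") + after_s)
  w <- w[order(w$start_s), , drop = FALSE]
  if (!merge) { rownames(w) <- NULL; return(w) }
  out <- w[1, ]
  for (i in seq_len(nrow(w))[-1]) {
    k <- nrow(out)
    if (w$start_s[i] <= out$end_s[k]) {
      out$end_s[k] <- max(out$end_s[k], w$end_s[i])
    } else out <- rbind(out, w[i, ])
  }
  rownames(out) <- NULL
  out
}

#' Session duration breakdown
#'
#' Splits the session into configuration time (setup, customization, baseline
#' measures) and active assessment time. Active time is, by default, the span
#' from the first repetition's start to the last repetition's end minus any
#' explicit break intervals marked in the log (`active = "span"`); the
#' alternative `"sum"` counts only time inside repetitions.
#'
#' @param session an `r2p_session`.
#' @param active `"span"` or `"sum"`.
#' @return named numeric `(configuration_min, active_min, total_min)`,
#'   minutes to 2 decimals.
#' @export
duration_breakdown <- function(session, active = c("span", "sum")) {
  active <- match.arg(active)
  ci <- session$configuration_interval
  if (length(ci) != 2L || !all(is.finite(ci)))
    stop_r2p("session has no configuration interval", class = "r2play_computation_error")
  config_s <- ci[2] - ci[1]
  reps <- session_reps(session)
  active_s <- if (!length(reps)) 0 else if (active == "sum") {
    sum(vapply(reps, function(r) r$end_s - r$start_s, 0))
  } else {
    span <- c(min(vapply(reps, `[[`, 0, "start_s")),
              max(vapply(reps, `[[`, 0, "end_s")))
    br <- session$break_intervals
    brk <- if (is.null(br) || !nrow(br)) 0 else
      sum(pmax(0, pmin(br$end_s, span[2]) - pmax(br$start_s, span[1])))
    diff(span) - brk
  }
  c(configuration_min = round_half_up(config_s / 60, 2),
    active_min = round_half_up(active_s / 60, 2),
    total_min = round_half_up((config_s + active_s) / 60, 2))
}
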