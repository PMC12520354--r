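#' @title Assessment protocol generation
#' @description
#' The assessment is a physical trail-making task: numbered/lettered tablets
#' are tapped in alternating alphanumeric order (1-A-2-B-3-C) while running
#' between them. Four core levels layer physical load (exercise bouts),
#' response inhibition (go/no-go), rule reversal (Stroop) and perceptual
#' interference on the baseline task, bracketed by a short pre/post motor
#' task. Trail sequences are generated so that the distance covered across
#' correct selections is standardized: 45 m (+/- 1%) for 12-selection
#' repetitions, 30 m (+/- 1%) for the 8-selection go/no-go and Stroop
#' repetitions, i.e. about 3.75 m per correct selection.
#' @name protocol
NULL

CHAR_CYCLE <- c("1", "A", "2", "B", "3", "C")

LEVEL_KINDS <- c("motor_pre", "number_letter", "exercise", "go_no_go",
                 "stroop", "motor_post")
CONDITIONS <- c("standard", "auditory", "scramble")

n_correct_for <- function(level_kind) {
  switch(level_kind,
         number_letter = 12L, exercise = 12L,
         go_no_go = 8L, stroop = 8L,
         motor_pre = 6L, motor_post = 6L,
         stop_r2p("unknown level_kind: ", level_kind, class = "r2play_config_error"))
}

has_distractors <- function(level_kind) level_kind %in% c("go_no_go", "stroop")

#' Protocol configuration
#'
#' Bundles the tunable pieces of a protocol build: tablet layout, the
#' standardized distances, the distance tolerance, and the seed controlling
#' condition order and character-to-tablet assignment.
#'
#' @param layout an [tablet_layout()] object; defaults to [default_layout()].
#' @param per_selection_m nominal distance per correct selection (m).
#' @param full_m target distance for 12-selection repetitions (m).
#' @param reduced_m target distance for 8-selection repetitions (m).
#' @param motor_m target distance for the 6-selection motor-task repetitions (m).
#' @param tolerance_frac fractional distance tolerance, in (0, 0.1].
#' @param seed integer RNG seed.
#' @param scramble_trigger optional 0-based index of the correct selection
#'   after which the scramble relocation fires; default halfway.
#' @return a list of class `r2p_protocol_config`.
#' @export
protocol_config <- function(layout = default_layout(),
                            per_selection_m = 3.75,
                            full_m = 45,
                            reduced_m = 30,
                            motor_m = 22.5,
                            tolerance_frac = 0.01,
                            seed = 1L,
                            scramble_trigger = NULL) {
  stopifnot(inherits(layout, "r2p_layout"))
  for (d in c(per_selection_m, full_m, reduced_m, motor_m))
    if (!is_scalar_number(d) || d <= 0)
      stop_r2p("distances must be positive numbers", class = "r2play_config_error")
  if (!is_scalar_number(tolerance_frac) || tolerance_frac <= 0 || tolerance_frac > 0.1)
    stop_r2p("tolerance_frac must lie in (0, 0.1]", class = "r2play_config_error")
  structure(
    list(layout = layout, per_selection_m = per_selection_m, full_m = full_m,
         reduced_m = reduced_m, motor_m = motor_m,
         tolerance_frac = tolerance_frac, seed = as.integer(seed),
         scramble_trigger = scramble_trigger),
    class = "r2p_protocol_config"
  )
}

#' Read a protocol configuration from YAML or JSON
#'
#' Recognized keys: `layout.tablets` (list of `[id, x, y]` or objects),
#' `layout.start`, `distances` (`per_selection`, `full`, `reduced`, `motor`,
#' `tolerance`) and `seed`. Missing keys fall back to the defaults of
#' [protocol_config()].
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return an `r2p_protocol_config`.
#' @export
read_protocol_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  layout <- default_layout()
  if (!is.null(raw$layout)) {
    tabs <- raw$layout$tablets
    if (is.data.frame(tabs)) {
      names(tabs) <- c("tablet_id", "x_m", "y_m")[seq_along(tabs)]
    } else {
      tabs <- do.call(rbind, lapply(tabs, function(t) {
        t <- unlist(t, use.names = FALSE)
        data.frame(tablet_id = as.character(t[1]),
                   x_m = as.numeric(t[2]), y_m = as.numeric(t[3]))
      }))
    }
    start <- as.numeric(unlist(raw$layout$start %||% c(0, 0)))
    layout <- tablet_layout(tabs, start)
  }
  d <- raw$distances %||% list()
  protocol_config(
    layout = layout,
    per_selection_m = d$per_selection %||% 3.75,
    full_m = d$full %||% 45,
    reduced_m = d$reduced %||% 30,
    motor_m = d$motor %||% 22.5,
    tolerance_frac = d$tolerance %||% 0.01,
    seed = raw$seed %||% 1L
  )
}

target_distance_for <- function(config, level_kind) {
  switch(level_kind,
         number_letter = , exercise = config$full_m,
         go_no_go = , stroop = config$reduced_m,
         motor_pre = , motor_post = config$motor_m)
}

correct_path_ids <- function(assignment, chars) unname(assignment[chars])

assignment_distance <- function(layout, assignment, chars) {
  path <- c(".start", unname(assignment[chars]))
  sum(layout$dist[cbind(path[-length(path)], path[-1])])
}

#' Generate one distance-standardized trail repetition
#'
#' Draws random character-to-tablet assignments (a bijection between the six
#' trail characters and six tablets) and rejects until the path distance over
#' correct selections falls within `target_distance_m * (1 +/- tolerance_frac)`,
#' bounded at `max_proposals` draws. Go/no-go and Stroop repetitions display
#' 12 items of which 4 are distractors to be skipped (go/no-go: distractors
#' red, targets green; Stroop: distractors green, targets red), leaving 8
#' correct selections. Scramble-condition plans are additionally passed
#' through [apply_scramble()].
#'
#' @param layout an `r2p_layout`.
#' @param level_kind one of `"motor_pre"`, `"number_letter"`, `"exercise"`,
#'   `"go_no_go"`, `"stroop"`, `"motor_post"`.
#' @param condition `"standard"`, `"auditory"` or `"scramble"`.
#' @param target_distance_m target path distance in metres.
#' @param tolerance_frac fractional tolerance on the target.
#' @param scramble_trigger optional 0-based correct-selection index for the
#'   scramble relocation (default: halfway through the trail).
#' @param max_proposals bound on rejection-sampling draws.
#' @return a repetition plan of class `r2p_rep_plan`; its `items` data frame
#'   has columns `character`, `tablet_id`, `order_index`, `is_distractor`,
#'   `display_color`.
#' @export
generate_trail <- function(layout, level_kind, condition = "standard",
                           target_distance_m = NULL, tolerance_frac = 0.01,
                           scramble_trigger = NULL, max_proposals = 10000L) {
  level_kind <- match.arg(level_kind, LEVEL_KINDS)
  condition <- match.arg(condition, CONDITIONS)
  n_cor <- n_correct_for(level_kind)
  if (is.null(target_distance_m))
    target_distance_m <- c(motor_pre = 22.5, number_letter = 45, exercise = 45,
                           go_no_go = 30, stroop = 30, motor_post = 22.5)[[level_kind]]
  tol <- target_distance_m * tolerance_frac
  chars <- rep_len(CHAR_CYCLE, n_cor)
  ids <- layout$tablets$tablet_id
  if (length(ids) < length(CHAR_CYCLE))
    stop_r2p("layout has fewer tablets than trail characters",
             class = "r2play_config_error")

  best <- Inf
  assignment <- NULL
  for (i in seq_len(max_proposals)) {
    cand <- stats::setNames(sample(ids, length(CHAR_CYCLE)), CHAR_CYCLE)
    d <- assignment_distance(layout, cand, chars)
    if (abs(d - target_distance_m) <= tol) { assignment <- cand; break }
    if (abs(d - target_distance_m) < abs(best - target_distance_m)) best <- d
  }
  if (is.null(assignment))
    stop_r2p(sprintf(
      "could not standardize trail to %.2f m (+/- %.1f%%); best achieved %.2f m",
      target_distance_m, 100 * tolerance_frac, best),
      class = "r2play_generation_error")

  if (has_distractors(level_kind)) {
    n_display <- 12L
    distractor_pos <- sort(sample.int(n_display, 4L)) # 1-based display slots
    is_distractor <- seq_len(n_display) %in% distractor_pos
    character <- character(n_display)
    character[!is_distractor] <- chars
    character[is_distractor] <- sample(CHAR_CYCLE, 4L, replace = TRUE)
    target_col <- if (level_kind == "go_no_go") "green" else "red"
    lure_col <- if (level_kind == "go_no_go") "red" else "green"
    display_color <- ifelse(is_distractor, lure_col, target_col)
  } else {
    n_display <- n_cor
    is_distractor <- rep(FALSE, n_display)
    character <- chars
    display_color <- rep("green", n_display)
  }
  items <- data.frame(
    character = character,
    tablet_id = unname(assignment[character]),
    order_index = seq_len(n_display) - 1L,
    is_distractor = is_distractor,
    display_color = display_color,
    stringsAsFactors = FALSE
  )

  plan <- structure(
    list(level_kind = level_kind, condition = condition, items = items,
         scramble_trigger = NULL, exercise_trigger = NULL,
         target_distance_m = target_distance_m, tolerance_frac = tolerance_frac,
         assignment = assignment),
    class = "r2p_rep_plan"
  )
  if (level_kind == "exercise") {
    # one beep per repetition, uniformly among correct selections 2..11
    plan$exercise_trigger <- sample(1:(n_cor - 2L), 1L)
  }
  if (condition == "scramble") {
    plan$scramble_trigger <- as.integer(scramble_trigger %||% (n_cor %/% 2L - 1L))
    if (plan$scramble_trigger < 0L || plan$scramble_trigger >= n_cor - 1L)
      stop_r2p("scramble_trigger out of range", class = "r2play_config_error")
    plan <- apply_scramble(plan, layout, max_proposals = max_proposals)
  }
  plan
}

#' Mid-trail scramble relocation
#'
#' Implements the scramble condition: after the trigger selection, the
#' remaining characters relocate to different tablet positions. A fresh
#' character-to-tablet bijection is drawn for the post-trigger portion and
#' redrawn until (a) at least one affected item actually moves and (b) the
#' total path distance over correct selections still satisfies the plan's
#' distance window.
#'
#' @param plan a scramble-condition `r2p_rep_plan` with `scramble_trigger` set.
#' @param layout the `r2p_layout` the plan was generated on.
#' @param max_proposals bound on redraws.
#' @return the plan with relocated post-trigger items and, in
#'   `$post_assignment`, the relocated bijection.
#' @export
apply_scramble <- function(plan, layout, max_proposals = 10000L) {
  stopifnot(inherits(plan, "r2p_rep_plan"))
  if (!identical(plan$condition, "scramble") || is.null(plan$scramble_trigger))
    stop_r2p("apply_scramble needs a scramble-condition plan with a trigger",
             class = "r2play_config_error")
  items <- plan$items
  cor_rows <- which(!items$is_distractor)
  trig <- plan$scramble_trigger
  if (trig < 0L || trig >= length(cor_rows) - 1L)
    stop_r2p("scramble_trigger outside the item range", class = "r2play_config_error")
  # display rows at or before the trigger-th (0-based) correct selection stay put
  last_fixed_row <- cor_rows[trig + 1L]
  moving <- seq_len(nrow(items)) > last_fixed_row
  chars_cor <- items$character[cor_rows]
  tol <- plan$target_distance_m * plan$tolerance_frac
  ids <- layout$tablets$tablet_id

  for (i in seq_len(max_proposals)) {
    cand <- stats::setNames(sample(ids, length(CHAR_CYCLE)), CHAR_CYCLE)
    new_tab <- items$tablet_id
    new_tab[moving] <- unname(cand[items$character[moving]])
    if (all(new_tab[moving] == items$tablet_id[moving])) next # must relocate
    path <- c(".start", new_tab[cor_rows])
    # the relocation must not drop a character onto the tablet the
    # participant is currently at (zero-length run segment)
    if (any(path[-1] == path[-length(path)])) next
    d <- sum(layout$dist[cbind(path[-length(path)], path[-1])])
    if (abs(d - plan$target_distance_m) <= tol) {
      plan$items$tablet_id <- new_tab
      plan$post_assignment <- cand
      return(plan)
    }
  }
  stop_r2p("could not satisfy the distance window after scramble relocation",
           class = "r2play_generation_error")
}

#' Build a full assessment protocol
#'
#' Assembles the level/condition/repetition plan: a 2-repetition pre-motor
#' task, the four core levels (number-letter, exercise, go/no-go, Stroop) with
#' 4 repetitions each -- repetition 1 standard, repetitions 2-4 a random
#' permutation of standard, auditory-interference and scramble -- and a
#' 2-repetition post-motor task. Every repetition gets its own
#' distance-standardized trail. Deterministic given `config$seed`.
#'
#' @param config an [protocol_config()]; defaults used when omitted.
#' @return an object of class `r2p_protocol`.
#' @examples
#' prot <- build_protocol(protocol_config(seed = 1))
#' sum(vapply(prot$levels, function(l) length(l$reps), 1L)) # 20 repetitions
#' @export
build_protocol <- function(config = protocol_config()) {
  stopifnot(inherits(config, "r2p_protocol_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  core <- c("number_letter", "exercise", "go_no_go", "stroop")
  levels <- lapply(LEVEL_KINDS, function(lk) {
    conds <- if (lk %in% core) c("standard", sample(CONDITIONS)) else rep("standard", 2L)
    reps <- lapply(seq_along(conds), function(i) {
      plan <- generate_trail(config$layout, lk, conds[i],
                             target_distance_for(config, lk),
                             config$tolerance_frac,
                             scramble_trigger = config$scramble_trigger)
      plan$rep_number <- i
      plan
    })
    list(level_kind = lk, reps = reps)
  })

  structure(
    list(layout = config$layout, levels = levels,
         per_selection_distance_m = config$per_selection_m,
         full_rep_distance_m = config$full_m,
         reduced_rep_distance_m = config$reduced_m,
         motor_rep_distance_m = config$motor_m,
         tolerance_frac = config$tolerance_frac,
         rng_seed = config$seed),
    class = "r2p_protocol"
  )
}

plan_to_list <- function(plan) {
  list(level_kind = plan$level_kind,
       condition = plan$condition,
       rep_number = plan$rep_number %||% NA_integer_,
       target_distance_m = plan$target_distance_m,
       tolerance_frac = plan$tolerance_frac,
       scramble_trigger = plan$scramble_trigger,
       exercise_trigger = plan$exercise_trigger,
       items = plan$items)
}

#' Write / read a protocol plan document
#'
#' The export is a single JSON document (schema `r2play-protocol/1`) holding
#' the layout, distance settings and one object per repetition; it is the
#' interchange format consumed by the simulator and scorer.
#'
#' @param protocol an `r2p_protocol`.
#' @param path output (input) file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol` an
#'   `r2p_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "r2p_protocol"))
  doc <- list(
    schema = "r2play-protocol/1",
    layout = list(tablets = protocol$layout$tablets,
                  start = protocol$layout$start),
    distances = list(per_selection = protocol$per_selection_distance_m,
                     full = protocol$full_rep_distance_m,
                     reduced = protocol$reduced_rep_distance_m,
                     motor = protocol$motor_rep_distance_m,
                     tolerance = protocol$tolerance_frac),
    seed = protocol$rng_seed,
    repetitions = lapply(protocol$levels, function(lv) lapply(lv$reps, plan_to_list))
  )
  doc$repetitions <- do.call(c, doc$repetitions)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(doc$schema, "r2play-protocol/1"))
    stop_r2p("not an r2play-protocol/1 document", class = "r2play_parse_error")
  layout <- tablet_layout(doc$layout$tablets, doc$layout$start)
  reps <- doc$repetitions
  plans <- lapply(seq_len(nrow(reps)), function(i) {
    items <- reps$items[[i]]
    structure(
      list(level_kind = reps$level_kind[i], condition = reps$condition[i],
           items = items,
           scramble_trigger = if (!is.null(reps$scramble_trigger) &&
                                  !is.na(reps$scramble_trigger[i]))
             as.integer(reps$scramble_trigger[i]),
           exercise_trigger = if (!is.null(reps$exercise_trigger) &&
                                  !is.na(reps$exercise_trigger[i]))
             as.integer(reps$exercise_trigger[i]),
           target_distance_m = reps$target_distance_m[i],
           tolerance_frac = reps$tolerance_frac[i],
           rep_number = reps$rep_number[i]),
      class = "r2p_rep_plan")
  })
  kinds <- vapply(plans, `[[`, "", "level_kind")
  levels <- lapply(unique(kinds), function(lk)
    list(level_kind = lk, reps = plans[kinds == lk]))
  structure(
    list(layout = layout, levels = levels,
         per_selection_distance_m = doc$distances$per_selection,
         full_rep_distance_m = doc$distances$full,
         reduced_rep_distance_m = doc$distances$reduced,
         motor_rep_distance_m = doc$distances$motor,
         tolerance_frac = doc$distances$tolerance,
         rng_seed = doc$seed),
    class = "r2p_protocol")
}
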