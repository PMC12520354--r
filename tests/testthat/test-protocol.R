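test_that("a built protocol has the mandated level/condition structure", {
  prot <- build_protocol(protocol_config(seed = 1))

  kinds <- vapply(prot$levels, `[[`, "", "level_kind")
  expect_identical(kinds, c("motor_pre", "number_letter", "exercise",
                            "go_no_go", "stroop", "motor_post"))
  expect_identical(sum(vapply(prot$levels, function(l) length(l$reps), 1L)), 20L)

  for (lv in prot$levels) {
    conds <- vapply(lv$reps, `[[`, "", "condition")
    if (lv$level_kind %in% c("motor_pre", "motor_post")) {
      expect_identical(conds, c("standard", "standard"))
    } else {
      expect_identical(conds[1], "standard")
      expect_setequal(conds[2:4], c("standard", "auditory", "scramble"))
    }
  }
})

test_that("protocol build is deterministic in the seed and varies across seeds", {
  a <- build_protocol(protocol_config(seed = 42))
  b <- build_protocol(protocol_config(seed = 42))
  c <- build_protocol(protocol_config(seed = 43))
  expect_identical(a, b)
  same_items <- mapply(function(la, lc) identical(
    lapply(la$reps, `[[`, "items"), lapply(lc$reps, `[[`, "items")),
    a$levels, c$levels)
  expect_false(all(same_items))
})

test_that("path_distance sums start-to-first plus consecutive segments", {
  lay <- tablet_layout(data.frame(tablet_id = c("A", "B"),
                                  x_m = c(0, 3), y_m = c(0, 0)),
                       start = c(0, 0))
  expect_identical(path_distance(lay, data.frame(tablet_id = character())), 0)
  expect_equal(path_distance(lay, data.frame(tablet_id = c("A", "B"))), 3)
  expect_error(path_distance(lay, data.frame(tablet_id = "Z")),
               class = "r2play_lookup_error")

  # distractors never enter the path
  items <- data.frame(tablet_id = c("A", "B", "A"),
                      is_distractor = c(FALSE, TRUE, FALSE))
  expect_equal(path_distance(lay, items), 0)
})

test_that("generated trails honour the standardized distance windows", {
  lay <- default_layout()
  set.seed(11)
  for (i in 1:25) {
    nl <- generate_trail(lay, "number_letter")
    expect_identical(nrow(nl$items), 12L)
    expect_true(all(!nl$items$is_distractor))
    d <- path_distance(lay, nl$items)
    expect_gte(d, 44.55); expect_lte(d, 45.45)

    gng <- generate_trail(lay, "go_no_go")
    expect_identical(nrow(gng$items), 12L)
    expect_identical(sum(gng$items$is_distractor), 4L)
    expect_identical(sum(!gng$items$is_distractor), 8L)
    d <- path_distance(lay, gng$items)
    expect_gte(d, 29.7); expect_lte(d, 30.3)
  }
})

test_that("colour rules follow the level: go/no-go lures red, Stroop lures green", {
  lay <- default_layout()
  set.seed(2)
  gng <- generate_trail(lay, "go_no_go")
  expect_true(all(gng$items$display_color[gng$items$is_distractor] == "red"))
  expect_true(all(gng$items$display_color[!gng$items$is_distractor] == "green"))
  st <- generate_trail(lay, "stroop")
  expect_true(all(st$items$display_color[st$items$is_distractor] == "green"))
  expect_true(all(st$items$display_color[!st$items$is_distractor] == "red"))
})

test_that("non-distractor items spell repeated alphanumeric cycles", {
  lay <- default_layout()
  set.seed(3)
  for (lk in c("number_letter", "go_no_go", "motor_pre")) {
    plan <- generate_trail(lay, lk)
    chars <- plan$items$character[!plan$items$is_distractor]
    expect_identical(chars, rep_len(c("1", "A", "2", "B", "3", "C"), length(chars)))
  }
})

test_that("scramble relocates post-trigger items while keeping the distance window", {
  lay <- default_layout()
  set.seed(5)
  for (i in 1:10) {
    plan <- generate_trail(lay, "number_letter", "scramble")
    expect_identical(plan$scramble_trigger, 5L)
    cor <- plan$items[!plan$items$is_distractor, ]
    pre <- cor$tablet_id[1:6]
    expect_identical(pre, unname(plan$assignment[cor$character[1:6]]))
    post_expected_old <- unname(plan$assignment[cor$character[7:12]])
    expect_false(all(cor$tablet_id[7:12] == post_expected_old))
    d <- path_distance(lay, plan$items)
    expect_gte(d, 44.55); expect_lte(d, 45.45)
  }
})

test_that("apply_scramble rejects plans without a scramble trigger", {
  lay <- default_layout()
  set.seed(1)
  std <- generate_trail(lay, "number_letter", "standard")
  expect_error(apply_scramble(std, lay), class = "r2play_config_error")
})

test_that("exercise repetitions carry exactly one beep trigger in range", {
  lay <- default_layout()
  set.seed(8)
  for (i in 1:20) {
    plan <- generate_trail(lay, "exercise")
    expect_true(plan$exercise_trigger %in% 1:10)
    nl <- generate_trail(lay, "number_letter")
    expect_null(nl$exercise_trigger)
  }
})

test_that("an unreachable distance target reports the best achieved distance", {
  lay <- tablet_layout(data.frame(tablet_id = paste0("T", 1:6),
                                  x_m = seq(0, 0.5, length.out = 6), y_m = 0),
                       start = c(0, 0))
  expect_error(
    generate_trail(lay, "number_letter", max_proposals = 200L),
    regexp = "best achieved", class = "r2play_generation_error")
})

test_that("layouts with too few tablets are rejected", {
  expect_error(tablet_layout(data.frame(tablet_id = "A", x_m = 0, y_m = 0)),
               class = "r2play_config_error")
  expect_error(protocol_config(tolerance_frac = 0.5),
               class = "r2play_config_error")
})

test_that("protocol documents round-trip through JSON", {
  prot <- build_protocol(protocol_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol(prot, path)
  back <- read_protocol(path)
  expect_identical(vapply(back$levels, `[[`, "", "level_kind"),
                   vapply(prot$levels, `[[`, "", "level_kind"))
  for (i in seq_along(prot$levels)) {
    for (j in seq_along(prot$levels[[i]]$reps)) {
      a <- prot$levels[[i]]$reps[[j]]; b <- back$levels[[i]]$reps[[j]]
      expect_equal(b$items$tablet_id, a$items$tablet_id)
      expect_equal(b$condition, a$condition)
      expect_equal(b$scramble_trigger, a$scramble_trigger)
    }
  }
})

test_that("config files set layout, distances and seed", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "distances:",
    "  per_selection: 3.75",
    "  tolerance: 0.02"), cfg_path)
  cfg <- read_protocol_config(cfg_path)
  expect_identical(cfg$seed, 5L)
  expect_equal(cfg$tolerance_frac, 0.02)
  expect_equal(cfg$full_m, 45)
})
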