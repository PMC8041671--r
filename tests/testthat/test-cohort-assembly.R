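test_that("training time rescales elapsed training to the five-year scale", {
  s <- as.Date("2013-09-01")
  e <- as.Date("2019-09-01")  # a six-year (part-time) program
  expect_equal(training_time(s, s, e), 0)
  expect_equal(training_time(e, s, e), 5)
  expect_equal(training_time(s + as.numeric(e - s) / 2, s, e), 2.5,
               tolerance = 1e-3)
  expect_error(training_time(s, e, s), "after")
  expect_true(is.na(training_time(s, as.Date(NA), e)))
})

test_that("test difficulty is the mean item P value minus one half", {
  expect_equal(drpt_difficulty(c(0.59, 0.64, 0.69)), 0.14)
  expect_equal(drpt_difficulty(rep(0.5, 4)), 0)
  expect_equal(drpt_difficulty(rep(1, 3)), 0.5)
  expect_error(drpt_difficulty(numeric()), "non-empty")
  expect_error(drpt_difficulty(c(0.4, 1.2)), "\\[0, 1\\]")
})

test_that("question selection applies the three criteria with strict coverage", {
  q <- tibble::tibble(
    question_id = paste0("q", 1:5),
    format = "multiple_choice", subdomain = "general", p_value = 0.6,
    requires_diagnosis = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    single_ct = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    n_slices_x = NA_integer_, n_slices_y = NA_integer_,
    n_slices_z = 100L)
  r <- tibble::tibble(
    question_id = paste0("q", 1:5), axis = "z",
    lo = c(1L, 1L, 1L, 1L, 20L),
    hi = c(10L, 60L, 10L, 10L, 30L))  # q2 covers 0.6 of the stack
  cohort <- structure(list(
    residents = toy_cohort()$residents, drpts = toy_cohort()$drpts,
    questions = q, regions = r,
    answers = toy_cohort()$answers[0, ]), class = "cohort_tables")
  kept <- select_questions(cohort)
  expect_equal(kept$question_id, c("q4", "q5"))
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["non_single_ct"]), 1L)
  expect_equal(unname(rej["no_diagnosis"]), 1L)
  expect_equal(unname(rej["volume_not_below_half"]), 1L)

  # coverage of exactly one half is rejected (strictly less than 50%)
  cohort$regions$hi[4] <- 50L
  cohort$regions$lo[4] <- 1L
  expect_equal(select_questions(cohort)$question_id, "q5")

  # missing region metadata flags the question instead of dropping silently
  cohort$regions <- cohort$regions[cohort$regions$question_id != "q5", ]
  cohort$questions$n_slices_z[5] <- NA_integer_
  kept2 <- select_questions(cohort)
  expect_true("q5" %in% attr(kept2, "flagged"))
})

test_that("aggregation averages available questions and counts accuracy", {
  cohort <- toy_cohort()
  metrics <- tibble::tibble(
    resident_id = c("r1", "r1", "r2", "r2"),
    drpt_id = "t1",
    question_id = c("q1", "q2", "q1", "q2"),
    perc_time_full_runs = c(20, 40, 10, NA),
    perc_time_rel_area = c(50, 70, 30, NA),
    total_time_ms = 1000L,
    correct = c(1L, 0L, 1L, 1L))
  rec <- aggregate_to_drpt(metrics, cohort)
  r1 <- rec[rec$resident_id == "r1", ]
  expect_equal(r1$perc_time_full_runs_avg, 30)
  expect_equal(r1$perc_time_rel_area_avg, 60)
  expect_equal(r1$n_correct, 1L)
  expect_equal(r1$n_questions, 2L)
  # missing logfile handled listwise: r2 averages over the remaining question
  r2 <- rec[rec$resident_id == "r2", ]
  expect_equal(r2$perc_time_full_runs_avg, 10)
  expect_equal(r2$n_questions, 2L)  # the answer still counts for accuracy
  # test difficulty: mean P of the questions entering accuracy, minus 0.5
  expect_equal(unique(rec$drpt_diff), mean(c(0.6, 0.8)) - 0.5)
  # training time from the roster
  expect_equal(r1$tr_time,
               training_time(cohort$drpts$date, cohort$residents$start_date[1],
                             cohort$residents$end_date[1]))
})

test_that("excluded formats leave scroll averages but not accuracy counts", {
  cohort <- toy_cohort()  # q2 is a marker question
  metrics <- tibble::tibble(
    resident_id = "r1", drpt_id = "t1",
    question_id = c("q1", "q2"),
    perc_time_full_runs = c(20, 40),
    perc_time_rel_area = c(50, 70),
    total_time_ms = 1000L, correct = c(1L, 1L))
  rec <- aggregate_to_drpt(metrics, cohort, exclude_formats = "marker")
  expect_equal(rec$perc_time_full_runs_avg, 30)  # marker still averaged
  expect_equal(rec$n_questions, 1L)              # but not counted
  expect_equal(rec$n_correct, 1L)
  expect_equal(rec$drpt_diff, 0.6 - 0.5)         # difficulty without marker
})

test_that("aggregation is invariant to question order and warns on exclusions", {
  cohort <- toy_cohort()
  metrics <- tibble::tibble(
    resident_id = rep(c("r1", "r2"), each = 2),
    drpt_id = "t1",
    question_id = rep(c("q1", "q2"), 2),
    perc_time_full_runs = c(20, 40, 15, 25),
    perc_time_rel_area = c(50, 70, 45, 55),
    total_time_ms = 1000L,
    correct = c(1L, 0L, 1L, 1L))
  rec1 <- aggregate_to_drpt(metrics, cohort)
  rec2 <- aggregate_to_drpt(metrics[sample(4), ], cohort)
  expect_equal(rec1, rec2)

  cohort$residents$start_date[2] <- NA
  expect_warning(rec3 <- aggregate_to_drpt(metrics, cohort),
                 "without enrolment date")
  expect_false("r2" %in% rec3$resident_id)
})

test_that("training time strictly increases over a resident's successive tests", {
  rec <- simulate_cohort(cohort_params(n_residents = 40, seed = 5))
  for (rid in unique(rec$resident_id)) {
    tt <- rec$tr_time[rec$resident_id == rid]
    if (length(tt) > 1) expect_true(all(diff(tt) > 0))
  }
})
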