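test_that("generated trajectories are valid logs and reproducible by seed", {
  for (s in 1:10) {
    tp <- trajectory_params(n_slices = c(z = sample(10:60, 1)),
                            mean_question_time_ms = 60000,
                            sd_question_time_ms = 30000, seed = s)
    log <- simulate_trajectory(tp)
    expect_silent(validate_log(log, tp$geometry))
    expect_equal(log$events$time_ms[1], 0L)
    log2 <- simulate_trajectory(tp)
    expect_identical(log$events, log2$events)  # bit-reproducible per seed
  }
})

test_that("pipeline metrics recover low-noise targets within two points", {
  for (s in 1:8) {
    tp <- trajectory_params(
      n_slices = c(z = 40), target_perc_full_runs = 20,
      target_perc_rel_area = 50, noise_sd = c(full_runs = 0.2,
                                              rel_area = 0.2),
      mean_question_time_ms = 90000, sd_question_time_ms = 40000, seed = s)
    log <- simulate_trajectory(tp)
    got_f <- perc_time_full_runs(log, tp$geometry)$perc_time_full_runs
    got_r <- time_in_relevant_area(log, tp$relevant)$perc_time_rel_area
    expect_lt(abs(got_f - 20), 2)
    expect_lt(abs(got_r - 50), 2)
    truth <- attr(log, "truth")
    expect_lt(abs(got_f - truth$perc_time_full_runs), 0.5)
    expect_lt(abs(got_r - truth$perc_time_rel_area), 0.5)
  }
})

test_that("a whole-stack region with maximal targets is recovered exactly", {
  tp <- trajectory_params(
    n_slices = c(z = 40),
    relevant = relevant_region(data.frame(axis = "z", lo = 1, hi = 40)),
    target_perc_full_runs = 100, target_perc_rel_area = 100,
    noise_sd = c(full_runs = 0, rel_area = 0),
    mean_question_time_ms = 60000, sd_question_time_ms = 0, seed = 1)
  log <- simulate_trajectory(tp)
  # the full-run target is capped at 90% of question time by construction;
  # with the whole stack relevant the relevance dwell is complete
  expect_gte(perc_time_full_runs(log, tp$geometry)$perc_time_full_runs, 89)
  expect_equal(time_in_relevant_area(log, tp$relevant)$perc_time_rel_area,
               100)
})

test_that("incompatible target pairs raise an infeasibility error", {
  # heavy full runs sweep through the relevant half repeatedly: relevance
  # cannot stay near zero
  tp <- trajectory_params(
    n_slices = c(z = 40),
    relevant = relevant_region(data.frame(axis = "z", lo = 1, hi = 20)),
    target_perc_full_runs = 80, target_perc_rel_area = 2,
    noise_sd = c(full_runs = 0, rel_area = 0),
    mean_question_time_ms = 60000, sd_question_time_ms = 0, seed = 1)
  expect_error(simulate_trajectory(tp), "infeasible")
  # relevance plus full runs exceeding the available time
  tp2 <- trajectory_params(
    n_slices = c(z = 40),
    relevant = relevant_region(data.frame(axis = "z", lo = 19, hi = 22)),
    target_perc_full_runs = 80, target_perc_rel_area = 90,
    noise_sd = c(full_runs = 0, rel_area = 0),
    mean_question_time_ms = 60000, sd_question_time_ms = 0, seed = 1)
  expect_error(simulate_trajectory(tp2), "infeasible")
})

test_that("macro cohorts have the documented panel structure", {
  rec <- simulate_cohort(cohort_params(seed = 31))
  per_res <- table(rec$resident_id)
  expect_true(all(per_res >= 1 & per_res <= 9))
  expect_gt(mean(per_res), 3.5)
  expect_lt(mean(per_res), 4.7)
  expect_true(all(rec$tr_time > 0 & rec$tr_time <= 5))
  expect_true(all(rec$drpt_diff >= 0.02 & rec$drpt_diff <= 0.24))
  expect_true(all(rec$n_questions >= 2 & rec$n_questions <= 9))
  expect_true(all(rec$n_correct >= 0 & rec$n_correct <= rec$n_questions))
  # consecutive attendance: attended tests form one block per resident
  ids <- as.integer(sub("T", "", rec$drpt_id))
  for (rid in sample(unique(rec$resident_id), 50)) {
    tests <- sort(ids[rec$resident_id == rid])
    expect_true(all(diff(tests) == 1))
  }
})

test_that("zero variance components and slopes give constant outcomes", {
  rec <- simulate_cohort(cohort_params(
    n_residents = 20, seed = 32,
    fullruns = list(b0 = 18, b_tr = 0, b_diff = 0, sigma2_e = 0,
                    sigma2_u0 = 0),
    relarea = list(b0 = 52, b_tr = 0, b_diff = 0, sigma2_e = 0,
                   sigma2_u0 = 0)))
  expect_true(all(rec$perc_time_full_runs_avg == 18))
  expect_true(all(rec$perc_time_rel_area_avg == 52))
})

test_that("simulated scroll metrics trend with training time as expected", {
  rec <- simulate_cohort(cohort_params(seed = 33))
  full_slope <- coef(lm(perc_time_full_runs_avg ~ tr_time, rec))[2]
  rel_slope <- coef(lm(perc_time_rel_area_avg ~ tr_time, rec))[2]
  expect_lt(full_slope, 0)
  expect_gt(rel_slope, 0)
})

test_that("micro cohorts build quickly and survive missing logfiles", {
  cp <- cohort_params(n_residents = 5, n_drpts = 2, seed = 34)
  tpar <- trajectory_params(mean_question_time_ms = 30000,
                            sd_question_time_ms = 10000,
                            osc_period_ms = 1000)
  t0 <- Sys.time()
  mic <- simulate_micro_cohort(cp, trajectory = tpar)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(length(mic$logs), nrow(mic$cohort$answers))
  for (log in mic$logs[1:5]) {
    expect_silent(validate_log(
      log, question_geometry(mic$cohort, log$question_id)))
  }
  # write to disk and run from files
  dir <- withr::local_tempdir()
  simulate_micro_cohort(cp, trajectory = tpar, dir = dir)
  # deleting a few random logfiles leaves aggregation functional
  files <- list.files(dir, pattern = "log\\.csv$", full.names = TRUE)
  set.seed(1)
  file.remove(sample(files, min(9, length(files) - 5)))
  out <- suppressWarnings(
    run_pipeline(dir, dir, exclude_formats = "marker"))
  expect_true(nrow(out$records) > 0)
  expect_true(all(out$records$perc_time_full_runs_avg >= 0 &
                    out$records$perc_time_full_runs_avg <= 100,
                  na.rm = TRUE))
})
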