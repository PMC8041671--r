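make_log <- function(times, slices, end, axes = "z") {
  ev <- data.frame(time_ms = times, axis = axes, slice_index = slices,
                   event_kind = "scroll")
  question_log("r", "t", "q", ev, question_end_ms = end)
}

test_that("axis episodes are maximal single-axis stretches partitioning time", {
  log <- make_log(c(0, 100, 200), c(5, 10, 15), 400)
  expect_length(axis_episodes(log), 1L)

  ev <- data.frame(time_ms = c(0, 100, 200, 300),
                   axis = c("z", "x", "x", "z"),
                   slice_index = c(5L, 3L, 8L, 6L),
                   event_kind = c("scroll", "axis_change", "scroll",
                                  "axis_change"))
  log3 <- question_log("r", "t", "q", ev, question_end_ms = 500)
  eps <- axis_episodes(log3)
  expect_length(eps, 3L)
  expect_equal(vapply(eps, attr, "", "axis"), c("z", "x", "z"))
  starts <- vapply(eps, attr, numeric(1), "t_start_ms")
  ends <- vapply(eps, attr, numeric(1), "t_end_ms")
  expect_equal(starts, c(0, 100, 300))
  expect_equal(ends, c(100, 300, 500))   # spans partition [0, end]
})

test_that("extrema are the endpoints plus direction reversals, plateaus collapsed", {
  ep <- function(s, t = seq_along(s) * 100 - 100) {
    structure(data.frame(time_ms = t, slice_index = s), axis = "z")
  }
  expect_equal(find_extrema(ep(c(10, 20, 30)))$slice_index, c(10, 30))
  expect_equal(find_extrema(ep(c(10, 80, 20)))$slice_index, c(10, 80, 20))
  # stationary episode: a single extremum at the plateau's first timestamp
  ex <- find_extrema(ep(c(5, 5, 5)))
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$time_ms, 0)
  # plateau inside a sweep creates no spurious extremum
  expect_equal(find_extrema(ep(c(10, 20, 20, 30)))$slice_index, c(10, 30))
})

test_that("runs span consecutive extrema with a strict >50% full threshold", {
  ep <- structure(data.frame(time_ms = c(0, 2000, 3000),
                             slice_index = c(10L, 80L, 20L)), axis = "z")
  runs <- segment_runs(ep, 100)
  expect_equal(runs$delta_slices, c(70, 60))
  expect_true(all(runs$is_full))
  expect_equal(runs$t_end_ms - runs$t_start_ms, c(2000, 1000))

  # a single 1 -> 100 sweep is one full run covering its whole duration
  sweep <- structure(data.frame(time_ms = c(0, 4000),
                                slice_index = c(1L, 100L)), axis = "z")
  r <- segment_runs(sweep, 100)
  expect_equal(nrow(r), 1L)
  expect_equal(r$delta_slices, 99)
  expect_true(r$is_full)

  # exactly half the stack is NOT a full run ("more than 50%")
  half <- structure(data.frame(time_ms = c(0, 1000),
                               slice_index = c(25L, 75L)), axis = "z")
  expect_false(segment_runs(half, 100)$is_full)
  expect_true(segment_runs(half, 99)$is_full)

  # small oscillation: never full
  osc <- structure(data.frame(time_ms = seq(0, 900, 100),
                              slice_index = rep(c(40L, 45L), 5)), axis = "z")
  expect_false(any(segment_runs(osc, 100)$is_full))
})

test_that("perc_time_full_runs relates full-run time to total question time", {
  g <- volume_geometry(c(z = 100))
  # one sweep occupying the whole question
  log <- make_log(c(0, 4000), c(1, 100), 4000)
  expect_equal(perc_time_full_runs(log, g)$perc_time_full_runs, 100)
  # no full runs at all
  log0 <- make_log(c(0, 1000), c(40, 45), 4000)
  expect_equal(perc_time_full_runs(log0, g)$perc_time_full_runs, 0)
  # 1000 ms sweep inside a 4000 ms question, stationary remainder
  log25 <- make_log(c(0, 1000), c(1, 100), 4000)
  p <- perc_time_full_runs(log25, g)
  expect_equal(p$perc_time_full_runs, 25)
  expect_equal(p$full_run_time_ms, 1000)
  expect_error(perc_time_full_runs(make_log(0, 1, 0), g), "zero")
})

test_that("the fixed-axis threshold option compares all runs to one slice count", {
  ev <- data.frame(time_ms = c(0, 1000), axis = "x",
                   slice_index = c(1L, 20L), event_kind = "scroll")
  log <- question_log("r", "t", "q", ev, 1000)
  g <- volume_geometry(c(x = 20, z = 100))
  expect_equal(perc_time_full_runs(log, g)$perc_time_full_runs, 100)
  expect_equal(perc_time_full_runs(log, g,
                                   threshold_axis = "z")$perc_time_full_runs,
               0)  # 19 slices is not >50 on the axial count
})

test_that("segmentation agrees with the brute-force reversal scan", {
  set.seed(101)
  for (i in 1:200) {
    rl <- random_log()
    ep <- axis_episodes(rl$log)[[1]]
    n_ax <- rl$geometry[[attr(ep, "axis")]]
    got <- segment_runs(ep, n_ax)
    want <- oracle_runs(ep$time_ms, ep$slice_index, n_ax)
    expect_equal(got$delta_slices, want$delta_slices)
    expect_equal(got$t_start_ms, want$t_start_ms)
    expect_equal(got$t_end_ms, want$t_end_ms)
    expect_equal(got$is_full, want$is_full)
  }
})

test_that("run durations tile each episode up to its stationary tail", {
  set.seed(102)
  for (i in 1:100) {
    rl <- random_log(axes = sample(list("z", c("x", "z")), 1)[[1]])
    prof <- perc_time_full_runs(rl$log, rl$geometry)
    eps <- axis_episodes(rl$log)
    run_total <- 0
    span_total <- 0
    for (ep in eps) {
      ex <- find_extrema(ep)
      runs <- prof$runs[prof$runs$t_start_ms >= attr(ep, "t_start_ms") &
                          prof$runs$t_end_ms <= attr(ep, "t_end_ms") &
                          prof$runs$axis == attr(ep, "axis"), ]
      if (nrow(runs) > 0) {
        # contiguous: each run starts where the previous ended
        expect_equal(runs$t_start_ms[-1], runs$t_end_ms[-nrow(runs)])
        expect_equal(runs$t_start_ms[1], ex$time_ms[1])
      }
      run_total <- run_total + sum(runs$t_end_ms - runs$t_start_ms)
      span_total <- span_total +
        (ex$time_ms[nrow(ex)] - ex$time_ms[1])
    }
    expect_equal(run_total, span_total)
    expect_gte(prof$total_time_ms, run_total)
    expect_true(prof$perc_time_full_runs >= 0 &&
                  prof$perc_time_full_runs <= 100)
  }
})

test_that("appending a full sweep in stationary tail time never lowers the metric", {
  set.seed(103)
  for (i in 1:50) {
    rl <- random_log(end_pad = 5000)
    g <- rl$geometry
    before <- perc_time_full_runs(rl$log, g)$perc_time_full_runs
    ev <- rl$log$events
    t_last <- max(ev$time_ms)
    n <- g[["z"]]
    sweep <- data.frame(
      time_ms = c(t_last + 1000, t_last + 3000),
      axis = "z", slice_index = c(1L, n), event_kind = "scroll")
    log2 <- question_log("r", "t", "q", rbind(ev, sweep),
                         question_end_ms = rl$log$question_end_ms)
    after <- perc_time_full_runs(log2, g)$perc_time_full_runs
    expect_gte(after, before)
  }
})

test_that("uniform time scaling leaves the percentage unchanged", {
  set.seed(104)
  for (i in 1:50) {
    rl <- random_log()
    g <- rl$geometry
    p1 <- perc_time_full_runs(rl$log, g)$perc_time_full_runs
    ev <- rl$log$events
    ev$time_ms <- ev$time_ms * 3L
    log2 <- question_log("r", "t", "q", ev,
                         question_end_ms = rl$log$question_end_ms * 3L)
    expect_equal(perc_time_full_runs(log2, g)$perc_time_full_runs, p1)
  }
})
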