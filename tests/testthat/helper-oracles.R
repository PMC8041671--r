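# Brute-force reference implementations, deliberately naive and
# independent of the package's vectorised code paths.

# scans every index of the (plateau-collapsed) slice sequence for a
# direction reversal; returns runs between consecutive extrema
oracle_runs <- function(times, slices, n_slices) {
  keep <- rep(TRUE, length(slices))
  for (i in seq_along(slices)[-1]) {
    if (slices[i] == slices[i - 1]) keep[i] <- FALSE
  }
  t <- times[keep]
  s <- slices[keep]
  if (length(s) < 2) {
    return(data.frame(t_start_ms = integer(), t_end_ms = integer(),
                      delta_slices = integer(), is_full = logical()))
  }
  ext <- 1L
  if (length(s) > 2) {
    for (i in 2:(length(s) - 1)) {
      up_then_down <- s[i] > s[i - 1] && s[i] > s[i + 1]
      down_then_up <- s[i] < s[i - 1] && s[i] < s[i + 1]
      if (up_then_down || down_then_up) ext <- c(ext, i)
    }
  }
  ext <- c(ext, length(s))
  out <- NULL
  for (k in seq_len(length(ext) - 1)) {
    a <- ext[k]; b <- ext[k + 1]
    delta <- abs(s[b] - s[a])
    out <- rbind(out, data.frame(
      t_start_ms = t[a], t_end_ms = t[b], delta_slices = delta,
      is_full = delta > 0.5 * n_slices))
  }
  out
}

# per-millisecond accumulator: for every whole millisecond of the
# question, look up the latest display event at or before it and test
# slice membership against the region of the displayed axis
oracle_relevant_ms <- function(log, region) {
  ev <- log$events[log$events$event_kind != "other", , drop = FALSE]
  ms <- seq(0L, log$question_end_ms - 1L)
  state <- findInterval(ms, ev$time_ms)
  rel_by_event <- vapply(seq_len(nrow(ev)), function(i) {
    slice_in_region(region, ev$axis[i], ev$slice_index[i])
  }, logical(1))
  sum(rel_by_event[state])
}

# random piecewise-constant trajectory over one or more axes
random_log <- function(n_events = sample(2:50, 1), n_slices = NULL,
                       axes = "z", end_pad = sample(0:2000, 1),
                       with_other = FALSE) {
  if (is.null(n_slices)) {
    n_slices <- setNames(sample(4:30, length(axes), replace = TRUE), axes)
  }
  times <- sort(sample(0:20000, n_events))
  times <- times - times[1]
  ax <- sample(axes, n_events, replace = TRUE)
  ev <- data.frame(
    time_ms = times,
    axis = ax,
    slice_index = vapply(ax, function(a) sample.int(n_slices[[a]], 1),
                         integer(1)),
    event_kind = "scroll")
  if (with_other && n_events > 2) {
    k <- sample(1:3, 1)
    other <- data.frame(
      time_ms = sample(0:max(times), k, replace = TRUE),
      axis = sample(axes, k, replace = TRUE),
      slice_index = 1L,
      event_kind = "other")
    ev <- rbind(ev, other)
  }
  list(log = question_log("r1", "t1", "q1", ev,
                          question_end_ms = max(times) + end_pad + 1L),
       geometry = volume_geometry(n_slices))
}

# random region over the axes of a geometry (possibly empty per axis)
random_region <- function(geometry) {
  rows <- lapply(names(geometry), function(ax) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    lo <- sort(sample.int(geometry[[ax]], k))
    hi <- pmin(lo + sample(0:5, k, replace = TRUE), geometry[[ax]])
    data.frame(axis = ax, lo = lo, hi = hi)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(axis = character(), lo = integer(), hi = integer())
  }
  relevant_region(rows, axes = names(geometry))
}

# minimal in-memory cohort fixture: 2 residents x 1 test x 2 questions
toy_cohort <- function() {
  structure(list(
    residents = tibble::tibble(
      resident_id = c("r1", "r2"),
      start_date = as.Date(c("2013-01-01", "2014-01-01")),
      end_date = as.Date(c("2018-01-01", "2019-01-01"))),
    drpts = tibble::tibble(drpt_id = "t1", date = as.Date("2015-06-01")),
    questions = tibble::tibble(
      question_id = c("q1", "q2"),
      format = c("multiple_choice", "marker"),
      subdomain = "general",
      p_value = c(0.6, 0.8),
      requires_diagnosis = TRUE, single_ct = TRUE,
      n_slices_x = NA_integer_, n_slices_y = NA_integer_,
      n_slices_z = c(100L, 50L)),
    regions = tibble::tibble(question_id = c("q1", "q2"), axis = "z",
                             lo = c(30L, 10L), hi = c(40L, 14L)),
    answers = tibble::tibble(
      resident_id = rep(c("r1", "r2"), each = 2),
      drpt_id = "t1",
      question_id = rep(c("q1", "q2"), 2),
      correct = c(1L, 0L, 1L, 1L))),
    class = "cohort_tables")
}
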