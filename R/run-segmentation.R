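#' Split a log into single-axis viewing episodes
#'
#' A run is defined on the slice numbers of one axis, so the trajectory is
#' first cut into maximal contiguous stretches of display events sharing
#' one axis. Episode `k` spans from its first event to the first event of
#' episode `k + 1` (the final episode closes at `question_end_ms`), so
#' episode time spans partition `[0, question_end_ms]`.
#'
#' @param log A [question_log()].
#' @return List of episodes; each is a data frame with `time_ms` and
#'   `slice_index`, plus attributes `axis`, `t_start_ms`, `t_end_ms`.
#' @export
axis_episodes <- function(log) {
  ev <- log$events[log$events$event_kind != "other", , drop = FALSE]
  breaks <- c(TRUE, ev$axis[-1] != ev$axis[-nrow(ev)])
  grp <- cumsum(breaks)
  starts <- ev$time_ms[breaks]
  ends <- c(starts[-1], log$question_end_ms)
  lapply(seq_len(max(grp)), function(k) {
    e <- ev[grp == k, c("time_ms", "slice_index"), drop = FALSE]
    rownames(e) <- NULL
    structure(e, axis = ev$axis[breaks][k],
              t_start_ms = starts[k], t_end_ms = ends[k])
  })
}

#' Local extrema of an episode's slice trajectory
#'
#' Plateaus (consecutive repeats of a slice value) are collapsed to a
#' single candidate at the plateau's first timestamp before reversal
#' detection, so sampled piecewise-constant logs do not produce spurious
#' extrema. The first and last displayed positions are always extrema;
#' interior extrema are direction reversals of the slice sequence. A
#' stationary episode yields a single extremum.
#'
#' @param episode One element of [axis_episodes()].
#' @return Data frame with `time_ms` and `slice_index` of the extrema, in
#'   time order.
#' @export
find_extrema <- function(episode) {
  t <- episode$time_ms
  s <- episode$slice_index
  if (length(s) == 0) stop("empty episode", call. = FALSE)
  keep <- c(TRUE, s[-1] != s[-length(s)])   # plateau -> first timestamp
  t <- t[keep]; s <- s[keep]
  n <- length(s)
  if (n <= 2) {
    return(data.frame(time_ms = t, slice_index = s))
  }
  d <- diff(s)
  reversal <- d[-length(d)] * d[-1] < 0
  idx <- c(1L, which(reversal) + 1L, n)
  data.frame(time_ms = t[idx], slice_index = s[idx])
}

#' Segment an episode into runs between consecutive extrema
#'
#' Run `k` spans extrema `k` and `k + 1`: it starts at the earlier
#' extremum's timestamp and ends at the later one's, so run durations tile
#' the span between the first and last extremum without overlap. A run is
#' a *full run* when its slice distance exceeds half the slice count of
#' the episode's axis (strictly: `delta_slices > 0.5 * n_slices_axis`, so
#' a traversal of exactly half the stack is not full). Time after the last
#' extremum (stationary tail) belongs to no run.
#'
#' @param episode One element of [axis_episodes()].
#' @param n_slices_axis Slice count of the episode's axis.
#' @return Data frame of runs: `axis`, `t_start_ms`, `t_end_ms`,
#'   `slice_start`, `slice_end`, `delta_slices`, `is_full`. Zero rows for a
#'   stationary episode.
#' @export
segment_runs <- function(episode, n_slices_axis) {
  ex <- find_extrema(episode)
  k <- nrow(ex)
  if (k < 2) {
    return(data.frame(axis = character(), t_start_ms = integer(),
                      t_end_ms = integer(), slice_start = integer(),
                      slice_end = integer(), delta_slices = integer(),
                      is_full = logical()))
  }
  delta <- abs(diff(ex$slice_index))
  data.frame(
    axis = attr(episode, "axis"),
    t_start_ms = ex$time_ms[-k],
    t_end_ms = ex$time_ms[-1],
    slice_start = ex$slice_index[-k],
    slice_end = ex$slice_index[-1],
    delta_slices = delta,
    is_full = delta > 0.5 * n_slices_axis)
}

#' Percentage of question time spent on full runs
#'
#' Segments every axis episode of the log into runs and relates the summed
#' duration of full runs (traversals of more than 50% of the active axis's
#' slices) to the total time spent on the question:
#' `100 * full_run_time_ms / total_time_ms`. The full-run threshold is
#' evaluated against the slice count of each episode's own axis by
#' default; set `threshold_axis` to compare every run against one fixed
#' axis's slice count instead.
#'
#' @param log A [question_log()].
#' @param geometry A [volume_geometry()].
#' @param threshold_axis `NULL` (default: each episode's own axis) or a
#'   single axis name whose slice count defines the 50% threshold for all
#'   runs.
#' @return A `run_profile`: list with `runs` (all runs across episodes),
#'   `total_time_ms`, `full_run_time_ms`, `n_full_runs`,
#'   `perc_time_full_runs` in `[0, 100]`.
#' @examples
#' ev <- data.frame(time_ms = c(0, 1000), axis = "z",
#'                  slice_index = c(1, 100), event_kind = "scroll")
#' log <- question_log("r", "t", "q", ev, question_end_ms = 4000)
#' perc_time_full_runs(log, volume_geometry(c(z = 100)))$perc_time_full_runs
#' @export
perc_time_full_runs <- function(log, geometry, threshold_axis = NULL) {
  validate_log(log, geometry)
  total <- total_time_ms(log)
  if (total <= 0) {
    stop("total question time is zero; percentage undefined", call. = FALSE)
  }
  if (!is.null(threshold_axis) &&
      !threshold_axis %in% viewable_axes(geometry)) {
    stop("`threshold_axis` must be a viewable axis", call. = FALSE)
  }
  runs <- do.call(rbind, lapply(axis_episodes(log), function(ep) {
    n_ax <- geometry[[threshold_axis %||% attr(ep, "axis")]]
    segment_runs(ep, n_ax)
  }))
  full_ms <- sum(runs$t_end_ms[runs$is_full] - runs$t_start_ms[runs$is_full])
  structure(
    list(runs = runs,
         total_time_ms = total,
         full_run_time_ms = full_ms,
         n_full_runs = sum(runs$is_full),
         perc_time_full_runs = 100 * full_ms / total),
    class = "run_profile")
}

#' @exportS3Method base::print
print.run_profile <- function(x, ...) {
  cat(sprintf("<run_profile> %d runs (%d full); %.1f%% of %d ms on full runs\n",
              nrow(x$runs), x$n_full_runs, x$perc_time_full_runs,
              x$total_time_ms))
  invisible(x)
}
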