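#' A per-question scroll log
#'
#' The raw event stream recorded while one resident answered one volumetric
#' question: at each time-stamped event the viewer displayed a given slice
#' of a given axis. The displayed state is piecewise constant — the
#' `(axis, slice)` shown at time `t` is that of the latest event at or
#' before `t`, holding until the next event or `question_end_ms`.
#'
#' Events of kind `"other"` (pan, zoom, window-level changes) are retained
#' verbatim but carry no slice semantics: they never alter the displayed
#' state and are ignored by all metrics.
#'
#' Normalisation (applied on construction unless `normalize = FALSE`):
#' times are shifted so the first event is at 0 ms; simultaneous
#' display events (kinds `"scroll"`/`"axis_change"`) are collapsed keeping
#' the last, because the displayed state is single-valued; an `"other"`
#' event that coincides with a display event is dropped. Normalisation is
#' idempotent.
#'
#' @param resident_id,drpt_id,question_id Identifiers (coerced to character).
#' @param events Data frame with columns `time_ms` (non-negative integer
#'   milliseconds), `axis` (`"x"`, `"y"` or `"z"`), `slice_index` (1-based
#'   integer), `event_kind` (`"scroll"`, `"axis_change"` or `"other"`).
#' @param question_end_ms Time at which the question was left; must be at
#'   least the last event time.
#' @param normalize Apply normalisation (default `TRUE`).
#' @return A `question_log` object.
#' @examples
#' ev <- data.frame(time_ms = c(0, 500), axis = "z", slice_index = c(10, 12),
#'                  event_kind = "scroll")
#' question_log("r1", "t1", "q1", ev, question_end_ms = 1000)
#' @export
question_log <- function(resident_id, drpt_id, question_id, events,
                         question_end_ms, normalize = TRUE) {
  stopifnot(is.data.frame(events))
  req <- c("time_ms", "axis", "slice_index", "event_kind")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0) {
    stop("events lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) == 0) {
    stop("a question log needs at least one event (the initial display state)",
         call. = FALSE)
  }
  events <- events[req]
  events$time_ms <- as.integer(events$time_ms)
  events$axis <- as.character(events$axis)
  events$slice_index <- as.integer(events$slice_index)
  events$event_kind <- as.character(events$event_kind)

  if (any(is.na(events$time_ms)) || any(events$time_ms < 0L)) {
    stop("event times must be non-negative integers", call. = FALSE)
  }
  bad <- which(!events$axis %in% AXES)
  if (length(bad) > 0) {
    stop(sprintf("invalid axis '%s' in event row %d", events$axis[bad[1]],
                 bad[1]), call. = FALSE)
  }
  bad <- which(is.na(events$slice_index) | events$slice_index < 1L)
  if (length(bad) > 0) {
    stop(sprintf("invalid slice index in event row %d", bad[1]), call. = FALSE)
  }
  bad <- which(!events$event_kind %in% EVENT_KINDS)
  if (length(bad) > 0) {
    stop(sprintf("invalid event kind '%s' in event row %d",
                 events$event_kind[bad[1]], bad[1]), call. = FALSE)
  }
  if (normalize) {
    events <- normalize_events(events)
  } else if (is.unsorted(events$time_ms, strictly = TRUE)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  display <- events$event_kind != "other"
  if (!any(display)) {
    stop("a question log needs at least one display (scroll/axis_change) event",
         call. = FALSE)
  }
  if (events$time_ms[which(display)[1]] != 0L) {
    stop("the first display event must be at time 0 (initial state)",
         call. = FALSE)
  }
  question_end_ms <- as.integer(question_end_ms)
  if (is.na(question_end_ms) || question_end_ms < max(events$time_ms)) {
    stop("`question_end_ms` must be >= the last event time", call. = FALSE)
  }
  structure(
    list(resident_id = as.character(resident_id),
         drpt_id = as.character(drpt_id),
         question_id = as.character(question_id),
         events = events,
         question_end_ms = question_end_ms),
    class = "question_log")
}

# shift to t0 = 0, stable-sort by time, resolve simultaneous events:
# at a tied timestamp the last display event wins; "other" events at a
# display event's timestamp are dropped (they carry no state anyway)
normalize_events <- function(events) {
  events$time_ms <- events$time_ms - min(events$time_ms)
  ord <- order(events$time_ms)        # stable: preserves file order on ties
  events <- events[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(events))
  display <- events$event_kind != "other"
  for (t in unique(events$time_ms[duplicated(events$time_ms)])) {
    at <- which(events$time_ms == t)
    disp_at <- at[display[at]]
    keep[at] <- FALSE
    keep[if (length(disp_at) > 0) disp_at[length(disp_at)] else at[length(at)]] <- TRUE
  }
  events <- events[keep, , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' @exportS3Method base::print
print.question_log <- function(x, ...) {
  cat(sprintf("<question_log> resident %s, test %s, question %s\n",
              x$resident_id, x$drpt_id, x$question_id))
  n_disp <- sum(x$events$event_kind != "other")
  cat(sprintf("  %d events (%d display, %d other), %d ms\n",
              nrow(x$events), n_disp, nrow(x$events) - n_disp,
              x$question_end_ms))
  invisible(x)
}

#' Validate a question log against stack geometry
#'
#' Checks that every display event uses a viewable axis and a slice index
#' within `[1, n_slices\[axis\]]`.
#'
#' @param log A [question_log()].
#' @param geometry A [volume_geometry()].
#' @return The log, invisibly; errors otherwise.
#' @export
validate_log <- function(log, geometry) {
  ev <- log$events[log$events$event_kind != "other", , drop = FALSE]
  bad <- setdiff(unique(ev$axis), viewable_axes(geometry))
  if (length(bad) > 0) {
    stop("log uses non-viewable axis: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (ax in unique(ev$axis)) {
    s <- ev$slice_index[ev$axis == ax]
    if (any(s > geometry[[ax]])) {
      stop(sprintf("slice index %d out of [1, %d] on axis %s",
                   max(s), geometry[[ax]], ax), call. = FALSE)
    }
  }
  invisible(log)
}

#' Piecewise-constant display states of a log
#'
#' Expands a log into half-open display intervals `[t0, t1)`: during each
#' interval the viewer showed one `(axis, slice)` pair. The final interval
#' closes at `question_end_ms`, so interval durations tile the full
#' question time exactly. `"other"` events are ignored.
#'
#' @param log A [question_log()].
#' @return Data frame with columns `t0`, `t1`, `axis`, `slice_index`.
#' @export
display_states <- function(log) {
  ev <- log$events[log$events$event_kind != "other", , drop = FALSE]
  data.frame(
    t0 = ev$time_ms,
    t1 = c(ev$time_ms[-1], log$question_end_ms),
    axis = ev$axis,
    slice_index = ev$slice_index)
}

total_time_ms <- function(log) log$question_end_ms
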