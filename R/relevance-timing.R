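#' Percentage of question time spent on question-relevant slices
#'
#' Walks the piecewise-constant display states of the log and accrues the
#' duration of each half-open interval `[t, t')` to relevant time iff the
#' displayed slice lies in a relevant interval of the *currently displayed*
#' axis. The final state persists to `question_end_ms`. Time spent on an
#' axis whose relevant interval list is empty counts as irrelevant.
#' Pan/zoom/window events (`event_kind = "other"`) never affect the result.
#'
#' @param log A [question_log()].
#' @param relevant A [relevant_region()] defining intervals for (at least)
#'   every axis occurring in the log; an axis not covered by the region's
#'   `axes` attribute is a validation error.
#' @return A `relevance_profile`: list with `relevant_time_ms`,
#'   `total_time_ms` and `perc_time_rel_area` in `[0, 100]`.
#' @examples
#' ev <- data.frame(time_ms = 0, axis = "z", slice_index = 35,
#'                  event_kind = "scroll")
#' log <- question_log("r", "t", "q", ev, question_end_ms = 10000)
#' reg <- relevant_region(data.frame(axis = "z", lo = 30, hi = 40))
#' time_in_relevant_area(log, reg)$perc_time_rel_area # 100
#' @export
time_in_relevant_area <- function(log, relevant) {
  stopifnot(inherits(relevant, "relevant_region"))
  st <- display_states(log)
  missing_axes <- setdiff(unique(st$axis), region_axes(relevant))
  if (length(missing_axes) > 0) {
    stop("log uses axis with no relevant-interval definition: ",
         paste(missing_axes, collapse = ", "), call. = FALSE)
  }
  total <- total_time_ms(log)
  if (total <= 0) {
    stop("total question time is zero; percentage undefined", call. = FALSE)
  }
  rel <- logical(nrow(st))
  for (ax in unique(st$axis)) {
    i <- st$axis == ax
    rel[i] <- slice_in_region(relevant, ax, st$slice_index[i])
  }
  rel_ms <- sum((st$t1 - st$t0)[rel])
  structure(
    list(relevant_time_ms = rel_ms,
         total_time_ms = total,
         perc_time_rel_area = 100 * rel_ms / total),
    class = "relevance_profile")
}

#' @exportS3Method base::print
print.relevance_profile <- function(x, ...) {
  cat(sprintf("<relevance_profile> %.1f%% of %d ms on relevant slices\n",
              x$perc_time_rel_area, x$total_time_ms))
  invisible(x)
}

#' Complement of a relevant region within a stack
#'
#' The slices of each axis of `geometry` not covered by `region`. Useful
#' for the complementarity identity: relevant-time percentages of a region
#' and its complement sum to 100 for any log.
#'
#' @param region A [relevant_region()].
#' @param geometry A [volume_geometry()].
#' @return A [relevant_region()] over the same axes.
#' @export
region_complement <- function(region, geometry) {
  validate_region(region, geometry)
  rows <- lapply(viewable_axes(geometry), function(ax) {
    covered <- IRanges::IRanges(
      start = region$lo[region$axis == ax],
      end = region$hi[region$axis == ax])
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, geometry[[ax]]), covered)
    if (length(gaps) == 0) return(NULL)
    data.frame(axis = ax, lo = IRanges::start(gaps), hi = IRanges::end(gaps))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(axis = character(), lo = integer(), hi = integer())
  }
  relevant_region(rows, axes = viewable_axes(geometry))
}
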