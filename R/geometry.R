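#' Stack geometry of a volumetric question
#'
#' Records how many slices the CT stack has along each viewable axis.
#' Slice numbering is 1-based and inclusive throughout the package.
#'
#' @param n_slices Named integer vector, names from `c("x", "y", "z")`
#'   (sagittal, coronal, axial), values >= 2.
#' @return An object of class `volume_geometry`: a named integer vector
#'   with the viewable axes as names.
#' @examples
#' volume_geometry(c(z = 100))
#' volume_geometry(c(x = 60, y = 60, z = 120))
#' @export
volume_geometry <- function(n_slices) {
  if (length(n_slices) == 0 || is.null(names(n_slices)) ||
      !all(names(n_slices) %in% AXES)) {
    stop("`n_slices` must be a named vector with names among 'x', 'y', 'z'",
         call. = FALSE)
  }
  if (anyDuplicated(names(n_slices))) {
    stop("duplicated axis in `n_slices`", call. = FALSE)
  }
  n <- as.integer(n_slices)
  if (any(is.na(n)) || any(n < 2L)) {
    stop("each axis must have an integer slice count >= 2", call. = FALSE)
  }
  structure(setNames(n, names(n_slices)), class = "volume_geometry")
}

#' @exportS3Method base::print
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry> ",
      paste(sprintf("%s: %d slices", names(x), unclass(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

viewable_axes <- function(geometry) names(geometry)

#' Question-relevant slice intervals
#'
#' The expert-defined relevant area of a question, expressed per axis as a
#' list of inclusive 1-based slice intervals `[lo, hi]`. Overlapping or
#' adjacent intervals on the same axis are merged on construction, so the
#' stored intervals are pairwise disjoint. An axis may be covered by the
#' region yet have no intervals (its relevant set is empty); `axes` records
#' which axes the region is defined on.
#'
#' @param intervals Data frame with columns `axis`, `lo`, `hi` (zero rows
#'   allowed).
#' @param axes Character vector of axes the region is defined for; defaults
#'   to the axes present in `intervals`.
#' @return A `relevant_region`: a data frame of disjoint intervals with an
#'   `axes` attribute.
#' @examples
#' relevant_region(data.frame(axis = "z", lo = 30, hi = 40), axes = "z")
#' @export
relevant_region <- function(intervals = data.frame(axis = character(),
                                                   lo = integer(),
                                                   hi = integer()),
                            axes = NULL) {
  stopifnot(is.data.frame(intervals),
            all(c("axis", "lo", "hi") %in% names(intervals)))
  intervals$axis <- as.character(intervals$axis)
  intervals$lo <- as.integer(intervals$lo)
  intervals$hi <- as.integer(intervals$hi)
  if (!all(intervals$axis %in% AXES)) {
    stop("region axes must be among 'x', 'y', 'z'", call. = FALSE)
  }
  if (nrow(intervals) > 0 &&
      (any(intervals$lo < 1L) || any(intervals$hi < intervals$lo))) {
    stop("intervals must satisfy 1 <= lo <= hi", call. = FALSE)
  }
  axes <- axes %||% unique(intervals$axis)
  if (!all(intervals$axis %in% axes)) {
    stop("`axes` must include every axis present in `intervals`",
         call. = FALSE)
  }
  merged <- do.call(rbind, lapply(split(intervals, intervals$axis), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$lo, end = d$hi))
    data.frame(axis = d$axis[1], lo = IRanges::start(r), hi = IRanges::end(r))
  }))
  if (is.null(merged)) {
    merged <- data.frame(axis = character(), lo = integer(), hi = integer())
  }
  merged <- merged[order(merged$axis, merged$lo), , drop = FALSE]
  rownames(merged) <- NULL
  structure(merged, axes = axes, class = c("relevant_region", "data.frame"))
}

#' @exportS3Method base::print
print.relevant_region <- function(x, ...) {
  cat("<relevant_region> axes:", paste(attr(x, "axes"), collapse = ", "), "\n")
  if (nrow(x) == 0) cat("  (no relevant slices)\n")
  else print(as.data.frame(x))
  invisible(x)
}

region_axes <- function(region) attr(region, "axes")

#' Check whether a displayed slice is question-relevant
#'
#' @param region A [relevant_region()].
#' @param axis Displayed axis.
#' @param slice Displayed slice number (vectorised).
#' @return Logical vector.
#' @export
slice_in_region <- function(region, axis, slice) {
  r <- region[region$axis == axis, , drop = FALSE]
  if (nrow(r) == 0) return(rep(FALSE, length(slice)))
  vapply(slice, function(s) any(r$lo <= s & s <= r$hi), logical(1))
}

validate_region <- function(region, geometry) {
  bad <- setdiff(region$axis, viewable_axes(geometry))
  if (length(bad) > 0) {
    stop("region refers to non-viewable axis: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(region))) {
    if (region$hi[i] > geometry[[region$axis[i]]]) {
      stop(sprintf("region interval [%d, %d] exceeds %d slices on axis %s",
                   region$lo[i], region$hi[i],
                   geometry[[region$axis[i]]], region$axis[i]), call. = FALSE)
    }
  }
  invisible(region)
}

#' Fraction of the stack covered by the relevant region
#'
#' The number of relevant slices on a reference axis divided by that axis's
#' slice count. Used by the question-selection filter, which keeps only
#' questions whose relevant volume covers strictly less than half of the
#' provided stack (focal, not diffuse, abnormalities).
#'
#' @param region A [relevant_region()].
#' @param geometry A [volume_geometry()].
#' @param reference_axis Axis on which coverage is measured; defaults to
#'   `"z"` (axial), the viewer's default direction.
#' @return A proportion in `[0, 1]`.
#' @examples
#' g <- volume_geometry(c(z = 100))
#' r <- relevant_region(data.frame(axis = "z", lo = 30, hi = 40))
#' relevant_volume_fraction(r, g) # 0.11
#' @export
relevant_volume_fraction <- function(region, geometry, reference_axis = "z") {
  if (!reference_axis %in% viewable_axes(geometry)) {
    stop("reference axis '", reference_axis, "' is not a viewable axis",
         call. = FALSE)
  }
  validate_region(region, geometry)
  r <- region[region$axis == reference_axis, , drop = FALSE]
  sum(r$hi - r$lo + 1) / geometry[[reference_axis]]
}
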