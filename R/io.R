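#' Read a per-question scroll logfile
#'
#' Logfile dialect: UTF-8 delimited text, header row
#' `time_ms,axis,slice_index,event_kind`, one event per row in recording
#' order. The final row must have `event_kind = "end"`; its `time_ms` is
#' the moment the question was left (`question_end_ms`) and its axis/slice
#' repeat the last displayed state. One file per resident-question pair,
#' named `<resident>__<drpt>__<question>.log.csv`.
#'
#' @param path Path to the logfile.
#' @param geometry Optional [volume_geometry()]; when given, display events
#'   are validated against it.
#' @param resident_id,drpt_id,question_id Identifiers; by default parsed
#'   from the file name.
#' @return A normalised [question_log()].
#' @seealso [write_question_log()]
#' @export
read_question_log <- function(path, geometry = NULL, resident_id = NULL,
                              drpt_id = NULL, question_id = NULL) {
  ids <- parse_log_filename(basename(path))
  resident_id <- resident_id %||% ids$resident_id
  drpt_id <- drpt_id %||% ids$drpt_id
  question_id <- question_id %||% ids$question_id

  raw <- tryCatch(
    read.csv(path, colClasses = c("integer", "character", "integer",
                                  "character"), strip.white = TRUE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  req <- c("time_ms", "axis", "slice_index", "event_kind")
  if (!identical(names(raw), req)) {
    stop("'", path, "': header must be ", paste(req, collapse = ","),
         call. = FALSE)
  }
  if (nrow(raw) < 2) {
    stop("'", path, "': needs at least one event row and one end row",
         call. = FALSE)
  }
  end_rows <- which(raw$event_kind == "end")
  if (!identical(end_rows, nrow(raw))) {
    stop("'", path, "': exactly one 'end' row required, as the last row ",
         "(file line ", nrow(raw) + 1L, ")", call. = FALSE)
  }
  events <- raw[-nrow(raw), , drop = FALSE]
  bad <- which(!events$axis %in% AXES)
  if (length(bad) > 0) {
    stop(sprintf("'%s': invalid axis '%s' at file line %d", path,
                 events$axis[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  log <- tryCatch(
    question_log(resident_id, drpt_id, question_id, events,
                 question_end_ms = raw$time_ms[nrow(raw)] - min(events$time_ms)),
    error = function(e) stop("'", path, "': ", conditionMessage(e),
                             call. = FALSE))
  if (!is.null(geometry)) validate_log(log, geometry)
  log
}

#' Write a per-question scroll logfile
#'
#' Inverse of [read_question_log()]: writing then reading a normalised log
#' returns an equal value. `"other"` events are preserved verbatim.
#'
#' @param log A [question_log()].
#' @param path Output path; conventionally
#'   `<resident>__<drpt>__<question>.log.csv` (see [question_log_filename()]).
#' @return `path`, invisibly.
#' @export
write_question_log <- function(log, path) {
  stopifnot(inherits(log, "question_log"))
  last <- log$events[nrow(log$events), ]
  out <- rbind(
    log$events,
    data.frame(time_ms = log$question_end_ms, axis = last$axis,
               slice_index = last$slice_index, event_kind = "end"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Canonical logfile name for a resident-question pair
#' @param resident_id,drpt_id,question_id Identifiers.
#' @return File name `<resident>__<drpt>__<question>.log.csv`.
#' @export
question_log_filename <- function(resident_id, drpt_id, question_id) {
  sprintf("%s__%s__%s.log.csv", resident_id, drpt_id, question_id)
}

parse_log_filename <- function(name) {
  stem <- sub("\\.log\\.csv$", "", name)
  parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    return(list(resident_id = NA_character_, drpt_id = NA_character_,
                question_id = NA_character_))
  }
  list(resident_id = parts[1], drpt_id = parts[2], question_id = parts[3])
}

#' List the scroll logfiles in a directory
#'
#' @param dir Directory holding `*.log.csv` files.
#' @return Tibble with `resident_id`, `drpt_id`, `question_id`, `path`.
#' @export
find_question_logs <- function(dir) {
  paths <- list.files(dir, pattern = "\\.log\\.csv$", full.names = TRUE)
  ids <- lapply(basename(paths), parse_log_filename)
  tibble::tibble(
    resident_id = vapply(ids, `[[`, "", "resident_id"),
    drpt_id = vapply(ids, `[[`, "", "drpt_id"),
    question_id = vapply(ids, `[[`, "", "question_id"),
    path = paths)
}

#' Read the cohort tables of a study
#'
#' Expects five delimited files in `dir`:
#' * `residents.csv`: `resident_id`, `start_date`, `end_date` (ISO-8601;
#'   `start_date` may be empty when the enrolment date is unknown — such
#'   residents are excluded from analyses downstream),
#' * `drpts.csv`: `drpt_id`, `date`,
#' * `questions.csv`: `question_id`, `format` (`marker`, `multiple_choice`,
#'   `long_list`), `subdomain`, `p_value`, `requires_diagnosis`,
#'   `single_ct`, and per-axis slice counts `n_slices_x`, `n_slices_y`,
#'   `n_slices_z` (empty when the axis is not viewable),
#' * `regions.csv`: `question_id`, `axis`, `lo`, `hi` — one relevant
#'   interval per row,
#' * `answers.csv`: `resident_id`, `drpt_id`, `question_id`,
#'   `correct` in `{0, 1}`.
#'
#' Cross-references are validated: every answer must name an existing
#' resident, test and question, and every region an existing question. A
#' missing logfile for an answered question is permitted (treated as
#' missing downstream), so no check against the log directory happens here.
#'
#' @param dir Directory with the five tables.
#' @return A list of tibbles `residents`, `drpts`, `questions`, `regions`,
#'   `answers`, of class `cohort_tables`.
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("residents.csv", "drpts.csv", "questions.csv", "regions.csv",
              "answers.csv")) {
    if (!file.exists(path(f))) stop("missing cohort table: ", f, call. = FALSE)
  }
  residents <- tibble::as_tibble(read.csv(path("residents.csv"),
                                          colClasses = "character"))
  residents$start_date <- as.Date(ifelse(residents$start_date == "", NA,
                                         residents$start_date))
  residents$end_date <- as.Date(residents$end_date)
  drpts <- tibble::as_tibble(read.csv(path("drpts.csv"),
                                      colClasses = "character"))
  drpts$date <- as.Date(drpts$date)
  questions <- tibble::as_tibble(read.csv(path("questions.csv")))
  questions$question_id <- as.character(questions$question_id)
  regions <- tibble::as_tibble(read.csv(path("regions.csv")))
  regions$question_id <- as.character(regions$question_id)
  answers <- tibble::as_tibble(read.csv(path("answers.csv")))
  for (col in c("resident_id", "drpt_id", "question_id")) {
    answers[[col]] <- as.character(answers[[col]])
  }
  cohort <- structure(
    list(residents = residents, drpts = drpts, questions = questions,
         regions = regions, answers = answers),
    class = "cohort_tables")
  validate_cohort(cohort)
}

validate_cohort <- function(cohort) {
  a <- cohort$answers
  if (!all(a$correct %in% c(0L, 1L))) {
    stop("answers$correct must be 0 or 1", call. = FALSE)
  }
  dangling <- function(keys, universe, what) {
    bad <- unique(setdiff(keys, universe))
    if (length(bad) > 0) {
      stop("unknown ", what, " referenced: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  dangling(a$resident_id, cohort$residents$resident_id, "resident")
  dangling(a$drpt_id, cohort$drpts$drpt_id, "test")
  dangling(a$question_id, cohort$questions$question_id, "question")
  dangling(cohort$regions$question_id, cohort$questions$question_id,
           "question (in regions)")
  bad_p <- cohort$questions$p_value < 0 | cohort$questions$p_value > 1
  if (any(bad_p, na.rm = TRUE)) {
    stop("question p_value outside [0, 1]", call. = FALSE)
  }
  invisible(cohort)
}

#' Write cohort tables to a directory
#'
#' Inverse of [read_cohort()]; used by the synthetic-data generator.
#'
#' @param cohort A `cohort_tables` list as returned by [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE,
                                 quote = FALSE, na = "")
  wr(cohort$residents, "residents.csv")
  wr(cohort$drpts, "drpts.csv")
  wr(cohort$questions, "questions.csv")
  wr(cohort$regions, "regions.csv")
  wr(cohort$answers, "answers.csv")
  invisible(dir)
}

#' Geometry and relevant region of one question row
#'
#' Helpers extracting a [volume_geometry()] / [relevant_region()] from the
#' cohort tables for a given question.
#'
#' @param cohort A `cohort_tables` list.
#' @param question_id Question identifier.
#' @return A [volume_geometry()] or [relevant_region()].
#' @export
question_geometry <- function(cohort, question_id) {
  q <- cohort$questions[cohort$questions$question_id == question_id, ]
  if (nrow(q) != 1) stop("unknown question: ", question_id, call. = FALSE)
  n <- c(x = q$n_slices_x, y = q$n_slices_y, z = q$n_slices_z)
  n <- n[!is.na(n)]
  names(n) <- sub("^n_slices_", "", names(n))  # guard against name mangling
  volume_geometry(n)
}

#' @rdname question_geometry
#' @export
question_region <- function(cohort, question_id) {
  g <- question_geometry(cohort, question_id)
  r <- cohort$regions[cohort$regions$question_id == question_id,
                      c("axis", "lo", "hi")]
  relevant_region(as.data.frame(r), axes = viewable_axes(g))
}
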