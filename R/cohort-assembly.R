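#' Relative training time at a test date
#'
#' Residents progress through the residency program at different paces
#' (part-time work, research), so elapsed training is standardised to a
#' five-year scale:
#' `tr_time = (test_date - start_date) / (end_date - start_date) * 5`,
#' with date arithmetic in whole days. A resident with an unknown
#' enrolment date yields `NA` (such residents are excluded from analyses).
#'
#' @param drpt_date Test date(s), `Date`.
#' @param start_date,end_date Training start/end dates, `Date` (vectorised;
#'   recycled against `drpt_date`).
#' @return Training time in years on the `[0, 5]` scale.
#' @examples
#' training_time(as.Date("2016-03-01"),
#'               as.Date("2013-09-01"), as.Date("2018-09-01"))
#' @export
training_time <- function(drpt_date, start_date, end_date) {
  stopifnot(inherits(drpt_date, "Date"), inherits(start_date, "Date"),
            inherits(end_date, "Date"))
  dur <- as.numeric(end_date - start_date)
  if (any(dur <= 0, na.rm = TRUE)) {
    stop("end_date must be after start_date", call. = FALSE)
  }
  as.numeric(drpt_date - start_date) / dur * 5
}

#' Rescaled test difficulty from item P values
#'
#' A question's P value is the proportion of residents answering it
#' correctly (classical item difficulty; higher = easier). Test difficulty
#' is the mean P value of the selected questions, rescaled to
#' `[-0.5, 0.5]` by subtracting 0.5, so that 0 corresponds to a test on
#' which 50 percent of residents answered correctly, and higher values
#' mean an easier test.
#'
#' @param p_values Numeric vector of item P values in `[0, 1]`.
#' @return The rescaled difficulty, `mean(p_values) - 0.5`.
#' @examples
#' drpt_difficulty(c(0.59, 0.64, 0.69)) # 0.14
#' @export
drpt_difficulty <- function(p_values) {
  if (length(p_values) == 0 || anyNA(p_values)) {
    stop("need a non-empty vector of P values without missing entries",
         call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1)) {
    stop("P values must lie in [0, 1]", call. = FALSE)
  }
  mean(p_values) - 0.5
}

#' Apply the three question-selection criteria
#'
#' Keeps questions that (1) require interpretation of a single CT scan,
#' (2) ask for a diagnosis (not mere anatomy marking), and (3) have a
#' relevant volume covering strictly less than 50 percent of the provided
#' stack on the reference axis — restricting the set to focal
#' abnormalities. A question whose geometry or region metadata is missing
#' is flagged (listed in the `flagged` attribute), not silently dropped.
#'
#' @param cohort A `cohort_tables` list (see [read_cohort()]).
#' @param reference_axis Axis on which volume coverage is measured
#'   (default `"z"`).
#' @return The kept rows of `cohort$questions`, with attributes
#'   `rejections` (named counts per criterion) and `flagged` (question ids
#'   with unusable metadata).
#' @export
select_questions <- function(cohort, reference_axis = "z") {
  q <- cohort$questions
  frac <- vapply(q$question_id, function(id) {
    tryCatch(relevant_volume_fraction(question_region(cohort, id),
                                      question_geometry(cohort, id),
                                      reference_axis),
             error = function(e) NA_real_)
  }, numeric(1))
  flagged <- q$question_id[is.na(frac)]
  keep_ct <- q$single_ct %in% TRUE
  keep_diag <- q$requires_diagnosis %in% TRUE
  keep_focal <- !is.na(frac) & frac < 0.5   # strict: exactly half is rejected
  kept <- q[keep_ct & keep_diag & keep_focal, , drop = FALSE]
  structure(kept,
            rejections = c(
              non_single_ct = sum(!keep_ct),
              no_diagnosis = sum(keep_ct & !keep_diag),
              volume_not_below_half = sum(keep_ct & keep_diag & !keep_focal &
                                            !is.na(frac)),
              missing_metadata = sum(keep_ct & keep_diag & is.na(frac))),
            flagged = flagged)
}

#' Compute both scroll metrics for one question log
#'
#' @param log A [question_log()].
#' @param geometry A [volume_geometry()].
#' @param region A [relevant_region()].
#' @param correct Optional 0/1 correctness of the answer.
#' @return One-row tibble with `resident_id`, `drpt_id`, `question_id`,
#'   `perc_time_full_runs`, `perc_time_rel_area`, `total_time_ms`,
#'   `correct`.
#' @export
question_metrics <- function(log, geometry, region, correct = NA_integer_) {
  rp <- perc_time_full_runs(log, geometry)
  ap <- time_in_relevant_area(log, region)
  tibble::tibble(
    resident_id = log$resident_id,
    drpt_id = log$drpt_id,
    question_id = log$question_id,
    perc_time_full_runs = rp$perc_time_full_runs,
    perc_time_rel_area = ap$perc_time_rel_area,
    total_time_ms = rp$total_time_ms,
    correct = as.integer(correct))
}

#' Compute question-level metrics for a set of logs
#'
#' Joins each log with its question's geometry/region and the recorded
#' answer. Answers without a logfile are kept with `NA` metrics (missing
#' listwise downstream).
#'
#' @param logs List of [question_log()] objects.
#' @param cohort A `cohort_tables` list.
#' @param questions Question table to restrict to (default: the full
#'   `cohort$questions`); typically the output of [select_questions()].
#' @return Tibble of question-level metrics, one row per answer of a
#'   retained question.
#' @export
compute_question_metrics <- function(logs, cohort,
                                     questions = cohort$questions) {
  key <- function(r, d, q) paste(r, d, q, sep = "\r")
  log_keys <- vapply(logs, function(l) key(l$resident_id, l$drpt_id,
                                           l$question_id), character(1))
  a <- cohort$answers[cohort$answers$question_id %in% questions$question_id, ]
  # geometry/region construction is not free; build each question's once
  geoms <- new.env(parent = emptyenv())
  regs <- new.env(parent = emptyenv())
  for (qid in unique(a$question_id)) {
    assign(qid, question_geometry(cohort, qid), envir = geoms)
    assign(qid, question_region(cohort, qid), envir = regs)
  }
  n <- nrow(a)
  ptfr <- rep(NA_real_, n)
  ptra <- rep(NA_real_, n)
  total <- rep(NA_integer_, n)
  j <- match(key(a$resident_id, a$drpt_id, a$question_id), log_keys)
  for (i in which(!is.na(j))) {
    log <- logs[[j[i]]]
    rp <- perc_time_full_runs(log, get(a$question_id[i], envir = geoms))
    ap <- time_in_relevant_area(log, get(a$question_id[i], envir = regs))
    ptfr[i] <- rp$perc_time_full_runs
    ptra[i] <- ap$perc_time_rel_area
    total[i] <- rp$total_time_ms
  }
  tibble::tibble(
    resident_id = a$resident_id, drpt_id = a$drpt_id,
    question_id = a$question_id,
    perc_time_full_runs = ptfr, perc_time_rel_area = ptra,
    total_time_ms = total, correct = as.integer(a$correct))
}

#' Aggregate question-level metrics to resident-by-test records
#'
#' The two scroll metrics are averaged (unweighted) over the questions
#' with an available logfile; missing logfiles are dropped listwise.
#' Diagnostic accuracy is aggregated as `n_correct` out of `n_questions`,
#' counted over questions whose format is not in `exclude_formats`
#' (marker questions are excluded this way in the accuracy analysis). Test
#' difficulty `drpt_diff` is recomputed per test from the P values of the
#' questions entering the accuracy counts. Relative training time
#' `tr_time` comes from the resident roster; residents with an unknown
#' enrolment date are excluded with a warning. A resident-test pair with
#' no available scroll metrics at all is omitted with a warning.
#'
#' @param metrics Question-level metrics (see [compute_question_metrics()]).
#' @param cohort A `cohort_tables` list.
#' @param exclude_formats Character vector of question formats excluded
#'   from the accuracy aggregation (e.g. `"marker"`). Scroll-metric
#'   averages always use all available questions.
#' @return Tibble of test-level records: `resident_id`, `drpt_id`,
#'   `tr_time`, `drpt_diff`, `perc_time_full_runs_avg`,
#'   `perc_time_rel_area_avg`, `n_correct`, `n_questions`.
#' @export
aggregate_to_drpt <- function(metrics, cohort, exclude_formats = character()) {
  q <- cohort$questions
  fmt <- q$format[match(metrics$question_id, q$question_id)]
  pval <- q$p_value[match(metrics$question_id, q$question_id)]
  in_acc <- !fmt %in% exclude_formats

  res <- cohort$residents
  no_start <- res$resident_id[is.na(res$start_date)]
  if (length(no_start) > 0 && any(metrics$resident_id %in% no_start)) {
    warning(sum(unique(metrics$resident_id) %in% no_start),
            " resident(s) without enrolment date excluded", call. = FALSE)
    metrics_keep <- !metrics$resident_id %in% no_start
    metrics <- metrics[metrics_keep, , drop = FALSE]
    fmt <- fmt[metrics_keep]; pval <- pval[metrics_keep]
    in_acc <- in_acc[metrics_keep]
  }

  # test difficulty is a property of the test: mean P value over the
  # distinct questions entering the accuracy aggregation for that test
  dq <- unique(data.frame(drpt_id = metrics$drpt_id[in_acc],
                          question_id = metrics$question_id[in_acc],
                          p_value = pval[in_acc]))
  diff_by_drpt <- vapply(split(dq$p_value, dq$drpt_id), drpt_difficulty,
                         numeric(1))

  grp <- paste(metrics$resident_id, metrics$drpt_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(metrics)), grp), function(i) {
    m <- metrics[i, ]
    have <- !is.na(m$perc_time_full_runs)
    acc <- in_acc[i] & !is.na(m$correct)
    if (!any(have) && !any(acc)) return(NULL)
    tibble::tibble(
      resident_id = m$resident_id[1],
      drpt_id = m$drpt_id[1],
      perc_time_full_runs_avg =
        if (any(have)) mean(m$perc_time_full_runs[have]) else NA_real_,
      perc_time_rel_area_avg =
        if (any(have)) mean(m$perc_time_rel_area[have]) else NA_real_,
      n_correct = sum(m$correct[acc]),
      n_questions = sum(acc),
      drpt_diff = unname(diff_by_drpt[m$drpt_id[1]]))
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " resident-test pair(s) with no available questions ",
            "omitted", call. = FALSE)
  }
  rec <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(rec) || nrow(rec) == 0) {
    stop("no aggregable records", call. = FALSE)
  }
  d_date <- cohort$drpts$date[match(rec$drpt_id, cohort$drpts$drpt_id)]
  ri <- match(rec$resident_id, res$resident_id)
  rec$tr_time <- training_time(d_date, res$start_date[ri], res$end_date[ri])
  rec <- rec[order(rec$resident_id, d_date), ]
  rec[, c("resident_id", "drpt_id", "tr_time", "drpt_diff",
          "perc_time_full_runs_avg", "perc_time_rel_area_avg",
          "n_correct", "n_questions")]
}
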