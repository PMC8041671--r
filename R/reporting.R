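#' Run the full scroll-analysis pipeline
#'
#' Orchestrates parse -> metrics -> aggregate -> fit in one deterministic
#' call. The question filter is applied first; metrics are computed per
#' answered question; records are aggregated twice — once with all
#' question formats (expertise-development models on both scroll metrics)
#' and once excluding the formats in `exclude_formats` (the diagnostic-
#' accuracy model, which drops marker questions) — and the model ladders
#' are fitted and the best model per outcome selected by likelihood-ratio
#' test.
#'
#' @param cohort A `cohort_tables` list or a directory for [read_cohort()].
#' @param logs A list of [question_log()]s or a directory of logfiles.
#' @param exclude_formats Formats excluded from the accuracy aggregation
#'   (default `"marker"`).
#' @param reference_axis Axis for the volume-coverage filter (default
#'   `"z"`).
#' @param alpha Significance level for model selection (default 0.05).
#' @param nAGQ Quadrature nodes for the binomial ladder (default 20).
#' @param robust Cluster-robust SEs in the Gaussian ladders (default
#'   `TRUE`).
#' @param out_dir Optional output directory: writes `question_metrics.csv`,
#'   `drpt_records.csv`, `drpt_records_accuracy.csv`, one
#'   `model_<outcome>.csv` per outcome and a `run_log.txt` with the
#'   configuration and rejection counts. Re-running with the same inputs
#'   reproduces the tables byte for byte.
#' @return A list: `selected_questions`, `metrics`, `records`,
#'   `records_accuracy`, `ladders` (per outcome), `best` (per outcome),
#'   `r2_level1` (per Gaussian outcome).
#' @export
run_pipeline <- function(cohort, logs, exclude_formats = "marker",
                         reference_axis = "z", alpha = 0.05, nAGQ = 20,
                         robust = TRUE, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  sel <- select_questions(cohort, reference_axis)
  if (is.character(logs)) {
    idx <- find_question_logs(logs)
    idx <- idx[idx$question_id %in% sel$question_id, ]
    logs <- lapply(seq_len(nrow(idx)), function(i) {
      read_question_log(idx$path[i],
                        geometry = question_geometry(cohort,
                                                     idx$question_id[i]))
    })
  }
  metrics <- compute_question_metrics(logs, cohort, questions = sel)
  d_date <- cohort$drpts$date[match(metrics$drpt_id, cohort$drpts$drpt_id)]
  ri <- match(metrics$resident_id, cohort$residents$resident_id)
  metrics$tr_time <- training_time(d_date, cohort$residents$start_date[ri],
                                   cohort$residents$end_date[ri])

  records <- aggregate_to_drpt(metrics, cohort)
  records_acc <- aggregate_to_drpt(metrics, cohort,
                                   exclude_formats = exclude_formats)

  ladders <- list(
    perc_time_full_runs_avg =
      fit_lmm_ladder(records, "perc_time_full_runs_avg", robust = robust),
    perc_time_rel_area_avg =
      fit_lmm_ladder(records, "perc_time_rel_area_avg", robust = robust),
    accuracy = fit_binomial_ladder(records_acc, nAGQ = nAGQ))
  best <- lapply(ladders, function(l) {
    tryCatch(select_best(l, alpha = alpha), error = function(e) NULL)
  })
  safe_r2 <- function(outc) {
    tryCatch(level1_r2(best[[outc]], ladders[[outc]][[1]]),
             error = function(e) NA_real_)
  }
  r2 <- list(perc_time_full_runs_avg = safe_r2("perc_time_full_runs_avg"),
             perc_time_rel_area_avg = safe_r2("perc_time_rel_area_avg"))
  out <- list(selected_questions = sel, metrics = metrics, records = records,
              records_accuracy = records_acc, ladders = ladders, best = best,
              r2_level1 = r2)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir,
                                                exclude_formats)
  out
}

write_pipeline_outputs <- function(out, out_dir, exclude_formats) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.csv(x, file.path(out_dir, f),
                                 row.names = FALSE, na = "")
  wr(out$metrics, "question_metrics.csv")
  wr(out$records, "drpt_records.csv")
  wr(out$records_accuracy, "drpt_records_accuracy.csv")
  for (nm in names(out$best)) {
    if (!is.null(out$best[[nm]])) {
      wr(out$best[[nm]]$fixed, paste0("model_", nm, ".csv"))
    }
  }
  rej <- attr(out$selected_questions, "rejections")
  lines <- c(
    paste0("volscroll ", as.character(utils::packageVersion("volscroll"))),
    paste0("questions kept: ", nrow(out$selected_questions)),
    paste0("rejections: ", paste(names(rej), rej, sep = "=",
                                 collapse = ", ")),
    paste0("accuracy aggregation excludes: ",
           paste(exclude_formats, collapse = ", ")),
    vapply(names(out$best), function(nm) {
      paste0("best model (", nm, "): ",
             out$best[[nm]]$label %||% "none converged")
    }, character(1)),
    vapply(names(out$r2_level1), function(nm) {
      sprintf("level-1 R2 (%s): %.3f", nm, out$r2_level1[[nm]])
    }, character(1)))
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Descriptive statistics of the scroll metrics by training-time bin
#'
#' Training time is a continuous predictor in all models; for descriptive
#' tables it is binned (default half-year bins `[0, 0.5)`, ..., with the
#' final bin closed at 5). A resident contributes to every bin they have a
#' test in, so residents can appear in several bins.
#'
#' @param records Test-level records.
#' @param bin_width_years Bin width (default 0.5).
#' @return Tibble: `bin`, `n`, mean/SD of both averaged metrics (SD is
#'   `NA` for single-record bins).
#' @export
binned_descriptives <- function(records, bin_width_years = 0.5) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  top <- max(5, ceiling(max(records$tr_time) / bin_width_years) *
               bin_width_years)
  breaks <- seq(0, top, by = bin_width_years)
  idx <- findInterval(records$tr_time, breaks, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  labels <- sprintf("%g-%g", breaks[-length(breaks)], breaks[-1])
  rows <- lapply(sort(unique(idx)), function(k) {
    r <- records[idx == k, ]
    tibble::tibble(
      bin = labels[k], n = nrow(r),
      mean_full_runs = mean(r$perc_time_full_runs_avg, na.rm = TRUE),
      sd_full_runs = sd(r$perc_time_full_runs_avg, na.rm = TRUE),
      mean_rel_area = mean(r$perc_time_rel_area_avg, na.rm = TRUE),
      sd_rel_area = sd(r$perc_time_rel_area_avg, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Question-level metrics by format and correctness
#'
#' Splits the question-level metrics by question format crossed with
#' answer correctness and reports count, mean and SD of both metrics per
#' stratum. Empty strata are omitted.
#'
#' @param metrics Question-level metrics with `correct`.
#' @param cohort A `cohort_tables` list (for the format lookup).
#' @param formats Formats to include (default: all present).
#' @return Tibble: `format`, `correct`, `n`, means and SDs.
#' @export
format_stratified_descriptives <- function(metrics, cohort, formats = NULL) {
  q <- cohort$questions
  fmt <- q$format[match(metrics$question_id, q$question_id)]
  keep <- !is.na(metrics$perc_time_full_runs) & !is.na(metrics$correct)
  if (!is.null(formats)) keep <- keep & fmt %in% formats
  m <- metrics[keep, ]
  fmt <- fmt[keep]
  grp <- split(seq_len(nrow(m)), list(fmt, m$correct), drop = TRUE)
  rows <- lapply(grp, function(i) {
    tibble::tibble(
      format = fmt[i[1]], correct = m$correct[i[1]], n = length(i),
      mean_rel_area = mean(m$perc_time_rel_area[i]),
      sd_rel_area = sd(m$perc_time_rel_area[i]),
      mean_full_runs = mean(m$perc_time_full_runs[i]),
      sd_full_runs = sd(m$perc_time_full_runs[i]))
  })
  out <- do.call(rbind, rows)
  out[order(out$format, -out$correct), ]
}

#' Cross-sectional scatterplot of a question-level metric
#'
#' Plots one metric against relative training time for (typically) a
#' single question's answers across residents, with an ordinary
#' least-squares trend line whose slope is annotated (2 decimals). With
#' `by_correctness = TRUE` points are marked by diagnostic accuracy.
#'
#' @param metrics Question-level metrics with `tr_time`.
#' @param outcome `"perc_time_full_runs"` or `"perc_time_rel_area"`.
#' @param by_correctness Colour points by `correct` (default `FALSE`).
#' @param file Optional path; when given the figure is saved there.
#' @return A ggplot object (invisibly when `file` is given); its
#'   `trend_slope` attribute carries the OLS slope.
#' @export
item_scatter <- function(metrics, outcome = c("perc_time_full_runs",
                                              "perc_time_rel_area"),
                         by_correctness = FALSE, file = NULL) {
  outcome <- match.arg(outcome)
  m <- metrics[!is.na(metrics[[outcome]]) & !is.na(metrics$tr_time), ]
  if (nrow(m) < 2) stop("need at least 2 points", call. = FALSE)
  slope <- unname(coef(lm(m[[outcome]] ~ m$tr_time))[2])
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$tr_time,
                                       y = .data[[outcome]]))
  if (by_correctness) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$correct)),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "correct")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p <- p +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("slope = %.2f", slope)) +
    ggplot2::labs(x = "relative training time (years)", y = outcome)
  attr(p, "trend_slope") <- slope
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4)
    return(invisible(p))
  }
  p
}
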