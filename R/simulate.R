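#' Parameters for simulating one scroll trajectory
#'
#' The generator emulates the canonical behavioural phases seen in CT
#' reading: initial *full sweeps* through the stack (global search),
#' *oscillation* over a small slice range concentrated on the relevant
#' interval (focal analysis), and stationary dwell elsewhere. Realism is
#' deliberately minimal — enough to exercise the metrics, with no attempt
#' to model finer navigation behaviour.
#'
#' Default question time follows the observed distribution of time spent
#' on CT-scan questions (mean 122.9 s, SD 124.1 s), drawn log-normally and
#' truncated to `[5, 900]` s. Default metric targets derive from the
#' growth model (see [cohort_params()]) evaluated at `expertise` training
#' years and average test difficulty 0.14.
#'
#' @param n_slices Named slice counts as in [volume_geometry()] (default
#'   `c(z = 40)`).
#' @param relevant A [relevant_region()]; default is the central fifth of
#'   the axial stack.
#' @param expertise Training-years scalar in `[0, 5]` used to derive
#'   default targets (default 2.5).
#' @param target_perc_full_runs,target_perc_rel_area Target percentages;
#'   `NULL` (default) derives them from `expertise`.
#' @param resident_offsets Named pair `c(full_runs = , rel_area = )` of
#'   additive offsets (a resident's random intercepts on both metrics).
#' @param mean_question_time_ms,sd_question_time_ms Question-time
#'   distribution (log-normal).
#' @param noise_sd Named pair of SDs of Gaussian jitter applied to the
#'   targets per question.
#' @param axis Axis on which the trajectory is generated (default `"z"`).
#' @param sweep_ms Duration of one full sweep (default 4000 ms).
#' @param osc_period_ms Spacing of oscillation events (default 250 ms).
#' @param seed Optional integer seed.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(n_slices = c(z = 40),
                              relevant = NULL,
                              expertise = 2.5,
                              target_perc_full_runs = NULL,
                              target_perc_rel_area = NULL,
                              resident_offsets = c(full_runs = 0,
                                                   rel_area = 0),
                              mean_question_time_ms = 122900,
                              sd_question_time_ms = 124100,
                              noise_sd = c(full_runs = 2, rel_area = 2),
                              axis = "z",
                              sweep_ms = 4000,
                              osc_period_ms = 250,
                              seed = NULL) {
  geometry <- volume_geometry(n_slices)
  if (is.null(relevant)) {
    n <- geometry[[axis]]
    len <- max(1L, round(0.2 * n))
    lo <- max(1L, round((n - len) / 2))
    relevant <- relevant_region(
      data.frame(axis = axis, lo = lo, hi = lo + len - 1L),
      axes = viewable_axes(geometry))
  }
  validate_region(relevant, geometry)
  stopifnot(expertise >= 0, expertise <= 5, mean_question_time_ms > 0)
  if (is.null(target_perc_full_runs)) {
    target_perc_full_runs <- 20.19 - 0.94 * expertise + 6.70 * 0.14
  }
  if (is.null(target_perc_rel_area)) {
    target_perc_rel_area <- 53.16 + 1.70 * expertise - 57.47 * 0.14
  }
  stopifnot(target_perc_full_runs >= 0, target_perc_full_runs <= 100,
            target_perc_rel_area >= 0, target_perc_rel_area <= 100)
  structure(
    list(geometry = geometry, relevant = relevant, axis = axis,
         expertise = expertise,
         target_perc_full_runs = target_perc_full_runs,
         target_perc_rel_area = target_perc_rel_area,
         resident_offsets = resident_offsets,
         mean_question_time_ms = mean_question_time_ms,
         sd_question_time_ms = sd_question_time_ms,
         noise_sd = noise_sd, sweep_ms = sweep_ms,
         osc_period_ms = osc_period_ms, seed = seed),
    class = "trajectory_params")
}

# nearest in-region / out-of-region slice helpers (single axis)
.nearest_in <- function(slice, reg) {
  cand <- unlist(mapply(function(lo, hi) c(lo, hi), reg$lo, reg$hi,
                        SIMPLIFY = FALSE))
  cand <- c(cand, pmin(pmax(slice, reg$lo), reg$hi))
  cand[which.min(abs(cand - slice))]
}
.nearest_out <- function(slice, reg, n) {
  all_s <- seq_len(n)
  out <- all_s[!vapply(all_s, function(s) any(reg$lo <= s & s <= reg$hi),
                       logical(1))]
  if (length(out) == 0) return(NA_integer_)
  out[which.min(abs(out - slice))]
}

#' Simulate one question's scroll log
#'
#' Emits an event stream whose pipeline metrics match the (noise-jittered)
#' targets: full sweeps through all slices whose summed duration over the
#' question time yields the full-run percentage, then oscillation inside
#' the relevant interval sized so total relevant dwell (including what the
#' sweeps themselves contribute) matches the relevant-area percentage,
#' then stationary dwell on an irrelevant slice. Target pairs that cannot
#' coexist (for example a relevance target below what the requested full
#' runs already accrue while crossing the relevant interval, or targets
#' that together exceed the question time) raise an infeasibility error.
#'
#' @param params A [trajectory_params()].
#' @param resident_id,drpt_id,question_id Identifiers for the log.
#' @return A [question_log()] with attribute `truth`: the realised
#'   percentages and the jittered targets.
#' @export
simulate_trajectory <- function(params, resident_id = "sim", drpt_id = "sim",
                                question_id = "sim") {
  stopifnot(inherits(params, "trajectory_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  axis <- params$axis
  N <- params$geometry[[axis]]
  if (N < 4) stop("need at least 4 slices to stage full sweeps", call. = FALSE)
  reg <- params$relevant[params$relevant$axis == axis, , drop = FALSE]

  # question time: log-normal matched to the requested mean/SD
  cv2 <- (params$sd_question_time_ms / params$mean_question_time_ms)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(params$mean_question_time_ms) - sdlog^2 / 2
  T_ms <- round(min(max(rlnorm(1, meanlog, sdlog), 5000), 900000))

  p_f <- params$target_perc_full_runs + params$resident_offsets[["full_runs"]] +
    rnorm(1, 0, params$noise_sd[["full_runs"]])
  p_r <- params$target_perc_rel_area + params$resident_offsets[["rel_area"]] +
    rnorm(1, 0, params$noise_sd[["rel_area"]])
  p_f <- min(max(p_f, 0), 90)
  p_r <- min(max(p_r, 0), 100)

  F_ms <- round(p_f / 100 * T_ms)
  jump_ms <- 40L
  ts <- integer(0)
  ss <- integer(0)

  # --- full sweeps -------------------------------------------------------
  if (F_ms > 0) {
    k <- max(1L, round(F_ms / params$sweep_ms))
    durs <- diff(round(seq(0, F_ms, length.out = k + 1)))
    # end the last sweep at the extreme nearest the relevant region, so the
    # jump to the oscillation anchor can never itself be a full run
    if (nrow(reg) > 0) {
      d1 <- abs(1 - .nearest_in(1L, reg))
      dN <- abs(N - .nearest_in(N, reg))
      end_extreme <- if (d1 <= dN) 1L else N
    } else {
      end_extreme <- N
    }
    start_extreme <- if (k %% 2 == 1) (N + 1L) - end_extreme else end_extreme
    cur <- start_extreme
    t0 <- 0L
    for (j in seq_len(k)) {
      dest <- if (cur == 1L) N else 1L
      m <- min(41L, max(2L, floor(durs[j] / 30) + 1L))
      sl <- round(seq(cur, dest, length.out = m))
      tm <- t0 + round(seq(0, durs[j], length.out = m))
      drop_first <- if (j == 1) 0L else 1L   # shared extreme already emitted
      ts <- c(ts, tm[(1 + drop_first):m])
      ss <- c(ss, sl[(1 + drop_first):m])
      cur <- dest
      t0 <- t0 + durs[j]
    }
  }

  # relevant dwell the sweeps already accrue (each event holds its slice
  # until the next event; the final sweep event holds for the jump)
  in_reg <- function(s) nrow(reg) > 0 && any(reg$lo <= s & s <= reg$hi)
  if (length(ts) > 0) {
    dwell <- c(diff(ts), jump_ms)
    R_pre <- sum(dwell[vapply(ss, in_reg, logical(1))])
    t_cursor <- ts[length(ts)] + jump_ms
  } else {
    R_pre <- 0
    t_cursor <- 0L
  }

  # --- oscillation on the relevant interval ------------------------------
  R_target <- p_r / 100 * T_ms
  D_osc <- R_target - R_pre
  tol <- 0.005 * T_ms
  if (D_osc < -tol) {
    stop("infeasible targets: the requested full runs already spend more ",
         "time on relevant slices than the relevance target allows",
         call. = FALSE)
  }
  D_osc <- max(0, round(D_osc))
  if (D_osc > 0 && nrow(reg) == 0) {
    stop("infeasible targets: positive relevance target but no relevant ",
         "slices on axis ", axis, call. = FALSE)
  }
  D_irr <- T_ms - t_cursor - D_osc
  if (D_irr < -tol) {
    stop("infeasible targets: full-run and relevant-area targets together ",
         "exceed the question time", call. = FALSE)
  }
  D_irr <- max(0, D_irr)

  if (D_osc > 0) {
    anchor <- .nearest_in(if (length(ss) > 0) ss[length(ss)] else 1L, reg)
    iv <- reg[reg$lo <= anchor & anchor <= reg$hi, ][1, ]
    buddy <- if (anchor < iv$hi) anchor + 1L else
      if (anchor > iv$lo) anchor - 1L else anchor
    otimes <- seq(t_cursor, t_cursor + D_osc - 1, by = params$osc_period_ms)
    oslices <- rep_len(c(anchor, buddy), length(otimes))
    ts <- c(ts, otimes)
    ss <- c(ss, oslices)
    t_cursor <- t_cursor + D_osc
  } else if (length(ts) == 0) {
    # no sweeps, no oscillation: the whole question is stationary
    t_cursor <- 0L
  }

  achieved_rel <- R_pre + D_osc
  if (D_irr > 0) {
    here <- if (length(ss) > 0) ss[length(ss)] else
      if (nrow(reg) > 0) .nearest_in(1L, reg) else 1L
    irr <- .nearest_out(here, reg, N)
    if (is.na(irr)) {
      stop("infeasible targets: relevant region covers the whole axis but ",
           "irrelevant dwell time is required", call. = FALSE)
    }
    ts <- c(ts, t_cursor)
    ss <- c(ss, irr)
  } else if (length(ts) == 0) {
    # degenerate: sit on a relevant slice (or slice 1) for the whole time
    ts <- 0L
    ss <- if (nrow(reg) > 0) .nearest_in(1L, reg) else 1L
    achieved_rel <- if (in_reg(ss)) T_ms else 0
  }
  if (length(ts) > 0 && ts[1] != 0L) {
    # ensure the initial display state is recorded at time zero
    ts <- c(0L, ts)
    ss <- c(ss[1], ss)
  }

  keep <- ts <= T_ms
  events <- data.frame(time_ms = as.integer(ts[keep]), axis = axis,
                       slice_index = as.integer(ss[keep]),
                       event_kind = "scroll")
  log <- question_log(resident_id, drpt_id, question_id, events,
                      question_end_ms = T_ms)
  attr(log, "truth") <- list(
    perc_time_full_runs = 100 * F_ms / T_ms,
    perc_time_rel_area = 100 * achieved_rel / T_ms,
    total_time_ms = T_ms,
    target_perc_full_runs = p_f,
    target_perc_rel_area = p_r)
  log
}

#' Parameters for simulating a longitudinal testing cohort
#'
#' Defaults mirror the study conditions of the longitudinal progress-test
#' data the package is built around: 648 residents, 9 semi-annual tests,
#' 2-9 selected CT questions per test (mean 5), test difficulty drawn from
#' Normal(0.14, 0.07) truncated to `[0.02, 0.24]`, and growth-model fixed
#' effects and variance components for the three outcomes:
#'
#' * full-run percentage: intercept 20.19, training-time slope -0.94,
#'   difficulty slope 6.70; level-1 variance 81.56, intercept variance 10.84;
#' * relevant-area percentage: 53.16, 1.70, -57.47; 133.04, 5.30;
#' * accuracy (logit scale): intercept -1.078, training time 0.338,
#'   full-run 0.001, relevant-area 0.003, difficulty 5.093; resident
#'   intercept variance 0.056.
#'
#' Enrolment dates are uniform over the nine years ending at the last test
#' so that relative training time spans the whole `(0, 5]` scale; each
#' resident is eligible for the consecutive tests falling inside their
#' five-year program and attends a consecutive block of them
#' (attendance rate 0.82), reproducing an unbalanced panel with 1-9 tests
#' per resident and around 4 on average.
#'
#' @param n_residents,n_drpts Cohort dimensions.
#' @param first_drpt_date First test date.
#' @param drpt_interval_days Days between tests (semi-annual).
#' @param attendance Per-eligible-test attendance rate in `(0, 1]`.
#' @param fullruns,relarea,accuracy Lists of generating parameters (see
#'   above for fields).
#' @param drpt_diff List `mean`, `sd`, `min`, `max` of the test-difficulty
#'   distribution.
#' @param seed Optional integer seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_residents = 648, n_drpts = 9,
                          first_drpt_date = as.Date("2013-09-15"),
                          drpt_interval_days = 183,
                          attendance = 0.82,
                          fullruns = list(b0 = 20.19, b_tr = -0.94,
                                          b_diff = 6.70, sigma2_e = 81.56,
                                          sigma2_u0 = 10.84),
                          relarea = list(b0 = 53.16, b_tr = 1.70,
                                         b_diff = -57.47, sigma2_e = 133.04,
                                         sigma2_u0 = 5.30),
                          accuracy = list(b0 = -1.078, b_tr = 0.338,
                                          b_fullruns = 0.001,
                                          b_relarea = 0.003, b_diff = 5.093,
                                          sigma2_u0 = 0.056),
                          drpt_diff = list(mean = 0.14, sd = 0.07,
                                           min = 0.02, max = 0.24),
                          seed = NULL) {
  stopifnot(n_residents >= 2, n_drpts >= 1,
            attendance > 0, attendance <= 1)
  structure(
    list(n_residents = n_residents, n_drpts = n_drpts,
         first_drpt_date = first_drpt_date,
         drpt_interval_days = drpt_interval_days,
         attendance = attendance, fullruns = fullruns, relarea = relarea,
         accuracy = accuracy, drpt_diff = drpt_diff, seed = seed),
    class = "cohort_params")
}

#' Simulate a macro-level cohort of test records
#'
#' Generates resident-by-test records directly from the two-level growth
#' models (no scroll logs): per resident a random intercept per outcome,
#' per attended test Gaussian outcomes
#' `b0 + b_tr * tr_time + b_diff * drpt_diff + u0 + e` for both scroll
#' metrics, and a binomial `n_correct` out of `n_questions` with
#' logit-linear predictor using the accuracy coefficients. Gaussian
#' outcomes live on the model scale and are not truncated to `[0, 100]`
#' (the fitted model is linear and unbounded; truncation would bias
#' parameter recovery).
#'
#' @param params A [cohort_params()].
#' @return Tibble of records (as from [aggregate_to_drpt()]) with
#'   attributes `truth` (the generating parameters), `residents` and
#'   `drpts` tables.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  dates <- p$first_drpt_date + (seq_len(p$n_drpts) - 1) * p$drpt_interval_days
  dd <- pmin(pmax(rnorm(p$n_drpts, p$drpt_diff$mean, p$drpt_diff$sd),
                  p$drpt_diff$min), p$drpt_diff$max)
  prog_days <- 5 * 365.25
  span <- as.numeric(dates[p$n_drpts] - p$first_drpt_date)

  res_id <- sprintf("R%04d", seq_len(p$n_residents))
  drpt_id <- sprintf("T%02d", seq_len(p$n_drpts))
  starts <- p$first_drpt_date - prog_days +
    round(runif(p$n_residents, 0, span + prog_days - 1))
  ends <- starts + round(prog_days)

  u_f <- rnorm(p$n_residents, 0, sqrt(p$fullruns$sigma2_u0))
  u_r <- rnorm(p$n_residents, 0, sqrt(p$relarea$sigma2_u0))
  u_a <- rnorm(p$n_residents, 0, sqrt(p$accuracy$sigma2_u0))

  rows <- vector("list", p$n_residents)
  for (i in seq_len(p$n_residents)) {
    elig <- which(dates > starts[i] & dates <= ends[i])
    if (length(elig) == 0) next
    L <- max(1L, rbinom(1, length(elig), p$attendance))
    off <- sample.int(length(elig) - L + 1L, 1) - 1L
    att <- elig[(1 + off):(off + L)]
    tr <- training_time(dates[att], starts[i], ends[i])
    y_f <- p$fullruns$b0 + p$fullruns$b_tr * tr + p$fullruns$b_diff * dd[att] +
      u_f[i] + rnorm(L, 0, sqrt(p$fullruns$sigma2_e))
    y_r <- p$relarea$b0 + p$relarea$b_tr * tr + p$relarea$b_diff * dd[att] +
      u_r[i] + rnorm(L, 0, sqrt(p$relarea$sigma2_e))
    nq <- 2L + rbinom(L, 7, 3 / 7)           # 2..9 questions, mean 5
    eta <- p$accuracy$b0 + p$accuracy$b_tr * tr + p$accuracy$b_diff * dd[att] +
      p$accuracy$b_fullruns * y_f + p$accuracy$b_relarea * y_r + u_a[i]
    rows[[i]] <- tibble::tibble(
      resident_id = res_id[i], drpt_id = drpt_id[att], tr_time = tr,
      drpt_diff = dd[att], perc_time_full_runs_avg = y_f,
      perc_time_rel_area_avg = y_r,
      n_correct = rbinom(L, nq, plogis(eta)), n_questions = nq)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "truth") <- list(params = p, drpt_diff = setNames(dd, drpt_id))
  attr(out, "residents") <- tibble::tibble(
    resident_id = res_id, start_date = as.character(starts),
    end_date = as.character(ends))
  attr(out, "drpts") <- tibble::tibble(drpt_id = drpt_id,
                                       date = as.character(dates))
  out
}

#' Simulate a micro-level cohort: scroll logs plus cohort tables
#'
#' Composes [simulate_cohort()] with [simulate_trajectory()]: each
#' resident's test-level generated metrics become per-question trajectory
#' targets (clamped into the feasible range of the question's geometry),
#' and answers are drawn from the accuracy model, yielding a complete
#' fixture — roster, test, question, region and answer tables plus one
#' scroll log per answered question — that the full
#' parse-metrics-aggregate-fit pipeline can consume.
#'
#' Unlike the macro records, all residents of a test answer the same
#' question set, whose size per test is drawn from the 2-9 (mean 5) range.
#'
#' @param params A [cohort_params()]; use small `n_residents`/`n_drpts`
#'   for quick fixtures.
#' @param trajectory A [trajectory_params()] providing timing/noise
#'   settings; targets are overridden per question.
#' @param dir Optional directory: when given, cohort tables and logfiles
#'   are written there (see [write_cohort()], [write_question_log()]).
#' @return List with `cohort` (a `cohort_tables` list), `logs` (list of
#'   [question_log()]), and `records` (the macro records driving the
#'   generation), invisibly when `dir` is given.
#' @export
simulate_micro_cohort <- function(params = cohort_params(n_residents = 12,
                                                         n_drpts = 3),
                                  trajectory = trajectory_params(),
                                  dir = NULL) {
  mac <- simulate_cohort(params)
  residents <- attr(mac, "residents")
  drpts <- attr(mac, "drpts")
  dd <- attr(mac, "truth")$drpt_diff

  # question set per test
  qrows <- list(); rrows <- list()
  for (j in seq_along(drpts$drpt_id)) {
    Q <- 2L + rbinom(1, 7, 3 / 7)
    N <- sample(24:60, Q, replace = TRUE)
    frac <- runif(Q, 0.10, 0.35)
    len <- pmax(1L, round(frac * N))
    lo <- vapply(N - len, function(m) sample.int(m, 1), integer(1))
    fmt <- sample(c("marker", "multiple_choice", "long_list"), Q,
                  replace = TRUE, prob = c(2, 32, 14))
    pv <- rnorm(Q, 0, 0.08)
    pv <- pmin(pmax(pv - mean(pv) + dd[j] + 0.5, 0.05), 0.95)
    qid <- sprintf("%s_Q%02d", drpts$drpt_id[j], seq_len(Q))
    qrows[[j]] <- tibble::tibble(
      question_id = qid, format = fmt, subdomain = "general",
      p_value = round(pv, 4), requires_diagnosis = TRUE, single_ct = TRUE,
      n_slices_x = NA_integer_, n_slices_y = NA_integer_, n_slices_z = N)
    rrows[[j]] <- tibble::tibble(question_id = qid, axis = "z", lo = lo,
                                 hi = lo + len - 1L)
  }
  questions <- do.call(rbind, qrows)
  regions <- do.call(rbind, rrows)

  # pre-build each question's geometry and region once
  geom_by_q <- list(); reg_by_q <- list()
  for (j in seq_along(qrows)) {
    for (q in seq_len(nrow(qrows[[j]]))) {
      qid <- qrows[[j]]$question_id[q]
      geom_by_q[[qid]] <- volume_geometry(c(z = qrows[[j]]$n_slices_z[q]))
      reg_by_q[[qid]] <- relevant_region(
        data.frame(axis = "z", lo = rrows[[j]]$lo[q], hi = rrows[[j]]$hi[q]))
    }
  }

  acc <- params$accuracy
  mac_res <- mac$resident_id
  mac_drpt <- mac$drpt_id
  mac_tr <- mac$tr_time
  mac_f <- mac$perc_time_full_runs_avg
  mac_r <- mac$perc_time_rel_area_avg
  n_total <- sum(vapply(match(mac_drpt, drpts$drpt_id),
                        function(j) nrow(qrows[[j]]), integer(1)))
  logs <- vector("list", n_total)
  a_res <- character(n_total); a_drpt <- character(n_total)
  a_q <- character(n_total); a_corr <- integer(n_total)
  pos <- 0L
  noise_f <- trajectory$noise_sd[["full_runs"]]
  noise_r <- trajectory$noise_sd[["rel_area"]]
  tp <- trajectory
  tp$noise_sd <- c(full_runs = 0, rel_area = 0)
  tp$seed <- NULL                          # inherit the RNG stream
  for (i in seq_along(mac_res)) {
    j <- match(mac_drpt[i], drpts$drpt_id)
    qs <- qrows[[j]]; rg <- rrows[[j]]
    eta <- acc$b0 + acc$b_tr * mac_tr[i] + acc$b_diff * dd[j] +
      acc$b_fullruns * mac_f[i] + acc$b_relarea * mac_r[i]
    for (q in seq_len(nrow(qs))) {
      # question-level jitter is applied here, then clamped into the
      # feasible target box of this question's geometry, so the trajectory
      # generator (run with zero extra noise) never sees infeasible targets
      fr <- (rg$hi[q] - rg$lo[q] + 1) / qs$n_slices_z[q]
      p_f <- min(max(mac_f[i] + rnorm(1, 0, noise_f), 1), 80)
      lo_r <- p_f * fr + 2
      hi_r <- 100 - p_f * (1 - fr) - 2
      p_r <- min(max(mac_r[i] + rnorm(1, 0, noise_r), lo_r), hi_r)
      tp$geometry <- geom_by_q[[qs$question_id[q]]]
      tp$relevant <- reg_by_q[[qs$question_id[q]]]
      tp$target_perc_full_runs <- p_f
      tp$target_perc_rel_area <- p_r
      pos <- pos + 1L
      logs[[pos]] <- simulate_trajectory(tp, resident_id = mac_res[i],
                                         drpt_id = mac_drpt[i],
                                         question_id = qs$question_id[q])
      a_res[pos] <- mac_res[i]
      a_drpt[pos] <- mac_drpt[i]
      a_q[pos] <- qs$question_id[q]
      a_corr[pos] <- rbinom(1, 1, plogis(eta))
    }
  }
  cohort <- structure(
    list(residents = residents, drpts = drpts, questions = questions,
         regions = regions,
         answers = tibble::tibble(resident_id = a_res, drpt_id = a_drpt,
                                  question_id = a_q, correct = a_corr)),
    class = "cohort_tables")
  cohort$residents$start_date <- as.Date(cohort$residents$start_date)
  cohort$residents$end_date <- as.Date(cohort$residents$end_date)
  cohort$drpts$date <- as.Date(cohort$drpts$date)
  out <- list(cohort = cohort, logs = logs, records = mac)
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    for (log in logs) {
      write_question_log(log, file.path(dir, question_log_filename(
        log$resident_id, log$drpt_id, log$question_id)))
    }
    return(invisible(out))
  }
  out
}
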