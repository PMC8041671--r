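#' Construct a model-fit summary object
#'
#' Container for the results of one two-level model: fixed effects
#' (coefficient, standard error, p value, and — for logistic models —
#' odds ratio with 95% confidence interval), variance components,
#' full-maximum-likelihood deviance, and a convergence flag. Usually
#' produced by [fit_lmm_ladder()] / [fit_binomial_ladder()], but can be
#' built directly from a published coefficient table to compute derived
#' quantities with [marginal_effect()].
#'
#' @param fixed Data frame with at least `term` and `b`; `se`, `p`, `or`,
#'   `ci_lo`, `ci_hi` are filled in when absent (odds ratios only for
#'   binomial fits).
#' @param var List with elements `sigma2_e` (level-1 residual variance;
#'   `NA` for binomial fits, where the level-1 variance is fixed by the
#'   binomial assumption), `sigma2_u0` (random-intercept variance) and
#'   optionally `sigma2_u1` (random-slope variance).
#' @param deviance `-2 * logLik` under full ML.
#' @param df Number of estimated parameters (for likelihood-ratio tests).
#' @param family `"gaussian"` or `"binomial"`.
#' @param label Short model label.
#' @param converged Logical.
#' @param fit Optional underlying `merMod` object.
#' @param n_obs,n_groups Optional sample sizes.
#' @return A `model_fit` object.
#' @export
model_fit <- function(fixed, var = list(sigma2_e = NA_real_,
                                        sigma2_u0 = NA_real_),
                      deviance = NA_real_, df = NA_integer_,
                      family = c("gaussian", "binomial"), label = "model",
                      converged = TRUE, fit = NULL,
                      n_obs = NA_integer_, n_groups = NA_integer_) {
  family <- match.arg(family)
  fixed <- tibble::as_tibble(fixed)
  stopifnot(all(c("term", "b") %in% names(fixed)))
  has <- function(col) col %in% names(fixed)
  if (!has("se")) fixed$se <- NA_real_
  if (!has("p")) fixed$p <- 2 * pnorm(-abs(fixed$b / fixed$se))
  if (family == "binomial") {
    if (!has("or")) fixed$or <- exp(fixed$b)
    if (!has("ci_lo")) fixed$ci_lo <- exp(fixed$b - qnorm(.975) * fixed$se)
    if (!has("ci_hi")) fixed$ci_hi <- exp(fixed$b + qnorm(.975) * fixed$se)
  }
  structure(
    list(label = label, family = family, fixed = fixed, var = var,
         deviance = deviance, df = df, converged = converged, fit = fit,
         n_obs = n_obs, n_groups = n_groups),
    class = "model_fit")
}

#' @exportS3Method base::print
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s (%s), deviance %.1f%s\n", x$label, x$family,
              x$deviance, if (x$converged) "" else " [not converged]"))
  print(as.data.frame(x$fixed), digits = 3)
  v <- unlist(x$var)
  v <- v[!is.na(v)]
  if (length(v) > 0) {
    cat("variance components:",
        paste(sprintf("%s = %.3f", names(v), v), collapse = ", "), "\n")
  }
  invisible(x)
}

# Cluster-robust (CR0 sandwich) covariance of the fixed effects of a
# Gaussian lmer fit, clustered on the fit's (first) grouping factor.
# bread = (sum_g X_g' V_g^-1 X_g)^-1, meat = sum_g u_g u_g' with
# u_g = X_g' V_g^-1 (y_g - X_g beta) and V_g = sigma^2 (Z L L' Z' + I)_g.
cluster_robust_vcov <- function(fit) {
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  r <- as.numeric(y - X %*% lme4::fixef(fit))
  A <- lme4::getME(fit, "Lambdat") %*% lme4::getME(fit, "Zt")  # q x n
  s2 <- lme4::getME(fit, "sigma")^2
  grp <- fit@flist[[1]]
  p <- ncol(X)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (idx in split(seq_along(grp), grp, drop = TRUE)) {
    Vg <- s2 * (as.matrix(Matrix::crossprod(A[, idx, drop = FALSE])) +
                  diag(length(idx)))
    # degenerate zero-variance fits: keep V_g invertible
    diag(Vg) <- diag(Vg) + 1e-10
    Xg <- X[idx, , drop = FALSE]
    W <- solve(Vg)
    B <- B + t(Xg) %*% W %*% Xg
    u <- t(Xg) %*% W %*% r[idx]
    M <- M + u %*% t(u)
  }
  Binv <- solve(B)
  Binv %*% M %*% Binv
}

var_components <- function(fit) {
  vc <- lme4::VarCorr(fit)
  g <- vc[[1]]
  out <- list(sigma2_e = if (lme4::isLMM(fit)) sigma(fit)^2 else NA_real_,
              sigma2_u0 = unname(g["(Intercept)", "(Intercept)"]))
  if (nrow(g) > 1) {
    slope <- setdiff(rownames(g), "(Intercept)")[1]
    out$sigma2_u1 <- unname(g[slope, slope])
    out$cov_u01 <- unname(g["(Intercept)", slope])
  }
  out
}

# boundary (singular) fits count as converged: a variance component on
# the zero boundary is a legitimate ML solution, not an optimizer failure.
# A max|grad| warning is rescued when the Hessian-scaled relative gradient
# is tiny (the usual false alarm with covariates on very different scales).
converged_ok <- function(fit) {
  if (fit@optinfo$conv$opt != 0) return(FALSE)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("unable to evaluate", msgs))) return(FALSE)
  if (any(grepl("failed to converge", msgs))) {
    dd <- fit@optinfo$derivs
    relgrad <- tryCatch(max(abs(solve(dd$Hessian, dd$gradient))),
                        error = function(e) Inf)
    return(is.finite(relgrad) && relgrad < 1e-3)
  }
  TRUE
}

as_model_fit <- function(fit, label, family, robust = FALSE,
                         converged = NULL) {
  b <- lme4::fixef(fit)
  vc <- if (robust) cluster_robust_vcov(fit) else as.matrix(vcov(fit))
  se <- sqrt(diag(vc))
  fixed <- tibble::tibble(term = names(b), b = unname(b), se = unname(se))
  mf <- model_fit(
    fixed = fixed,
    var = var_components(fit),
    deviance = as.numeric(-2 * logLik(fit)),
    df = attr(logLik(fit), "df"),
    family = family,
    label = label,
    converged = converged %||% converged_ok(fit),
    fit = fit,
    n_obs = nrow(fit@frame),
    n_groups = nlevels(fit@flist[[1]]))
  mf
}

#' Fit the two-level Gaussian model ladder for a scroll metric
#'
#' Fits, by full maximum likelihood, the nested sequence of two-level
#' models for a test-level averaged scroll metric (occasions at level 1,
#' residents at level 2):
#' * Model 0 — unconditional means: intercept + random resident intercept;
#' * Model 1 — adds a fixed effect of relative training time (`tr_time`);
#' * Model 2 — adds a fixed effect of test difficulty (`drpt_diff`);
#' * Model 3 — adds a random `tr_time` slope per resident (unstructured
#'   2x2 intercept-slope covariance).
#'
#' Standard errors of fixed effects are cluster-robust (CR0 sandwich) at
#' the resident level by default, guarding against non-normal level-1
#' residuals; p values use the normal approximation. A non-converging
#' model is flagged and the ladder continues.
#'
#' @param records Test-level records (see [aggregate_to_drpt()] or
#'   [simulate_cohort()]).
#' @param outcome `"perc_time_full_runs_avg"` or
#'   `"perc_time_rel_area_avg"`.
#' @param robust Use cluster-robust standard errors (default `TRUE`).
#' @return List of four [model_fit()] objects.
#' @export
fit_lmm_ladder <- function(records,
                           outcome = c("perc_time_full_runs_avg",
                                       "perc_time_rel_area_avg"),
                           robust = TRUE) {
  outcome <- match.arg(outcome)
  records <- records[!is.na(records[[outcome]]) & !is.na(records$tr_time), ]
  if (length(unique(records$resident_id)) < 2 || nrow(records) < 2) {
    stop("need records for at least two residents", call. = FALSE)
  }
  forms <- list(
    "Model 0" = paste(outcome, "~ 1 + (1 | resident_id)"),
    "Model 1" = paste(outcome, "~ tr_time + (1 | resident_id)"),
    "Model 2" = paste(outcome, "~ tr_time + drpt_diff + (1 | resident_id)"),
    "Model 3" = paste(outcome, "~ tr_time + drpt_diff + (tr_time | resident_id)"))
  lapply(names(forms), function(lbl) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(as.formula(forms[[lbl]]), data = records, REML = FALSE))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(model_fit(fixed = tibble::tibble(term = character(),
                                              b = numeric()),
                       family = "gaussian", label = lbl, converged = FALSE))
    }
    as_model_fit(fit, lbl, "gaussian", robust = robust)
  })
}

#' Fit the two-level binomial (logit) model ladder for diagnostic accuracy
#'
#' The number of questions correct out of the number of questions per test
#' is modelled as binomial with a logit link, a random resident intercept,
#' and level-1 variance fixed by the binomial assumption. The ladder is:
#' Model 0 — intercept only; Model 1 — adds `tr_time`; Model 2 — adds
#' `drpt_diff`, `perc_time_full_runs_avg` and `perc_time_rel_area_avg`;
#' Model 3 — adds a random `tr_time` slope. Estimation uses adaptive
#' Gauss-Hermite quadrature with `nAGQ` nodes for scalar random effects
#' (the random-slope model falls back to the Laplace approximation, the
#' best `glmer` offers for vector random effects). Odds ratios and 95%
#' Wald confidence intervals are reported. Fits showing signs of complete
#' separation (exploding estimates) are flagged as non-converged and are
#' skipped by [select_best()].
#'
#' @param records Test-level records with `n_correct` and `n_questions`.
#' @param nAGQ Number of quadrature nodes (default 20).
#' @return List of four [model_fit()] objects.
#' @export
fit_binomial_ladder <- function(records, nAGQ = 20) {
  records <- records[!is.na(records$tr_time) & records$n_questions >= 1, ]
  forms <- list(
    "Model 0" = "cbind(n_correct, n_questions - n_correct) ~ 1 + (1 | resident_id)",
    "Model 1" = "cbind(n_correct, n_questions - n_correct) ~ tr_time + (1 | resident_id)",
    "Model 2" = paste("cbind(n_correct, n_questions - n_correct) ~ tr_time +",
                      "drpt_diff + perc_time_full_runs_avg +",
                      "perc_time_rel_area_avg + (1 | resident_id)"),
    "Model 3" = paste("cbind(n_correct, n_questions - n_correct) ~ tr_time +",
                      "drpt_diff + perc_time_full_runs_avg +",
                      "perc_time_rel_area_avg + (tr_time | resident_id)"))
  lapply(names(forms), function(lbl) {
    agq <- if (lbl == "Model 3") 1L else as.integer(nAGQ)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::glmer(as.formula(forms[[lbl]]), data = records,
                    family = stats::binomial(), nAGQ = agq))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(model_fit(fixed = tibble::tibble(term = character(),
                                              b = numeric()),
                       family = "binomial", label = lbl, converged = FALSE))
    }
    mf <- as_model_fit(fit, lbl, "binomial", robust = FALSE)
    # complete separation: intercept/effects running off to +-Inf
    if (any(abs(mf$fixed$b) > 15 & mf$fixed$term == "(Intercept)") ||
        any(mf$fixed$se > 50, na.rm = TRUE)) {
      mf$converged <- FALSE
    }
    mf
  })
}

#' Select the best-fitting model of a nested ladder
#'
#' Forward selection by likelihood-ratio test on full-ML deviance
#' differences: each successive converged model is adopted iff it reduces
#' the deviance significantly at level `alpha` relative to the currently
#' selected model (degrees of freedom = difference in parameter counts).
#' Ties and non-significant extensions keep the simpler model;
#' non-converged fits are skipped.
#'
#' @param ladder List of nested [model_fit()]s, simplest first.
#' @param alpha Significance level (default 0.05).
#' @return The selected [model_fit()].
#' @export
select_best <- function(ladder, alpha = 0.05) {
  ok <- which(vapply(ladder, function(m) isTRUE(m$converged), logical(1)))
  if (length(ok) == 0) stop("no converged model in the ladder", call. = FALSE)
  best <- ladder[[ok[1]]]
  for (i in ok[-1]) {
    cand <- ladder[[i]]
    d_dev <- best$deviance - cand$deviance
    d_df <- cand$df - best$df
    if (d_df > 0 && d_dev > 0 &&
        pchisq(d_dev, d_df, lower.tail = FALSE) < alpha) {
      best <- cand
    }
  }
  best
}

#' Level-1 explained variance relative to the unconditional means model
#'
#' The proportional reduction of the level-1 (within-resident) residual
#' variance of a fitted model relative to its unconditional means model:
#' `(sigma2_e_null - sigma2_e_fit) / sigma2_e_null`, floored at 0. Only
#' defined for Gaussian fits.
#'
#' @param fit,null_fit Converged [model_fit()]s on the same records;
#'   `null_fit` is the intercept-only model.
#' @return A proportion in `[0, 1]`.
#' @export
level1_r2 <- function(fit, null_fit) {
  if (!isTRUE(fit$converged) || !isTRUE(null_fit$converged)) {
    stop("both fits must have converged", call. = FALSE)
  }
  s0 <- null_fit$var$sigma2_e
  s1 <- fit$var$sigma2_e
  if (is.na(s0) || is.na(s1)) stop("level-1 variance unavailable",
                                   call. = FALSE)
  if (s0 == 0) stop("null model has zero level-1 variance; R2 undefined",
                    call. = FALSE)
  max(0, (s0 - s1) / s0)
}

#' Outcome-scale effect of a change in a predictor
#'
#' For a Gaussian model the effect of increasing `predictor` by `delta` is
#' `b * delta` on the outcome scale (percent points for the scroll
#' metrics). For a binomial model it is the multiplicative change in the
#' odds, `exp(b)^delta = OR^delta`.
#'
#' @param fit A [model_fit()].
#' @param predictor Name of a fixed-effect term in the fit.
#' @param delta Change in the predictor.
#' @return Numeric effect on the outcome (Gaussian) or odds (binomial)
#'   scale.
#' @examples
#' m <- model_fit(data.frame(term = "drpt_diff", b = 6.70, se = 2.35))
#' marginal_effect(m, "drpt_diff", 0.1) # 0.67 percent points
#' @export
marginal_effect <- function(fit, predictor, delta) {
  i <- match(predictor, fit$fixed$term)
  if (is.na(i)) stop("unknown predictor: ", predictor, call. = FALSE)
  b <- fit$fixed$b[i]
  if (fit$family == "binomial") exp(b)^delta else b * delta
}
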