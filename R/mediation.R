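#' Z-score columns of a table
#'
#' Centers each column to mean 0 and scales it to (sample) SD 1, computed
#' over all included rows. Variables are scaled like this before mediation
#' so path estimates are comparable in strength.
#'
#' @param table A data frame.
#' @param columns Character vector of numeric columns to standardize.
#' @return The table with the columns replaced by their z-scores.
#' @export
standardize <- function(table, columns) {
  for (cl in columns) {
    x <- table[[cl]]
    if (!is.numeric(x)) stop(sprintf("column `%s` is not numeric", cl),
                             call. = FALSE)
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("column `%s` has zero variance", cl), call. = FALSE)
    table[[cl]] <- (x - mean(x)) / s
  }
  table
}

#' Model specification for the mediation system
#'
#' Declares one of the three models of the mediation system: `M0` (outcome
#' on treatment, ignoring the mediator), `M` (mediator on treatment) and
#' `Y` (outcome on mediator + treatment); all carry a random subject
#' intercept.
#'
#' @param role `"M0"`, `"M"` or `"Y"`.
#' @param outcome Outcome column name.
#' @param treatment Treatment column (repetition number).
#' @param mediator Mediator column (pre-stimulus power); required for `Y`,
#'   must be the outcome of `M`, and absent from `M0`.
#' @param group Random-intercept grouping column (default `"subject"`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(role = c("M0", "M", "Y"), outcome, treatment,
                       mediator = NULL, group = "subject") {
  role <- match.arg(role)
  if (role == "Y" && is.null(mediator))
    stop("model Y requires a mediator", call. = FALSE)
  if (role == "M0" && !is.null(mediator))
    stop("model M0 must not include the mediator", call. = FALSE)
  if (role == "M" && !is.null(mediator) && !identical(outcome, mediator))
    stop("model M's outcome must be the mediator", call. = FALSE)
  structure(list(role = role, outcome = outcome, treatment = treatment,
                 mediator = if (role == "Y") mediator else NULL,
                 group = group),
            class = "model_spec")
}

#' Model formula of a mediation model specification
#'
#' Builds the `lme4` formula `outcome ~ [mediator +] treatment +
#' (1 | group)` from a [model_spec()].
#'
#' @param spec A [model_spec()].
#' @return A formula.
#' @export
lmm_formula <- function(spec) {
  rhs <- c(spec$mediator, spec$treatment)
  as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + "),
                   "+ (1 |", spec$group, ")"))
}

#' Fit a linear mixed model for the mediation system
#'
#' Random-intercept LMM via `lme4::lmer` (REML), with the formula built
#' from a [model_spec()]. When the random-intercept variance is estimated
#' at (or numerically indistinguishable from) zero the fit falls back to
#' OLS with a warning. Wald 95% confidence intervals; p-values use the
#' normal approximation to the t statistic.
#'
#' @param table Data frame with the spec's columns.
#' @param spec A [model_spec()].
#' @param require_levels Minimum number of grouping levels for a random
#'   intercept (default 5).
#' @return Object of class `lmm_fit`: `fixed` (tibble: term, estimate,
#'   std_error, ci_lower, ci_upper, statistic, p_value), `random_sd`,
#'   `singular`, `fallback_ols`, `spec`, and the underlying `model`.
#' @export
fit_lmm <- function(table, spec, require_levels = 5) {
  stopifnot(inherits(spec, "model_spec"))
  n_levels <- dplyr::n_distinct(table[[spec$group]])
  if (n_levels < require_levels)
    stop(sprintf("random intercept needs >= %d grouping levels (got %d)",
                 require_levels, n_levels), call. = FALSE)
  fit_lmm_impl(table, spec, warn = TRUE)
}

fit_lmm_impl <- function(table, spec, warn = FALSE) {
  form <- lmm_formula(spec)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  model <- suppressMessages(lme4::lmer(form, data = table, REML = TRUE,
                                       control = ctrl))
  re_sd <- sqrt(unname(unlist(lme4::VarCorr(model)))[1])
  singular <- lme4::isSingular(model, tol = 1e-6)
  fallback <- FALSE
  if (re_sd < 1e-8) {
    if (warn)
      warning("random-intercept variance estimated at zero; using OLS",
              call. = FALSE)
    fallback <- TRUE
    fixed_form <- as.formula(paste(spec$outcome, "~",
                                   paste(c(spec$mediator, spec$treatment),
                                         collapse = " + ")))
    model <- lm(fixed_form, data = table)
    est <- summary(model)$coefficients
    fixed <- tibble::tibble(term = rownames(est), estimate = est[, 1],
                            std_error = est[, 2], statistic = est[, 3],
                            p_value = est[, 4])
  } else {
    est <- coef(summary(model))
    fixed <- tibble::tibble(term = rownames(est), estimate = est[, 1],
                            std_error = est[, 2], statistic = est[, 3],
                            p_value = 2 * pnorm(-abs(est[, 3])))
  }
  fixed$ci_lower <- fixed$estimate - 1.959964 * fixed$std_error
  fixed$ci_upper <- fixed$estimate + 1.959964 * fixed$std_error
  structure(list(fixed = fixed[, c("term", "estimate", "std_error",
                                   "ci_lower", "ci_upper", "statistic",
                                   "p_value")],
                 random_sd = if (fallback) 0 else re_sd,
                 singular = singular, fallback_ols = fallback,
                 spec = spec, model = model),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit %s> %s; random-intercept SD %.4f%s\n", x$spec$role,
              deparse(lmm_formula(x$spec)), x$random_sd,
              if (x$fallback_ols) " (OLS fallback)" else ""))
  print(x$fixed)
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) x$fixed

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(role = x$spec$role, random_sd = x$random_sd,
                 singular = x$singular, fallback_ols = x$fallback_ols,
                 nobs = length(residuals(x$model)))
}

coef_of <- function(fit, term) {
  i <- match(term, fit$fixed$term)
  list(est = fit$fixed$estimate[i], se = fit$fixed$std_error[i],
       p = fit$fixed$p_value[i])
}

#' Causal mediation analysis on the M/Y model system
#'
#' Fits the mediation system (`M`: mediator ~ treatment, `Y`: outcome ~
#' mediator + treatment, both with a random subject intercept) and computes
#' the average causal mediation effect (ACME `= a*b`), average direct
#' effect (ADE `= c'`), total effect (`ACME + ADE`, exact in this linear
#' no-interaction system) and proportion mediated, with percentile
#' confidence intervals.
#'
#' Uncertainty is quantified either by a nonparametric cluster bootstrap
#' (`ci_method = "bootstrap"`: subjects resampled with replacement, both
#' models refit per draw -- the primary method, since both models carry
#' subject random intercepts) or by quasi-Bayesian Monte-Carlo draws from
#' the asymptotic sampling distribution of the fixed effects
#' (`ci_method = "montecarlo"`, the classical simulation estimator; also
#' serves as an independent cross-check of the bootstrap). Bootstrap
#' p-values are twice the proportion of draws crossing zero, capped at 1.
#'
#' Before the analysis the premise of a treatment effect in model M0 or M
#' is checked; failure is reported as a warning, not an error. Inconsistent
#' mediation (ACME and ADE of opposite signs, i.e. the mediator suppresses
#' or reverses the direct effect) is flagged.
#'
#' @param table Data frame (typically standardized; see [standardize()]).
#' @param outcome,treatment,mediator,group Column names.
#' @param n_draws Number of bootstrap / Monte-Carlo draws (default 1000).
#' @param ci_method `"bootstrap"` or `"montecarlo"`.
#' @param seed Integer seed for the draws.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `mediation_result` with point estimates, CI
#'   bounds, p-values, flags (`inconsistent_mediation`,
#'   `prop_mediated_undefined`), the fitted `model_m` / `model_y` /
#'   `model_m0`, draw matrix and bookkeeping (failed draws).
#' @export
mediate <- function(table, outcome, treatment = "repetition", mediator,
                    group = "subject", n_draws = 1000,
                    ci_method = c("bootstrap", "montecarlo"), seed = 1L,
                    conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  spec_m0 <- model_spec("M0", outcome, treatment, group = group)
  spec_m <- model_spec("M", mediator, treatment, group = group)
  spec_y <- model_spec("Y", outcome, treatment, mediator, group = group)
  fit_m0 <- fit_lmm(table, spec_m0)
  fit_m <- fit_lmm(table, spec_m)
  fit_y <- fit_lmm(table, spec_y)

  premise_ok <- coef_of(fit_m0, treatment)$p < 0.05 ||
    coef_of(fit_m, treatment)$p < 0.05
  if (!premise_ok)
    warning("no treatment effect in model M0 or M: mediation premise fails",
            call. = FALSE)

  a <- coef_of(fit_m, treatment)$est
  b <- coef_of(fit_y, mediator)$est
  cp <- coef_of(fit_y, treatment)$est
  acme <- a * b
  ade <- cp
  total <- acme + ade

  withr::local_seed(seed)
  n_failed <- 0L
  if (ci_method == "bootstrap") {
    subjects <- unique(table[[group]])
    ns <- length(subjects)
    by_subj <- split(seq_len(nrow(table)), table[[group]])
    draws <- matrix(NA_real_, n_draws, 2,
                    dimnames = list(NULL, c("acme", "ade")))
    for (i in seq_len(n_draws)) {
      pick <- sample(ns, ns, replace = TRUE)
      idx <- unlist(by_subj[pick], use.names = FALSE)
      boot <- table[idx, , drop = FALSE]
      # resampled copies of a subject become distinct clusters
      boot[[group]] <- rep(seq_len(ns), lengths(by_subj[pick]))
      est <- tryCatch({
        fm <- fit_lmm_impl(boot, spec_m)
        fy <- fit_lmm_impl(boot, spec_y)
        c(coef_of(fm, treatment)$est * coef_of(fy, mediator)$est,
          coef_of(fy, treatment)$est)
      }, error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else draws[i, ] <- est
    }
    draws <- draws[!is.na(draws[, 1]), , drop = FALSE]
  } else {
    # quasi-Bayesian: sample fixed effects from their asymptotic normal
    a_i <- rnorm(n_draws, a, coef_of(fit_m, treatment)$se)
    vc <- as.matrix(vcov(fit_y$model))
    rn <- rownames(vc)
    sel <- match(c(mediator, treatment), rn)
    ch <- chol(vc[sel, sel])
    z <- matrix(rnorm(2 * n_draws), n_draws, 2) %*% ch
    b_i <- b + z[, 1]
    cp_i <- cp + z[, 2]
    draws <- cbind(acme = a_i * b_i, ade = cp_i)
  }
  total_i <- draws[, "acme"] + draws[, "ade"]

  alpha <- (1 - conf_level) / 2
  ci <- function(v) quantile(v, c(alpha, 1 - alpha), names = FALSE)
  pval <- function(v) min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  prop_undefined <- abs(total) < 0.01
  prop <- if (prop_undefined) NA_real_ else acme / total

  structure(list(
    acme = acme, ade = ade, total = total, prop_mediated = prop,
    acme_ci = ci(draws[, "acme"]), ade_ci = ci(draws[, "ade"]),
    total_ci = ci(total_i),
    prop_ci = if (prop_undefined) c(NA_real_, NA_real_) else
      ci(draws[, "acme"] / total_i),
    acme_p = pval(draws[, "acme"]), ade_p = pval(draws[, "ade"]),
    total_p = pval(total_i),
    inconsistent_mediation = sign(acme) * sign(ade) < 0,
    prop_mediated_undefined = prop_undefined,
    premise_ok = premise_ok, ci_method = ci_method,
    n_draws = n_draws, n_failed_draws = n_failed, seed = seed,
    conf_level = conf_level,
    model_m0 = fit_m0, model_m = fit_m, model_y = fit_y,
    draws = draws,
    columns = c(outcome = outcome, treatment = treatment,
                mediator = mediator, group = group)),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (%s, %d draws)\n",
              x$columns["treatment"], x$columns["mediator"],
              x$columns["outcome"], x$ci_method, x$n_draws))
  print(tidy(x))
  if (x$inconsistent_mediation)
    cat("note: inconsistent mediation (ACME and ADE have opposite signs)\n")
  invisible(x)
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(x$acme, x$ade, x$total, x$prop_mediated),
    ci_lower = c(x$acme_ci[1], x$ade_ci[1], x$total_ci[1], x$prop_ci[1]),
    ci_upper = c(x$acme_ci[2], x$ade_ci[2], x$total_ci[2], x$prop_ci[2]),
    p_value = c(x$acme_p, x$ade_p, x$total_p, NA_real_)
  )
}

#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(ci_method = x$ci_method, n_draws = x$n_draws,
                 n_failed_draws = x$n_failed_draws,
                 premise_ok = x$premise_ok,
                 inconsistent_mediation = x$inconsistent_mediation,
                 prop_mediated_undefined = x$prop_mediated_undefined,
                 seed = x$seed)
}
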