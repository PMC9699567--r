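#' Fit the longitudinal visual-acuity mixed model
#'
#' Fits, by maximum likelihood (ML, not REML, so that models with
#' different fixed-effect sets are comparable by AIC/BIC), the linear
#' mixed model
#' \deqn{Y_i = X_i \beta + Z_i u_i + \varepsilon_i}
#' with a correlated per-subject random intercept and time slope,
#' `(time_weeks | subject_id)`. Rows with a missing response are dropped
#' (and counted); predictor columns must be complete (post-imputation).
#'
#' When `weight` is supplied (the stacked multiple-imputation case) the
#' total log-likelihood is scaled by that scalar: the ML point estimates
#' are unchanged, the reported log-likelihood equals `weight` times the
#' unweighted one, and the fixed-effect covariance is inflated by
#' `1/weight` — exactly the behaviour required of an observation weight
#' that multiplies every observation's log-likelihood contribution.
#'
#' @param table A complete (or response-only-missing) `cohort_table`, or
#'   any data.frame with `subject_id`, `time_weeks` and the columns named.
#' @param predictors Character vector of fixed-effect predictor names
#'   (empty for the null model).
#' @param response Response column (default the table's response
#'   attribute, `"va_response"`).
#' @param weight Optional scalar observation weight in (0, 1].
#' @param pin_slope_on_failure If the full random structure fails to
#'   converge, refit with the slope variance pinned to zero (random
#'   intercept only); the fit is flagged.
#' @return An `lmm_fit`: coefficients with standard errors, random-effect
#'   (co)variances, residual variance, log-likelihood, parameter count
#'   `K` (fixed coefficients + 3 covariance parameters + residual
#'   variance), fitted values at both population and subject level,
#'   convergence/singularity flags, and the underlying `merMod`.
#' @export
fit_lmm <- function(table, predictors = character(0),
                    response = NULL, weight = NULL,
                    pin_slope_on_failure = TRUE) {
  df <- as.data.frame(table)
  response <- response %||% attr(table, "response") %||% "va_response"
  if (response %in% predictors)
    stop_invalid("response cannot be among the predictors")
  miss <- setdiff(c(response, predictors, "subject_id", "time_weeks"),
                  colnames(df))
  if (length(miss))
    stop_invalid("missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(weight) && (weight <= 0 || weight > 1))
    stop_invalid("weight must be a scalar in (0, 1]")

  keep <- !is.na(df[[response]])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (length(predictors)) {
    bad <- predictors[vapply(df[predictors], anyNA, logical(1))]
    if (length(bad))
      stop_invalid("predictor(s) with missing values (impute first): %s",
                   paste(bad, collapse = ", "))
  }
  if (length(unique(df$subject_id)) < 2)
    stop_invalid("need at least 2 subjects")
  types <- attr(table, "predictor_types")
  for (nm in predictors)
    if (!is.null(types) && identical(types[[nm]], "categorical"))
      df[[nm]] <- factor(df[[nm]])

  rhs <- if (length(predictors))
    paste(predictors, collapse = " + ") else "1"
  fml <- as.formula(paste0(response, " ~ ", rhs,
                           " + (time_weeks | subject_id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = df, REML = FALSE, control = ctrl))),
    error = function(e) e)
  slope_pinned <- FALSE
  if (inherits(fit, "error") && pin_slope_on_failure) {
    fml2 <- as.formula(paste0(response, " ~ ", rhs, " + (1 | subject_id)"))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(fml2, data = df, REML = FALSE, control = ctrl))),
      error = function(e) e)
    slope_pinned <- TRUE
  }
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, error = conditionMessage(fit),
                          formula = fml, n_obs = nrow(df)),
                     class = "lmm_fit"))
  }

  w <- weight %||% 1
  ll <- as.numeric(logLik(fit)) * w
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit)) / w
  se <- sqrt(diag(V))
  vc <- lme4::VarCorr(fit)
  vs <- vc$subject_id
  var_int <- vs["(Intercept)", "(Intercept)"]
  var_slope <- if ("time_weeks" %in% rownames(vs))
    vs["time_weeks", "time_weeks"] else 0
  cov_is <- if ("time_weeks" %in% rownames(vs))
    vs["(Intercept)", "time_weeks"] else 0
  K <- length(beta) + length(lme4::getME(fit, "theta")) + 1L

  structure(list(
    formula = fml,
    beta = beta,
    se = se,
    vcov = V,
    var_components = c(intercept = var_int, slope = var_slope,
                       intercept_slope_cov = cov_is,
                       residual = stats::sigma(fit)^2),
    loglik = ll,
    K = K,
    n_obs = nrow(df),
    n_groups = lme4::ngrps(fit)[["subject_id"]],
    n_dropped_response = n_dropped,
    fitted = unname(stats::fitted(fit)),
    fitted_population = unname(predict(fit, re.form = NA)),
    converged = TRUE,
    singular = lme4::isSingular(fit),
    slope_pinned = slope_pinned,
    weight = w,
    predictors = predictors,
    response = response,
    data = df,
    model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<lmm_fit> NON-CONVERGED:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("<lmm_fit> %s\n", deparse(x$formula)))
  cat(sprintf("  ML loglik %.3f | K = %d | n = %d obs, %d subjects%s\n",
              x$loglik, x$K, x$n_obs, x$n_groups,
              if (x$weight != 1) sprintf(" | weight %.4f", x$weight) else ""))
  est <- cbind(Estimate = x$beta, `Std.Error` = x$se)
  print(round(est, 4))
  cat(sprintf("  random effects: var(intercept) %.3f, var(slope) %.5f, resid var %.3f\n",
              x$var_components["intercept"], x$var_components["slope"],
              x$var_components["residual"]))
  invisible(x)
}

#' Information criteria of a fitted mixed model
#'
#' `AIC = -2 logL + 2K`, `BIC = -2 logL + K log(n)`. For clustered
#' longitudinal data the effective sample size for BIC is ambiguous; the
#' default uses the number of subjects (grouping units), not rows.
#'
#' @param fit A converged `lmm_fit`.
#' @param n_for_bic Sample size for the BIC penalty (default: number of
#'   groups in the fit).
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit, n_for_bic = NULL) {
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  n <- n_for_bic %||% fit$n_groups
  if (n < 2) stop_invalid("n_for_bic must be >= 2")
  c(AIC = -2 * fit$loglik + 2 * fit$K,
    BIC = -2 * fit$loglik + log(n) * fit$K)
}

#' Marginal and conditional R-squared (variance-decomposition form)
#'
#' @param sigma_f2 Variance of the fixed-effect linear predictor.
#' @param sigma_l2 Summed random-effect variance.
#' @param sigma_e2 Residual variance.
#' @param sigma_d2 Distribution-specific variance (0 for the Gaussian
#'   identity-link model).
#' @return Named vector `c(R2_marginal, R2_conditional)`.
#' @export
r2_components <- function(sigma_f2, sigma_l2, sigma_e2, sigma_d2 = 0) {
  tot <- sigma_f2 + sigma_l2 + sigma_e2 + sigma_d2
  if (tot <= 0) stop_invalid("total variance is zero; R2 undefined")
  c(R2_marginal = sigma_f2 / tot,
    R2_conditional = (sigma_f2 + sigma_l2) / tot)
}

#' Nakagawa marginal and conditional R-squared of a mixed-model fit
#'
#' The fixed-effect variance is the variance of the fixed linear
#' predictor over the fitted rows. With a random slope the random-effect
#' variance is the average diagonal of \eqn{Z \Sigma Z'} (the mean
#' per-row random-effect variance, which reduces to the intercept
#' variance when the slope variance is zero). The distribution-specific
#' variance is zero for this Gaussian identity-link model.
#'
#' @param fit A converged `lmm_fit`.
#' @return Named vector `c(R2_marginal, R2_conditional)`; the variance
#'   components are attached as an attribute `"components"`.
#' @export
r2_nakagawa <- function(fit) {
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  sigma_f2 <- stats::var(fit$fitted_population)
  v <- fit$var_components
  t_ <- fit$data$time_weeks
  sigma_l2 <- mean(v["intercept"] + 2 * t_ * v["intercept_slope_cov"] +
                     t_^2 * v["slope"])
  sigma_l2 <- max(sigma_l2, 0)
  out <- r2_components(sigma_f2, sigma_l2, v[["residual"]])
  attr(out, "components") <- c(sigma_f2 = unname(sigma_f2),
                               sigma_l2 = unname(sigma_l2),
                               sigma_e2 = v[["residual"]])
  out
}

#' Predictions from a fitted mixed model
#'
#' Population-level predictions use the fixed effects only; subject-level
#' predictions add the empirical best linear unbiased predictions of each
#' subject's random intercept and slope. Subjects unseen at fit time fall
#' back to the population prediction.
#'
#' @param fit A converged `lmm_fit`.
#' @param table New data (default: the data used to fit).
#' @param level `"subject"` (default) or `"population"`.
#' @return Numeric vector of predicted ETDRS letters.
#' @export
predict_fitted <- function(fit, table = NULL,
                           level = c("subject", "population")) {
  level <- match.arg(level)
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  newdata <- if (is.null(table)) fit$data else as.data.frame(table)
  types <- attr(table, "predictor_types")
  for (nm in fit$predictors)
    if (!is.null(types) && identical(types[[nm]], "categorical"))
      newdata[[nm]] <- factor(newdata[[nm]])
  unname(predict(fit$model, newdata = newdata,
                 re.form = if (level == "population") NA else NULL,
                 allow.new.levels = TRUE))
}
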