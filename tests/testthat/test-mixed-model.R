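test_that("noise-free data are interpolated exactly", {
  g <- noise_free_cohort()
  fit <- fit_lmm(g$table, "time_weeks")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), c(10, 0.5), tolerance = 1e-6)
  expect_lt(max(abs(fit$fitted - as.data.frame(g$table)$va_response)), 1e-6)
})

test_that("with zero random-effect variances the fit matches OLS", {
  # dense within-subject sampling lets ML push both random variances to
  # the boundary, where the GLS and OLS estimators coincide
  cc <- cohort_config(n_subjects = 100, visit_weeks = seq(0, 104, by = 8),
                      true_fixed_effects = c("(Intercept)" = 40,
                                             baseline_va_le = 0.3,
                                             time_weeks = 0.05),
                      random_intercept_sd = 0, random_slope_sd = 0,
                      intercept_slope_corr = 0, residual_sd = 4,
                      missingness_rates = c(), seed = 3)
  g <- generate_cohort(cc)
  fit <- fit_lmm(g$table, c("baseline_va_le", "time_weeks"))
  expect_lt(fit$var_components[["intercept"]], 1e-6)
  expect_lt(fit$var_components[["slope"]], 1e-8)
  ols <- lm(va_response ~ baseline_va_le + time_weeks,
            data = as.data.frame(g$table))
  rel <- abs(fit$beta - coef(ols)) / pmax(abs(coef(ols)), 1e-8)
  expect_true(all(rel < 1e-4))
})

test_that("fixed effects are recovered on average over replicates", {
  truth <- c("(Intercept)" = 30, baseline_va_le = 0.4, time_weeks = 0.05)
  n_rep <- 40
  est <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    g <- small_cohort(n = 150, seed = 1000 + r, effects = truth)
    est[r, ] <- fit_lmm(g$table, c("baseline_va_le", "time_weeks"))$beta
  }
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-10))
})

test_that("rows with missing response are dropped and counted", {
  g <- small_cohort(n = 20, seed = 3)
  df <- as.data.frame(g$table)
  df$va_response[c(1, 7, 30)] <- NA
  tab <- rivlmm:::new_cohort_table(df, attr(g$table, "predictor_types"),
                                   visit_weeks = attr(g$table, "visit_weeks"))
  fit <- fit_lmm(tab, "time_weeks")
  expect_equal(fit$n_dropped_response, 3)
  expect_equal(fit$n_obs, nrow(df) - 3)
  df$baseline_va_le[2] <- NA
  tab2 <- rivlmm:::new_cohort_table(df, attr(g$table, "predictor_types"),
                                    visit_weeks = attr(g$table, "visit_weeks"))
  expect_error(fit_lmm(tab2, "baseline_va_le"), "impute")
})

test_that("information criteria evaluate their closed forms", {
  fake <- structure(list(loglik = -500, K = 5, n_groups = 150,
                         converged = TRUE), class = "lmm_fit")
  ic <- information_criteria(fake)
  expect_equal(ic[["AIC"]], 1010)
  expect_equal(ic[["BIC"]], 1000 + 5 * log(150), tolerance = 1e-9)
  expect_equal(information_criteria(fake, n_for_bic = 750)[["BIC"]],
               1000 + 5 * log(750), tolerance = 1e-9)
  fake0 <- structure(list(loglik = -123.4, K = 0, n_groups = 10,
                          converged = TRUE), class = "lmm_fit")
  expect_equal(information_criteria(fake0)[["AIC"]], 246.8)
  expect_error(information_criteria(fake, n_for_bic = 1), ">= 2")
})

test_that("reported AIC/BIC equal independent recomputation", {
  g <- small_cohort(n = 40, seed = 14)
  fit <- fit_lmm(g$table, c("baseline_va_le", "time_weeks"))
  ic <- information_criteria(fit)
  expect_equal(ic[["AIC"]], -2 * fit$loglik + 2 * fit$K, tolerance = 1e-9)
  expect_equal(ic[["BIC"]], -2 * fit$loglik + log(fit$n_groups) * fit$K,
               tolerance = 1e-9)
  # K = fixed coefficients + 3 covariance parameters + residual variance
  expect_equal(fit$K, length(fit$beta) + 4)
})

test_that("R2 components evaluate the variance-ratio formulas", {
  r2 <- r2_components(3, 1, 1)
  expect_equal(unname(r2), c(0.6, 0.8))
  expect_equal(unname(r2_components(2, 0, 1)),
               c(2 / 3, 2 / 3))              # no random variance: R2m = R2c
  expect_error(r2_components(0, 0, 0), "undefined")
})

test_that("Nakagawa R2 behaves on real fits", {
  g <- small_cohort(n = 60, seed = 15)
  fit <- fit_lmm(g$table, c("baseline_va_le", "time_weeks"))
  r2 <- r2_nakagawa(fit)
  expect_gte(r2[["R2_conditional"]], r2[["R2_marginal"]])
  expect_gte(r2[["R2_marginal"]], 0)
  expect_lte(r2[["R2_conditional"]], 1)
  null_fit <- fit_lmm(g$table, character(0))
  expect_equal(r2_nakagawa(null_fit)[["R2_marginal"]], 0, tolerance = 1e-10)
})

test_that("population and subject-level predictions are coherent", {
  cc <- cohort_config(n_subjects = 30,
                      true_fixed_effects = c("(Intercept)" = 50),
                      random_intercept_sd = 0, random_slope_sd = 0,
                      intercept_slope_corr = 0, residual_sd = 0,
                      missingness_rates = c(), seed = 16)
  g <- generate_cohort(cc)
  fit <- fit_lmm(g$table, character(0))
  pop <- predict_fitted(fit, level = "population")
  expect_true(all(abs(pop - 50) < 1e-6))

  g2 <- small_cohort(n = 30, seed = 17)
  fit2 <- fit_lmm(g2$table, c("baseline_va_le", "time_weeks"))
  expect_equal(predict_fitted(fit2, level = "subject"), fit2$fitted,
               tolerance = 1e-12)

  g3 <- noise_free_cohort()
  fit3 <- fit_lmm(g3$table, "time_weeks")
  expect_lt(max(abs(predict_fitted(fit3, level = "subject") -
                      as.data.frame(g3$table)$va_response)), 1e-6)
})

test_that("unseen subjects fall back to population predictions", {
  g <- small_cohort(n = 25, seed = 18)
  df <- as.data.frame(g$table)
  train <- df[df$subject_id != "S001", ]
  tab <- rivlmm:::new_cohort_table(train, attr(g$table, "predictor_types"),
                                   visit_weeks = attr(g$table, "visit_weeks"))
  fit <- fit_lmm(tab, c("baseline_va_le", "time_weeks"))
  new <- df[df$subject_id == "S001", ]
  ps <- predict_fitted(fit, new, level = "subject")
  pp <- predict_fitted(fit, new, level = "population")
  expect_equal(ps, pp, tolerance = 1e-12)
})

test_that("a scalar observation weight scales the loglik exactly", {
  g <- small_cohort(n = 40, seed = 19)
  fit1 <- fit_lmm(g$table, c("baseline_va_le", "time_weeks"))
  w <- 0.3
  fitw <- fit_lmm(g$table, c("baseline_va_le", "time_weeks"), weight = w)
  expect_equal(fitw$loglik, w * fit1$loglik, tolerance = 1e-10)
  expect_equal(fitw$beta, fit1$beta, tolerance = 1e-12)
  expect_equal(fitw$se, fit1$se / sqrt(w), tolerance = 1e-10)
})

test_that("log-likelihood is monotone in nested fixed-effect sets", {
  g <- small_cohort(n = 50, seed = 20,
                    effects = c("(Intercept)" = 30, baseline_va_le = 0.4,
                                time_weeks = 0.05, age = -0.1))
  sets <- list(character(0), "time_weeks",
               c("time_weeks", "baseline_va_le"),
               c("time_weeks", "baseline_va_le", "age"))
  ll <- vapply(sets, function(s) fit_lmm(g$table, s)$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})
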