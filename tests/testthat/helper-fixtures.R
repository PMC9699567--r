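# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# A compact cohort with a handful of informative predictors, cheap enough
# for refit-heavy diagnostics.
small_cohort <- function(n = 30, seed = 1, residual_sd = 4,
                         intercept_sd = 6, slope_sd = 0.03,
                         effects = c("(Intercept)" = 30,
                                     baseline_va_le = 0.4,
                                     time_weeks = 0.05)) {
  cc <- cohort_config(n_subjects = n,
                      true_fixed_effects = effects,
                      random_intercept_sd = intercept_sd,
                      random_slope_sd = slope_sd,
                      residual_sd = residual_sd,
                      missingness_rates = c(),
                      seed = seed)
  generate_cohort(cc)
}

# Deterministic cohort: no noise of any kind, response is exactly the
# fixed linear predictor.
noise_free_cohort <- function(n = 20, seed = 2,
                              effects = c("(Intercept)" = 10,
                                          time_weeks = 0.5)) {
  cc <- cohort_config(n_subjects = n,
                      true_fixed_effects = effects,
                      random_intercept_sd = 0, random_slope_sd = 0,
                      intercept_slope_corr = 0, residual_sd = 0,
                      missingness_rates = c(), seed = seed)
  generate_cohort(cc)
}

# A cohort where one candidate has a strong standardized effect, one is
# pure noise: the discrimination setting for importance tests. The
# "strong" predictor contributes 0.8 residual SDs per SD of the
# predictor; "noise" contributes nothing.
contrast_cohort <- function(n = 150, seed = 1, residual_sd = 4,
                            strong_beta = 0.8 * 4 / 24) {
  cc <- cohort_config(
    n_subjects = n,
    true_fixed_effects = c("(Intercept)" = 45,
                           baseline_va_le = strong_beta,
                           time_weeks = 0.04),
    random_intercept_sd = 8, random_slope_sd = 0.05,
    residual_sd = residual_sd,
    missingness_rates = c(), seed = seed)
  generate_cohort(cc)
}

# Minimal hand-built search_result over candidates {A, B} whose four
# models ({}, {A}, {B}, {A,B}) can be assigned arbitrary weights.
toy_search_result <- function(coefs_A = c(3, 2), coef_B = 1) {
  space <- enumerate_model_space(c("A", "B"))
  subsets <- vapply(1:4, function(i) paste(space[[i]], collapse = ";"),
                    character(1))
  models <- data.frame(model_id = 1:4, subset = subsets,
                       n_predictors = c(0, 1, 1, 2),
                       loglik = 0, K = 4, AIC = c(10, 10, 10, 10),
                       BIC = NA, converged = TRUE, singular = FALSE,
                       stringsAsFactors = FALSE)
  coefs <- list(c("(Intercept)" = 0),
                c("(Intercept)" = 0, A = coefs_A[1]),
                c("(Intercept)" = 0, B = coef_B),
                c("(Intercept)" = 0, A = coefs_A[2], B = coef_B))
  structure(list(models = models, coefs = coefs, space = space,
                 candidates = c("A", "B"), response = "y",
                 n_for_bic = 10, best_aic = 1, best_bic = 1),
            class = "search_result")
}
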