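test_that("generated marginals match their configured distributions", {
  cc <- cohort_config(n_subjects = 5000, seed = 42)
  g <- generate_cohort(cc)
  df <- as.data.frame(g$table)
  subj <- df[!duplicated(df$subject_id), ]
  expect_lt(abs(mean(subj$age) - 78.9), 0.3)
  expect_lt(abs(sd(subj$age) - 7.3), 0.3)
  expect_lt(abs(mean(subj$gender) - 0.567), 0.025)
  expect_lt(abs(mean(subj$treatment_drug) - 0.813), 0.02)
})

test_that("generation is deterministic given the seed", {
  cc <- cohort_config(n_subjects = 40, seed = 9)
  g1 <- generate_cohort(cc)
  g2 <- generate_cohort(cc)
  expect_identical(as.data.frame(g1$table), as.data.frame(g2$table))
  expect_identical(g1$truth$random_effects, g2$truth$random_effects)
  g3 <- generate_cohort(cohort_config(n_subjects = 40, seed = 10))
  expect_false(identical(as.data.frame(g1$table), as.data.frame(g3$table)))
})

test_that("noise-free response equals the fixed linear predictor", {
  g <- noise_free_cohort()
  df <- as.data.frame(g$table)
  expect_equal(df$va_response, 10 + 0.5 * df$time_weeks, tolerance = 1e-12)
  expect_equal(df$va_response, g$truth$fixed_part, tolerance = 1e-12)
})

test_that("residual variance decomposition holds at scale", {
  s <- 4
  cc <- cohort_config(n_subjects = 2000,
                      true_fixed_effects = c("(Intercept)" = 50),
                      random_intercept_sd = 0, random_slope_sd = 0,
                      intercept_slope_corr = 0, residual_sd = s,
                      missingness_rates = c(), seed = 77)
  g <- generate_cohort(cc)
  resid <- as.data.frame(g$table)$va_response - g$truth$fixed_part
  expect_gte(length(resid), 1e4)
  expect_lt(abs(sd(resid) - s) / s, 0.05)
})

test_that("clipping to the ETDRS scale is rare under the default truth", {
  g <- generate_cohort(cohort_config(n_subjects = 2000, seed = 5))
  expect_lt(g$truth$clipped / (2000 * 5), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_subjects = 0), "positive")
  expect_error(cohort_config(visit_weeks = numeric(0)), "non-empty")
  expect_error(cohort_config(visit_weeks = c(13, 26)), "start at 0")
  expect_error(cohort_config(visit_weeks = c(0, 26, 13)), "increasing")
  expect_error(cohort_config(residual_sd = -1), ">= 0")
  expect_error(cohort_config(intercept_slope_corr = 1.2), "corr")
  expect_error(cohort_config(missingness_rates = c(age = 1.5)), "\\[0, 1\\]")
  expect_error(cohort_config(missingness_rates = c(nope = 0.1)), "unknown")
})

test_that("masking reproduces the configured rates", {
  g <- generate_cohort(cohort_config(n_subjects = 10000, seed = 3,
                                     missingness_rates = c()))
  m <- apply_missingness(g$table, c(treatment_drug = 0.356), seed = 3)
  df <- as.data.frame(m)
  frac <- mean(tapply(is.na(df$treatment_drug), df$subject_id, any))
  expect_lt(abs(frac - 0.356), 0.015)

  # binomial 3-SE tolerance across several columns
  rates <- c(haemorrhage = 0.248, ped = 0.2067, diabetes = 0.0467)
  m2 <- apply_missingness(g$table, rates, seed = 4)
  df2 <- as.data.frame(m2)
  for (nm in names(rates)) {
    fr <- mean(tapply(is.na(df2[[nm]]), df2$subject_id, any))
    tol <- 3 * sqrt(rates[[nm]] * (1 - rates[[nm]]) / 10000)
    expect_lt(abs(fr - rates[[nm]]), tol)
  }
})

test_that("masking edge rates behave exactly", {
  g <- generate_cohort(cohort_config(n_subjects = 25, seed = 8,
                                     missingness_rates = c()))
  m0 <- apply_missingness(g$table, c(irf = 0, cmt = 0), seed = 1)
  expect_equal(as.data.frame(m0), as.data.frame(g$table),
               ignore_attr = TRUE)
  expect_false(anyNA(as.data.frame(m0)))
  m1 <- apply_missingness(g$table, c(irf = 1), seed = 1)
  df <- as.data.frame(m1)
  expect_true(all(is.na(df$irf)))
  expect_false(anyNA(df[, setdiff(colnames(df), "irf")]))
  expect_error(apply_missingness(g$table, c(irf = 1.2)), "\\[0, 1\\]")
  expect_error(apply_missingness(g$table, c(va_response = 0.1)), "masked")
})

test_that("MAR masking preserves the marginal rate but tracks the covariate", {
  g <- generate_cohort(cohort_config(n_subjects = 4000, seed = 13,
                                     missingness_rates = c()))
  m <- apply_missingness(g$table, c(cmt = 0.2), seed = 5,
                         mar_covariate = "age")
  df <- as.data.frame(m)
  subj <- df[!duplicated(df$subject_id), ]
  orig <- as.data.frame(g$table)
  orig <- orig[!duplicated(orig$subject_id), ]
  hi <- orig$age > median(orig$age)
  miss <- is.na(subj$cmt)
  expect_lt(abs(mean(miss) - 0.2), 0.025)
  expect_gt(mean(miss[hi]), mean(miss[!hi]) + 0.15)
})

test_that("long-wide reshape is a lossless round trip", {
  g <- generate_cohort(cohort_config(n_subjects = 150, seed = 21,
                                     missingness_rates = c()))
  expect_equal(nrow(g$table), 750)
  w <- reshape_cohort(g$table, "wide")
  expect_equal(nrow(w), 150)
  expect_length(grep("^va_response_w", colnames(w)), 5)
  back <- reshape_cohort(w, "long")
  orig <- as.data.frame(g$table)
  rt <- as.data.frame(back)[, colnames(orig)]
  key <- function(d) d[order(d$subject_id, d$time_weeks), ]
  expect_equal(key(rt), key(orig), ignore_attr = TRUE)
})

test_that("single-subject reshape carries identical content either way", {
  g <- generate_cohort(cohort_config(n_subjects = 1, visit_weeks = 0,
                                     missingness_rates = c(), seed = 2))
  w <- reshape_cohort(g$table, "wide")
  expect_equal(nrow(w), 1)
  expect_equal(w$va_response_w0, as.data.frame(g$table)$va_response)
  back <- reshape_cohort(w, "long")
  expect_equal(as.data.frame(back)$va_response,
               as.data.frame(g$table)$va_response)
})

test_that("duplicate keys are refused when widening", {
  g <- generate_cohort(cohort_config(n_subjects = 3, missingness_rates = c(),
                                     seed = 1))
  df <- as.data.frame(g$table)
  dup <- rbind(df, df[1, ])
  tab <- rivlmm:::new_cohort_table(dup, attr(g$table, "predictor_types"),
                                   visit_weeks = attr(g$table, "visit_weeks"))
  expect_error(reshape_cohort(tab, "wide"), "duplicate")
})

test_that("cohort CSV round trip preserves values and missingness", {
  g <- generate_cohort(cohort_config(n_subjects = 10, seed = 30))
  m <- apply_missingness(g$table, c(irf = 0.3, cmt = 0.3), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_cohort(m, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(m),
               ignore_attr = TRUE)
  expect_identical(attr(back, "layout"), "long")
  unlink(c(path, paste0(path, ".meta.json")))
})
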