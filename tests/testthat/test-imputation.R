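test_that("EM on complete data returns the sample mean and ML covariance", {
  set.seed(1)
  X <- matrix(rnorm(200), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  fit <- em_fit(X)
  expect_equal(fit$iterations, 1L)
  expect_equal(fit$mu, colMeans(X))
  n <- nrow(X)
  expect_equal(fit$sigma, crossprod(sweep(X, 2, colMeans(X))) / n,
               tolerance = 1e-12)
})

test_that("EM recovers the correlation under 30% MCAR", {
  set.seed(2)
  n <- 2000
  z1 <- rnorm(n); z2 <- rnorm(n)
  X <- cbind(x = z1, y = 0.8 * z1 + sqrt(1 - 0.8^2) * z2)
  Xm <- X
  Xm[runif(n) < 0.3, 2] <- NA
  fit <- em_fit(Xm)
  rho <- fit$sigma[1, 2] / sqrt(fit$sigma[1, 1] * fit$sigma[2, 2])
  expect_lt(abs(rho - 0.8), 0.05)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(400), ncol = 4)
    X[sample(length(X), 80)] <- NA
    X[1, ] <- rnorm(4)   # keep at least one fully observed row
    fit <- em_fit(X)
    expect_true(all(diff(fit$loglik) >= -1e-8))
    expect_true(fit$converged)
  }
})

test_that("EM refuses a fully missing column", {
  X <- cbind(a = rnorm(10), b = NA_real_)
  expect_error(em_fit(X), "fully missing")
})

test_that("EMB imputation completes every copy and preserves observed cells", {
  g <- generate_cohort(cohort_config(n_subjects = 150, seed = 4))
  m <- apply_missingness(g$table, default_missingness_rates(), seed = 4)
  imps <- impute_emb(m, m = 5, seed = 4)
  expect_equal(imps$m, 5)
  expect_equal(imps$p, 19)
  orig <- as.data.frame(m)
  for (cp in imps$copies) {
    d <- as.data.frame(cp)
    expect_equal(nrow(d), nrow(orig))
    expect_false(anyNA(d))
    for (col in colnames(orig)) {
      obs <- !is.na(orig[[col]])
      expect_identical(d[[col]][obs], orig[[col]][obs])
    }
  }
})

test_that("imputed cells vary across copies when data are missing", {
  g <- generate_cohort(cohort_config(n_subjects = 120, seed = 6))
  m <- apply_missingness(g$table, c(cmt = 0.3), seed = 6)
  imps <- impute_emb(m, m = 5, seed = 6)
  orig <- as.data.frame(m)
  nav <- which(is.na(orig$cmt))
  draws <- sapply(imps$copies, function(cp) as.data.frame(cp)$cmt[nav])
  between_var <- apply(draws, 1, var)
  expect_true(all(between_var > 0))
})

test_that("a complete table imputes to identical copies", {
  g <- generate_cohort(cohort_config(n_subjects = 30, seed = 7,
                                     missingness_rates = c()))
  imps <- impute_emb(g$table, m = 3, seed = 1)
  expect_equal(imps$f, 0)
  for (cp in imps$copies)
    expect_identical(as.data.frame(cp), as.data.frame(g$table))
})

test_that("categorical and binary imputations land on legal levels", {
  g <- generate_cohort(cohort_config(n_subjects = 200, seed = 8))
  m <- apply_missingness(g$table, c(smoking_status = 0.3, irf = 0.3,
                                    treatment_drug = 0.3), seed = 8)
  imps <- impute_emb(m, m = 3, seed = 8)
  for (cp in imps$copies) {
    d <- as.data.frame(cp)
    expect_true(all(d$smoking_status %in%
                      c("never", "past", "present", "rarely")))
    expect_true(all(d$irf %in% 0:1))
    expect_true(all(d$treatment_drug %in% 0:1))
  }
})

test_that("stacking applies the missing-information weight", {
  g <- generate_cohort(cohort_config(n_subjects = 150, seed = 9))
  m <- apply_missingness(g$table, default_missingness_rates(), seed = 9)
  imps <- impute_emb(m, m = 5, seed = 9)
  # recompute f independently from the masked table
  df <- as.data.frame(m)
  vars <- names(attr(m, "predictor_types"))
  miss <- vapply(vars, function(nm)
    sum(tapply(is.na(df[[nm]]), df$subject_id, any)), numeric(1))
  f_expected <- sum(miss) / (150 * 19)
  expect_equal(imps$f, f_expected, tolerance = 1e-12)

  st <- stack_imputations(imps)
  expect_equal(nrow(st), 5 * nrow(df))
  expect_equal(attr(st, "w"), (1 - imps$f) / 5, tolerance = 1e-12)
  expect_equal(sort(unique(as.data.frame(st)$copy)), 1:5)
})

test_that("stacking weight evaluates the closed form", {
  # 300 missing cells over a 150 x 19 grid, m = 5
  f <- 300 / (150 * 19)
  expect_equal(round(f, 6), 0.105263)
  expect_equal(round((1 - f) / 5, 6), 0.178947)
  # no missing data: w = 1/m; a single copy stacks to itself with w = 1
  g <- generate_cohort(cohort_config(n_subjects = 20, seed = 2,
                                     missingness_rates = c()))
  imps <- impute_emb(g$table, m = 5, seed = 2)
  expect_equal(attr(stack_imputations(imps), "w"), 0.2)
  one <- structure(list(m = 1L, copies = list(g$table), mask = NULL,
                        f = 0, n = 20, p = 19, seed = 1),
                   class = "imputation_set")
  st1 <- stack_imputations(one)
  expect_equal(attr(st1, "w"), 1)
  d1 <- as.data.frame(st1)
  d1$subject_id <- d1$source_subject   # copies are distinct individuals
  expect_equal(d1[, colnames(g$table)], as.data.frame(g$table),
               ignore_attr = TRUE)
})

test_that("Rubin's rules pool estimates and variances correctly", {
  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$variance, 1 + (1 + 1 / 3) * 1, tolerance = 1e-12)
  p2 <- rubin_pool(c(5, 5, 5), c(0.5, 0.7, 0.9))
  expect_equal(p2$variance, 0.7)          # B = 0
  p3 <- rubin_pool(c(0, 0), c(2, 4))
  expect_equal(p3$estimate, 0)
  expect_equal(p3$variance, 3)
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("pooled and weighted-stacked fixed effects agree", {
  g <- generate_cohort(cohort_config(n_subjects = 150, seed = 11))
  m <- apply_missingness(g$table, default_missingness_rates(), seed = 11)
  imps <- impute_emb(m, m = 5, seed = 11)
  preds <- c("baseline_va_le", "time_weeks", "cmt")
  fits <- lapply(imps$copies, fit_lmm, predictors = preds)
  est <- t(sapply(fits, `[[`, "beta"))
  pooled <- rubin_pool(est, t(sapply(fits, function(f) f$se^2)))
  st <- stack_imputations(imps)
  sfit <- fit_lmm(st, preds)
  rel <- abs(pooled$estimate - sfit$beta) /
    pmax(abs(pooled$estimate), abs(sfit$beta))
  expect_true(all(rel < 0.10))
})
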