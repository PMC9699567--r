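#' Default marginal specifications for the 19 candidate predictors
#'
#' Returns the per-variable marginal distributions used by
#' [generate_cohort()]: continuous variables as mean/SD, binary variables as
#' the probability of the positive level, and categorical variables as level
#' probabilities. The defaults emulate a treatment-naive neovascular AMD
#' cohort followed over two years of anti-VEGF therapy: age 78.9 +/- 7.3
#' years, baseline visual acuity 53.5 +/- 24.0 (left eye) and 48.4 +/- 24.3
#' (right eye) ETDRS letters, 56.7% female, 68% hypertensive, 81.3% treated
#' with ranibizumab, and so on. `time_weeks` is listed for completeness but
#' is generated from the visit schedule, not from a marginal.
#'
#' @return Named list of specs; each spec is a list with `type`
#'   (`"continuous"`, `"binary"`, `"categorical"`) and either `mean`/`sd`
#'   (plus optional `lower`/`upper` bounds and `integer` flag) or
#'   `levels`/`probs`.
#' @export
default_predictor_specs <- function() {
  list(
    age                = list(type = "continuous", mean = 78.9, sd = 7.3),
    baseline_va_le     = list(type = "continuous", mean = 53.5, sd = 24.0,
                              lower = 0, upper = 100),
    baseline_va_re     = list(type = "continuous", mean = 48.4, sd = 24.3,
                              lower = 0, upper = 100),
    cmt                = list(type = "continuous", mean = 300, sd = 60,
                              lower = 100),
    diabetes           = list(type = "binary", prob = 0.175),
    ethnicity_maternal = list(type = "categorical",
                              levels = c("european", "asian", "other"),
                              probs = c(0.70, 0.15, 0.15)),
    ethnicity_paternal = list(type = "categorical",
                              levels = c("european", "asian", "other"),
                              probs = c(0.70, 0.15, 0.15)),
    gender             = list(type = "binary", prob = 0.567),
    haemorrhage        = list(type = "binary", prob = 0.60),
    hypertension       = list(type = "binary", prob = 0.68),
    irf                = list(type = "binary", prob = 0.78),
    ped                = list(type = "binary", prob = 0.55),
    smokerpacks        = list(type = "continuous", mean = 39.1, sd = 28.7,
                              lower = 0),
    smoking_status     = list(type = "categorical",
                              levels = c("never", "past", "present", "rarely"),
                              probs = c(0.368, 0.444, 0.132, 0.056)),
    srf                = list(type = "binary", prob = 0.778),
    time_weeks         = list(type = "continuous", mean = NA, sd = NA),
    treated_eye        = list(type = "binary", prob = 0.573),
    treatment_drug     = list(type = "binary", prob = 0.813),
    treatment_quantity = list(type = "continuous", mean = 8, sd = 3,
                              lower = 1, integer = TRUE)
  )
}

#' Default ground-truth fixed effects for the synthetic cohort
#'
#' Coefficients (ETDRS letters per unit of the encoded predictor) of the
#' data-generating mixed model. The ten predictors of the default
#' prediction model carry non-zero effects; the remaining candidates are
#' pure noise, which is what makes recovery and importance-discrimination
#' tests meaningful.
#'
#' @return Named numeric vector including an `(Intercept)` term.
#' @export
default_true_effects <- function() {
  c("(Intercept)"      = 20,
    baseline_va_le     = 0.55,
    baseline_va_re     = 0.05,
    irf                = -3,
    cmt                = -0.02,
    time_weeks         = 0.04,
    treatment_quantity = 0.3,
    treatment_drug     = 1.5,
    treated_eye        = 2,
    haemorrhage        = -2,
    ped                = -1.5)
}

#' Default missingness rates by variable
#'
#' Missing-completely-at-random rates matching the profile of the study
#' cohort: no missingness in the treated eye, age, gender, hypertension,
#' smoker pack-years or baseline acuities; light missingness in demographics
#' and treatment counts; substantial missingness in the OCT-derived
#' variables, peaking at 35.6% for the treatment drug.
#'
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
default_missingness_rates <- function() {
  c(ethnicity_paternal = 0.02,
    ethnicity_maternal = 0.0133,
    smoking_status     = 0.04,
    diabetes           = 0.0467,
    time_weeks         = 0.048,
    treatment_quantity = 0.052,
    srf                = 0.1813,
    irf                = 0.1827,
    cmt                = 0.1947,
    ped                = 0.2067,
    haemorrhage        = 0.248,
    treatment_drug     = 0.356)
}

#' Candidate predictor names
#'
#' The 19 candidate predictors considered by the exhaustive model search.
#'
#' @return Character vector of length 19.
#' @export
candidate_predictors <- function() {
  setdiff(names(default_predictor_specs()), character(0))
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates everything [generate_cohort()] needs: cohort size,
#' the visit schedule, predictor marginals, the ground-truth fixed effects,
#' random-effect and residual standard deviations, missingness rates and a
#' seed. Defaults describe a 150-subject cohort measured at baseline and at
#' 3, 6, 12 and 24 months (weeks 0, 13, 26, 52, 104), with a per-subject
#' random intercept (SD 8 letters) and random time slope (SD 0.05
#' letters/week), residual SD 4 letters.
#'
#' @param n_subjects Number of subjects (one treated eye each).
#' @param visit_weeks Strictly increasing visit times in weeks, starting at 0.
#' @param predictor_specs See [default_predictor_specs()].
#' @param true_fixed_effects Named coefficient vector; see
#'   [default_true_effects()]. Categorical variables may carry a named
#'   per-level offset vector instead of a scalar.
#' @param random_intercept_sd,random_slope_sd,residual_sd Standard
#'   deviations in letters (slope: letters/week); all must be `>= 0`.
#' @param intercept_slope_corr Correlation of the random intercept and
#'   slope, in `[-1, 1]`.
#' @param missingness_rates Named rates in `[0, 1]`; see
#'   [default_missingness_rates()].
#' @param seed Integer seed controlling the whole generation.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 150,
                          visit_weeks = c(0, 13, 26, 52, 104),
                          predictor_specs = default_predictor_specs(),
                          true_fixed_effects = default_true_effects(),
                          random_intercept_sd = 8,
                          random_slope_sd = 0.05,
                          intercept_slope_corr = -0.25,
                          residual_sd = 4,
                          missingness_rates = default_missingness_rates(),
                          seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 1)
    stop_invalid("n_subjects must be a positive integer")
  if (length(visit_weeks) < 1)
    stop_invalid("visit_weeks must be non-empty")
  if (visit_weeks[1] != 0 || is.unsorted(visit_weeks, strictly = TRUE))
    stop_invalid("visit_weeks must be strictly increasing and start at 0")
  for (s in c(random_intercept_sd, random_slope_sd, residual_sd))
    if (s < 0) stop_invalid("standard deviations must be >= 0")
  if (abs(intercept_slope_corr) > 1)
    stop_invalid("|intercept_slope_corr| must be <= 1")
  if (length(missingness_rates) &&
      (any(missingness_rates < 0) || any(missingness_rates > 1)))
    stop_invalid("missingness rates must lie in [0, 1]")
  bad <- setdiff(names(missingness_rates), names(predictor_specs))
  if (length(bad))
    stop_invalid("missingness rate for unknown column(s): %s",
                 paste(bad, collapse = ", "))
  structure(list(
    n_subjects = as.integer(n_subjects),
    visit_weeks = as.numeric(visit_weeks),
    predictor_specs = predictor_specs,
    true_fixed_effects = true_fixed_effects,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    intercept_slope_corr = intercept_slope_corr,
    residual_sd = residual_sd,
    missingness_rates = missingness_rates,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Draw one subject-level predictor column of length n from its marginal spec.
draw_predictor <- function(spec, n) {
  switch(spec$type,
    continuous = {
      x <- rnorm(n, spec$mean, spec$sd)
      if (!is.null(spec$lower)) x <- pmax(x, spec$lower)
      if (!is.null(spec$upper)) x <- pmin(x, spec$upper)
      if (isTRUE(spec$integer)) x <- round(x)
      x
    },
    binary = rbinom(n, 1, spec$prob),
    categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    stop_invalid("unknown predictor type '%s'", spec$type))
}

# Numeric contribution of one predictor column to the linear predictor.
effect_contribution <- function(effects, name, values) {
  if (!name %in% names(effects) && !is.list(effects[[name]])) {
    eff <- effects[[name]]
    if (is.null(eff)) return(rep(0, length(values)))
  }
  eff <- effects[[name]]
  if (is.null(eff)) return(rep(0, length(values)))
  if (is.character(values) || is.factor(values)) {
    # per-level offsets; unnamed levels contribute 0
    off <- eff[as.character(values)]
    off[is.na(off)] <- 0
    as.numeric(off)
  } else {
    as.numeric(values) * eff
  }
}

new_cohort_table <- function(df, types, response = "va_response",
                             layout = "long", visit_weeks = NULL,
                             mask = NULL) {
  structure(df,
            class = c("cohort_table", "data.frame"),
            predictor_types = types,
            response = response,
            layout = layout,
            visit_weeks = visit_weeks,
            mask = mask)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %s layout: %d rows, %d subjects\n",
              attr(x, "layout"), nrow(x),
              length(unique(x$subject_id))))
  miss <- sum(is.na(as.data.frame(x)))
  cat(sprintf("  response: %s | predictors: %d | missing cells: %d\n",
              attr(x, "response"),
              length(attr(x, "predictor_types")), miss))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Simulates a complete (no missing values) long-format cohort from a
#' linear mixed model: per-subject baseline predictors drawn from the
#' configured marginals, visual acuity at each visit equal to the fixed
#' linear predictor plus a per-subject random intercept and time slope plus
#' Gaussian residual noise, clipped to the 0-100 ETDRS letter scale. Eyes
#' within a subject share the subject's random effects; each subject
#' contributes the treated eye's acuity series.
#'
#' @param config A [cohort_config()].
#' @return A list with components `table` (a `cohort_table` in long layout)
#'   and `truth` (a `truth_record`: realised random effects, the fixed
#'   effects used, the noise-free linear predictor, and a slot for the
#'   missingness mask).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_invalid("config must be a cohort_config")
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_subjects
  weeks <- config$visit_weeks
  specs <- config$predictor_specs
  pred_names <- setdiff(names(specs), "time_weeks")

  subj <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
  for (nm in pred_names) subj[[nm]] <- draw_predictor(specs[[nm]], n)

  # correlated random intercept and slope
  z <- matrix(rnorm(2 * n), ncol = 2)
  rho <- config$intercept_slope_corr
  b0 <- config$random_intercept_sd * z[, 1]
  b1 <- config$random_slope_sd * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])

  nv <- length(weeks)
  long <- subj[rep(seq_len(n), each = nv), , drop = FALSE]
  rownames(long) <- NULL
  long$time_weeks <- rep(weeks, times = n)
  long$eye <- if ("treated_eye" %in% colnames(long))
    ifelse(long$treated_eye == 1, "RE", "LE") else "RE"

  eff <- config$true_fixed_effects
  fixed_part <- rep(if ("(Intercept)" %in% names(eff)) eff[["(Intercept)"]] else 0,
                    nrow(long))
  for (nm in c(pred_names, "time_weeks"))
    fixed_part <- fixed_part + effect_contribution(as.list(eff), nm, long[[nm]])

  re_part <- b0[rep(seq_len(n), each = nv)] +
    b1[rep(seq_len(n), each = nv)] * long$time_weeks
  eps <- rnorm(nrow(long), 0, config$residual_sd)
  va <- fixed_part + re_part + eps
  long$va_response <- pmin(pmax(va, 0), 100)

  types <- vapply(specs, function(s) s$type, character(1))
  ord <- c("subject_id", "eye", "time_weeks", "va_response", pred_names)
  table <- new_cohort_table(long[, ord], types,
                            visit_weeks = weeks)
  truth <- structure(list(
    random_effects = data.frame(subject_id = subj$subject_id,
                                intercept = b0, slope = b1),
    fixed_effects = eff,
    fixed_part = fixed_part,
    clipped = sum(va < 0 | va > 100),
    mask = NULL
  ), class = "truth_record")
  list(table = table, truth = truth)
}

#' Apply missing-completely-at-random masking to a cohort table
#'
#' Masks cells of the listed columns at the given per-column rates.
#' Predictors that are constant within a subject are masked at the
#' subject level (a subject either has the value or lacks it at every
#' visit, as with baseline demographics and OCT gradings); per-visit
#' columns such as `time_weeks` are masked cell-wise. Optionally the
#' masking probability can depend on a covariate (a missing-at-random
#' mechanism) via `mar_covariate`: subjects above the covariate median are
#' masked at twice the rate, below at the complementary reduced rate, so
#' the marginal rate is preserved.
#'
#' @param table A long-layout `cohort_table`.
#' @param rates Named vector of rates in `[0, 1]`.
#' @param seed Integer seed.
#' @param mar_covariate Optional name of a complete continuous column that
#'   drives missingness (MAR); default `NULL` gives MCAR.
#' @return The masked `cohort_table` with the logical mask stored in
#'   `attr(, "mask")` (same shape as the table, `TRUE` = masked).
#' @export
apply_missingness <- function(table, rates, seed = 1L, mar_covariate = NULL) {
  if (any(rates < 0 | rates > 1))
    stop_invalid("missingness rates must lie in [0, 1]")
  bad <- setdiff(names(rates), colnames(table))
  if (length(bad))
    stop_invalid("rates refer to absent column(s): %s", paste(bad, collapse = ", "))
  if (any(names(rates) %in% c("subject_id", attr(table, "response"))))
    stop_invalid("subject_id and the response cannot be masked")
  set.seed(derive_seed(seed, 2L))
  df <- as.data.frame(table)
  subj_ids <- unique(df$subject_id)
  n <- length(subj_ids)
  subj_index <- match(df$subject_id, subj_ids)
  mask <- matrix(FALSE, nrow(df), ncol(df),
                 dimnames = list(NULL, colnames(df)))

  subject_rate <- function(rate) {
    p <- rep(rate, n)
    if (!is.null(mar_covariate)) {
      cov_val <- tapply(df[[mar_covariate]], subj_index, function(v) v[1])
      hi <- cov_val > stats::median(cov_val)
      p <- ifelse(hi, pmin(2 * rate, 1), pmax(2 * rate - pmin(2 * rate, 1), 0))
    }
    p
  }

  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r == 0) next
    constant <- all(tapply(df[[nm]], subj_index,
                           function(v) length(unique(v)) == 1))
    if (constant && nm != "time_weeks") {
      hit <- runif(n) < subject_rate(r)
      mask[, nm] <- hit[subj_index]
    } else {
      mask[, nm] <- runif(nrow(df)) < r
    }
    df[[nm]][mask[, nm]] <- NA
  }
  new_cohort_table(df, attr(table, "predictor_types"),
                   response = attr(table, "response"),
                   layout = attr(table, "layout"),
                   visit_weeks = attr(table, "visit_weeks"),
                   mask = mask)
}

#' Reshape a cohort table between long and wide layouts
#'
#' Long layout has one row per (subject, eye, visit); wide layout one row
#' per (subject, eye) with the response spread into `va_response_w<week>`
#' columns. Subject-constant predictors are carried through; the round
#' trip long -> wide -> long is lossless up to row order.
#'
#' @param table A `cohort_table`.
#' @param layout Target layout, `"long"` or `"wide"`.
#' @return The reshaped `cohort_table`.
#' @export
reshape_cohort <- function(table, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  cur <- attr(table, "layout")
  if (cur == layout) return(table)
  df <- as.data.frame(table)
  weeks <- attr(table, "visit_weeks")
  types <- attr(table, "predictor_types")
  resp <- attr(table, "response")

  if (layout == "wide") {
    key <- paste(df$subject_id, df$eye, df$time_weeks)
    if (anyDuplicated(key))
      stop_invalid("duplicate (subject, eye, time) keys")
    if (anyNA(df$time_weeks))
      stop_invalid("cannot reshape with missing time_weeks")
    if (is.null(weeks)) weeks <- sort(unique(df$time_weeks))
    const_cols <- setdiff(colnames(df), c(resp, "time_weeks"))
    units <- unique(df[, c("subject_id", "eye"), drop = FALSE])
    wide <- df[match(paste(units$subject_id, units$eye),
                     paste(df$subject_id, df$eye)),
               const_cols, drop = FALSE]
    rownames(wide) <- NULL
    for (w in weeks) {
      col <- paste0(resp, "_w", w)
      idx <- match(paste(wide$subject_id, wide$eye, w),
                   paste(df$subject_id, df$eye, df$time_weeks))
      wide[[col]] <- df[[resp]][idx]
    }
    new_cohort_table(wide, types, response = resp, layout = "wide",
                     visit_weeks = weeks)
  } else {
    if (is.null(weeks))
      stop_invalid("wide table lacks its visit_weeks attribute")
    resp_cols <- paste0(resp, "_w", weeks)
    const_cols <- setdiff(colnames(df), resp_cols)
    nv <- length(weeks)
    long <- df[rep(seq_len(nrow(df)), each = nv), const_cols, drop = FALSE]
    rownames(long) <- NULL
    long$time_weeks <- rep(weeks, times = nrow(df))
    long[[resp]] <- as.vector(t(as.matrix(df[, resp_cols])))
    keep <- !is.na(long[[resp]]) | TRUE   # keep structurally missing visits
    ord <- c("subject_id", "eye", "time_weeks", resp,
             setdiff(const_cols, c("subject_id", "eye")))
    new_cohort_table(long[keep, ord], types, response = resp,
                     layout = "long", visit_weeks = weeks)
  }
}

#' Write / read a cohort table as CSV
#'
#' Missing cells are written as empty fields; column types and layout are
#' stored in a JSON sidecar (`<path>.meta.json`) so the round trip is
#' lossless.
#'
#' @param table A `cohort_table`.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  meta <- list(predictor_types = as.list(attr(table, "predictor_types")),
               response = attr(table, "response"),
               layout = attr(table, "layout"),
               visit_weeks = attr(table, "visit_weeks"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  new_cohort_table(df, unlist(meta$predictor_types),
                   response = meta$response, layout = meta$layout,
                   visit_weeks = meta$visit_weeks)
}
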