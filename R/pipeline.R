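#' Default ten-predictor prediction model
#'
#' The predictor set of the reference visual-acuity prediction model:
#' both baseline acuities, intra-retinal fluid, central macular
#' thickness, time, treatment quantity and drug, treated eye,
#' haemorrhage and pigment epithelium detachment.
#'
#' @return Character vector of 10 predictor names.
#' @export
default_final_model <- function() {
  c("baseline_va_le", "baseline_va_re", "irf", "cmt", "time_weeks",
    "treatment_quantity", "treatment_drug", "treated_eye",
    "haemorrhage", "ped")
}

#' Configuration of the full analysis pipeline
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (or
#'   `NULL` when an observed table is passed to [run_pipeline()]).
#' @param m Number of imputations (default 5, minimum 2).
#' @param candidates Candidate predictors for the exhaustive search
#'   (default [candidate_predictors()], the full 19-variable list; note
#'   that searching all 19 means `2^19` fits per imputation — use a
#'   subset for desk-scale runs or set `allow_large`).
#' @param final_model Predictor set of the reported prediction model
#'   (default [default_final_model()]); must be a subset of the
#'   candidates.
#' @param rule Cross-imputation selection rule (`"half"`, `"any"`,
#'   `"all"`).
#' @param criterion Ranking criterion, `"aic"` (default) or `"bic"`.
#' @param allow_large Permit candidate sets larger than 12.
#' @param seed Master seed for every stage.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            m = 5,
                            candidates = candidate_predictors(),
                            final_model = default_final_model(),
                            rule = c("half", "any", "all"),
                            criterion = c("aic", "bic"),
                            allow_large = FALSE,
                            seed = 1L) {
  rule <- match.arg(rule)
  criterion <- match.arg(criterion)
  if (!is_count(m) || m < 2) stop_invalid("m must be an integer >= 2")
  if (!all(final_model %in% candidates))
    stop_invalid("final_model must be a subset of candidates")
  structure(list(cohort = cohort, m = as.integer(m),
                 candidates = candidates, final_model = final_model,
                 rule = rule, criterion = criterion,
                 allow_large = allow_large, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, mask it, impute it `m` times, run the
#' exhaustive mixed-model search on every copy, combine the best subsets
#' by the selection rule, compute per-imputation Akaike-weight variable
#' importance and its cross-imputation average (for the full candidate
#' list and for the final-model-only candidates), fit the final
#' prediction model on each copy, and produce influence diagnostics,
#' residual summaries and per-eye forecast reports. Fully reproducible
#' from the master seed.
#'
#' @param config A [pipeline_config()].
#' @param table Optional observed incomplete `cohort_table`; by default
#'   the cohort is simulated from `config$cohort` and masked with its
#'   missingness rates.
#' @param verbose Emit per-stage progress messages.
#' @return A `pipeline_bundle` list: `truth` (when simulated), `imputations`,
#'   `searches` (per-imputation `search_result`s), `best_sets`,
#'   `selected`, `weight_tables`, `importance`, `importance_final`,
#'   `final_fits`, `influence`, `residuals`, `forecast` (per-eye and
#'   pooled), `timings`, `config`.
#' @export
run_pipeline <- function(config, table = NULL, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
    timings[[name]] <<- tic() - t0
    say("stage %-10s %.2fs", name, timings[[name]])
    out
  }
  k <- length(config$candidates)
  cap <- if (config$allow_large) 21 else 12
  if (k > cap)
    stop_invalid(paste0("%d candidates means 2^%d model fits per ",
                        "imputation; pass allow_large = TRUE or choose ",
                        "a smaller candidate set"), k, k)

  truth <- NULL
  if (is.null(table)) {
    gen <- stage("simulate", {
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, 101L)
      generate_cohort(cc)
    })
    truth <- gen$truth
    table <- stage("mask", apply_missingness(
      gen$table, config$cohort$missingness_rates,
      seed = derive_seed(config$seed, 102L)))
  }

  imps <- stage("impute", impute_emb(table, m = config$m,
                                     seed = derive_seed(config$seed, 103L)))

  crit <- toupper(config$criterion)
  searches <- stage("search", lapply(seq_len(config$m), function(kk) {
    search_models(imps$copies[[kk]], config$candidates,
                  progress_every = Inf)
  }))
  best_sets <- lapply(searches, function(s) {
    idx <- if (crit == "AIC") s$best_aic else s$best_bic
    s$space[[idx]]
  })
  selected <- stage("select",
                    select_predictors_across_imputations(best_sets,
                                                         config$rule))

  weight_tables <- stage("riv", lapply(seq_len(config$m), function(kk)
    riv_table(searches[[kk]], imputation = kk)))
  importance <- average_riv(weight_tables)

  final_searches <- stage("riv_final", lapply(seq_len(config$m),
    function(kk) search_models(imps$copies[[kk]], config$final_model,
                               progress_every = Inf)))
  importance_final <- average_riv(lapply(seq_len(config$m), function(kk)
    riv_table(final_searches[[kk]], imputation = kk)))

  final_fits <- stage("fit_final", lapply(imps$copies, function(cp)
    fit_lmm(cp, config$final_model)))

  diag_fit <- final_fits[[1]]
  influence <- stage("diagnose", influence_report(diag_fit))
  residuals <- residual_summary(diag_fit)

  forecast <- stage("evaluate", {
    per_fit <- lapply(final_fits, evaluate_fit)
    by_eye <- lapply(c(LE = "LE", RE = "RE"), function(e) {
      d <- diag_fit$data
      sel <- d$eye == e
      if (!any(sel)) return(NULL)
      forecast_metrics(d[[diag_fit$response]][sel], diag_fit$fitted[sel])
    })
    list(per_imputation = per_fit, by_eye = by_eye)
  })

  structure(list(truth = truth, table = table, imputations = imps,
                 searches = searches, best_sets = best_sets,
                 selected = selected, weight_tables = weight_tables,
                 importance = importance,
                 importance_final = importance_final,
                 final_fits = final_fits, influence = influence,
                 residuals = residuals, forecast = forecast,
                 timings = timings, config = config),
            class = "pipeline_bundle")
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  cat(sprintf("  m = %d imputations | %d candidates | rule '%s'\n",
              x$config$m, length(x$config$candidates), x$config$rule))
  cat(sprintf("  selected predictors: {%s}\n",
              paste(x$selected, collapse = ", ")))
  cat("  importance (averaged w+):\n")
  print(x$importance[, c("variable", "average", "category")],
        row.names = FALSE)
  invisible(x)
}

#' Write the pipeline's table analogues to CSV
#'
#' Emits the forecast-metric table (one row per imputed copy plus the
#' per-eye rows), the per-imputation w+/w- weight tables with their
#' average, the ranked importance tables (full candidate list and
#' final-model-only), and a JSON run manifest (seed, configuration,
#' stage timings).
#'
#' @param bundle A `pipeline_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
report_tables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  fm <- do.call(rbind, lapply(seq_along(bundle$forecast$per_imputation),
    function(k) {
      r <- bundle$forecast$per_imputation[[k]]
      data.frame(model = sprintf("imputation_%d", k), ME = r$me,
                 MAD = r$mad, RMSE = r$rmse, MPE = r$mpe, MAPE = r$mape,
                 R2_marginal = r$r2[["R2_marginal"]],
                 R2_conditional = r$r2[["R2_conditional"]])
    }))
  for (e in names(bundle$forecast$by_eye)) {
    r <- bundle$forecast$by_eye[[e]]
    if (is.null(r)) next
    fm <- rbind(fm, data.frame(model = paste0("eye_", e), ME = r$me,
                               MAD = r$mad, RMSE = r$rmse, MPE = r$mpe,
                               MAPE = r$mape, R2_marginal = NA,
                               R2_conditional = NA))
  }
  put(fm, "forecast_metrics.csv")

  wt <- render_weight_csv(bundle$weight_tables)
  put(wt, "riv_weights_all.csv")
  put(as.data.frame(bundle$importance), "importance_all.csv")
  put(as.data.frame(bundle$importance_final), "importance_final.csv")

  dfb <- bundle$influence$dfbetas$dfbetas
  put(data.frame(group = rownames(dfb), dfb, check.names = FALSE),
      "dfbetas.csv")
  put(data.frame(group = names(bundle$influence$cooks$cooks),
                 cooks = bundle$influence$cooks$cooks),
      "cooks_distance.csv")
  put(bundle$residuals$points, "residuals_vs_fitted.csv")
  put(bundle$residuals$qq, "qq_points.csv")

  manifest <- list(seed = bundle$config$seed, m = bundle$config$m,
                   candidates = bundle$config$candidates,
                   final_model = bundle$config$final_model,
                   rule = bundle$config$rule,
                   criterion = bundle$config$criterion,
                   selected = bundle$selected,
                   f = bundle$imputations$f,
                   stacking_weight = (1 - bundle$imputations$f) /
                     bundle$imputations$m,
                   timings = as.list(bundle$timings))
  mpath <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  files <- c(files, mpath)
  invisible(files)
}

# Per-imputation w+/w- columns plus average, one pair of rows per
# variable, mirroring the familiar published layout.
render_weight_csv <- function(tables) {
  cand <- tables[[1]]$candidates
  if (!length(cand)) {
    cols <- c("variable", "weight", paste0("imp", seq_along(tables)),
              "average")
    return(as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols)))
  }
  rows <- list()
  for (v in cand) {
    wp <- vapply(tables, function(t)
      t$per_variable$w_plus[t$per_variable$variable == v], numeric(1))
    wm <- vapply(tables, function(t)
      t$per_variable$w_minus[t$per_variable$variable == v], numeric(1))
    base <- setNames(as.list(wp), paste0("imp", seq_along(tables)))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, weight = "w_plus", base, average = mean(wp))
    base <- setNames(as.list(wm), paste0("imp", seq_along(tables)))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, weight = "w_minus", base, average = mean(wm))
  }
  do.call(rbind, rows)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may set any of the [pipeline_config()] fields plus a
#' `cohort:` block with [cohort_config()] fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cohort_args <- cfg$cohort %||% list()
  if (!is.null(cohort_args$missingness_rates))
    cohort_args$missingness_rates <- unlist(cohort_args$missingness_rates)
  if (!is.null(cohort_args$true_fixed_effects))
    cohort_args$true_fixed_effects <- unlist(cohort_args$true_fixed_effects)
  cohort <- do.call(cohort_config, cohort_args)
  top <- cfg[setdiff(names(cfg), "cohort")]
  top <- top[names(top) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, c(list(cohort = cohort), top))
}
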