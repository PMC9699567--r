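#' Residual and normal-probability summary of a mixed-model fit
#'
#' Conditional (subject-level) residuals with their fitted values, the
#' theoretical-vs-sample normal quantile pairs used for a Q-Q plot, and
#' summary statistics. An even, patternless residual-vs-fitted cloud and
#' near-linear Q-Q pairs support the linearity, homoscedasticity and
#' normality assumptions of the model.
#'
#' @param fit A converged `lmm_fit`.
#' @return A `residual_summary`: data frame `points` (`fitted`,
#'   `residual`), data frame `qq` (`theoretical`, `sample`), and `stats`
#'   (mean, sd, skewness).
#' @export
residual_summary <- function(fit) {
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  res <- fit$data[[fit$response]] - fit$fitted
  n <- length(res)
  s <- sd(res)
  skew <- if (s > 0) mean(((res - mean(res)) / s)^3) else 0
  qq <- data.frame(theoretical = qnorm(ppoints(n)),
                   sample = sort(res))
  structure(list(points = data.frame(fitted = fit$fitted, residual = res),
                 qq = qq,
                 stats = c(mean = mean(res), sd = s, skewness = skew)),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("<residual_summary> %d residuals: mean %.4g, sd %.4g, skew %.3f\n",
              nrow(x$points), x$stats["mean"], x$stats["sd"],
              x$stats["skewness"]))
  invisible(x)
}

#' Rule-of-thumb influence cutoffs
#'
#' `2/sqrt(n)` for DFBETAS and `4/n` for Cook's distance, `n` being the
#' number of higher-level groups (subjects) in the fit. At `n = 150`
#' the Cook's cutoff is 4/150 = 0.0267 (0.027 to three decimals).
#'
#' @param n_groups Number of groups; must be positive.
#' @return Named vector `c(dfbetas, cooks)`.
#' @export
influence_cutoffs <- function(n_groups) {
  if (!is_count(n_groups) || n_groups < 1)
    stop_invalid("n_groups must be a positive integer")
  c(dfbetas = 2 / sqrt(n_groups), cooks = 4 / n_groups)
}

# Refit the model once per deleted group; returns per-group coefficient
# and SE matrices. Shared by DFBETAS, Cook's distance and the
# significance-change test so each deletion is fitted only once.
group_deletion_fits <- function(fit, groups = NULL) {
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  df <- fit$data
  all_groups <- unique(df$subject_id)
  groups <- groups %||% all_groups
  pnames <- names(fit$beta)
  beta_del <- se_del <- matrix(NA_real_, length(groups), length(pnames),
                               dimnames = list(groups, pnames))
  ok <- logical(length(groups))
  for (j in seq_along(groups)) {
    sub <- df[df$subject_id != groups[j], , drop = FALSE]
    refit <- fit_lmm(sub, fit$predictors, response = fit$response,
                     weight = if (fit$weight != 1) fit$weight else NULL)
    if (isTRUE(refit$converged) &&
        identical(names(refit$beta), pnames)) {
      beta_del[j, ] <- refit$beta
      se_del[j, ] <- refit$se
      ok[j] <- TRUE
    }
  }
  list(groups = groups, beta_del = beta_del, se_del = se_del, ok = ok)
}

#' Group-deletion DFBETAS of a mixed-model fit
#'
#' For each subject `j` and fixed-effect parameter `i`,
#' `DFBETAS_ij = (b_i - b_i(-j)) / se(b_i(-j))`: the standardised change
#' in the estimate when the subject's rows are deleted and the model
#' fully refit. Values beyond the rule-of-thumb cutoff `2/sqrt(n)` (`n` =
#' number of subjects in the fit) flag potentially influential subjects.
#'
#' @param fit A converged `lmm_fit` with at least 3 subjects.
#' @param deletions Optional precomputed [group_deletion_fits()] result
#'   (lets DFBETAS, Cook's distance and the significance test share one
#'   round of refits).
#' @return A list with `dfbetas` (groups x parameters matrix), `cutoff`,
#'   and `flagged` (group names with any `|DFBETAS|` above the cutoff).
#' @export
dfbetas_by_group <- function(fit, deletions = NULL) {
  del <- deletions %||% group_deletion_fits(fit)
  if (length(del$groups) < 3) stop_invalid("need at least 3 groups")
  dfb <- sweep(-del$beta_del, 2, fit$beta, `+`) / del$se_del
  cutoff <- influence_cutoffs(length(del$groups))[["dfbetas"]]
  flagged <- rownames(dfb)[apply(abs(dfb) > cutoff, 1, any)]
  flagged <- flagged[!is.na(flagged)]
  list(dfbetas = dfb, cutoff = cutoff, flagged = flagged,
       failed = del$groups[!del$ok])
}

#' Group-deletion Cook's distances of a mixed-model fit
#'
#' One quadratic-form summary per subject of its influence on all fixed
#' effects simultaneously:
#' `C_j = (b - b(-j))' V^{-1} (b - b(-j)) / (r + 1)` with `V` the
#' fixed-effect covariance of the full fit and `r + 1` the number of
#' fixed-effect parameters. The rule-of-thumb cutoff is `4/n`, `n` being
#' the number of subjects in the fit.
#'
#' @inheritParams dfbetas_by_group
#' @return A list with `cooks` (named vector), `cutoff`, `flagged`.
#' @export
cooks_distance_by_group <- function(fit, deletions = NULL) {
  del <- deletions %||% group_deletion_fits(fit)
  if (length(del$groups) < 3) stop_invalid("need at least 3 groups")
  Vinv <- tryCatch(solve(fit$vcov), error = function(e) {
    warning("singular fixed-effect covariance; using pseudo-inverse",
            call. = FALSE)
    pseudo_inverse(fit$vcov)
  })
  p <- length(fit$beta)
  cooks <- vapply(seq_along(del$groups), function(j) {
    if (!del$ok[j]) return(NA_real_)
    d <- fit$beta - del$beta_del[j, ]
    as.numeric(t(d) %*% Vinv %*% d) / p
  }, numeric(1))
  names(cooks) <- del$groups
  cutoff <- influence_cutoffs(length(del$groups))[["cooks"]]
  flagged <- names(cooks)[!is.na(cooks) & cooks > cutoff]
  list(cooks = cooks, cutoff = cutoff, flagged = flagged,
       failed = del$groups[!del$ok])
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Significance-change test after deleting flagged groups
#'
#' For each flagged subject, refits the model without that subject and
#' compares each fixed-effect parameter's significance verdict
#' (`|estimate/SE| >= critical`, normal approximation) with and without
#' the subject. A subject is overly influential only when a verdict
#' flips.
#'
#' @param fit A converged `lmm_fit`.
#' @param flagged Character vector of subject ids (e.g. from
#'   [dfbetas_by_group()] or [cooks_distance_by_group()]).
#' @param deletions Optional shared [group_deletion_fits()] result.
#' @param critical Critical value for the Wald z statistic (default 1.96).
#' @return A `sig_change` list: data frame `records` (group, parameter,
#'   significant with/without, changed) and `any_change`.
#' @export
significance_change_test <- function(fit, flagged, deletions = NULL,
                                     critical = 1.96) {
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  bad <- setdiff(flagged, unique(fit$data$subject_id))
  if (length(bad))
    stop_invalid("flagged group(s) not in the fit: %s",
                 paste(bad, collapse = ", "))
  full_sig <- abs(fit$beta / fit$se) >= critical
  if (!length(flagged)) {
    return(structure(list(records = data.frame(), any_change = FALSE,
                          critical = critical), class = "sig_change"))
  }
  del <- deletions %||% group_deletion_fits(fit, groups = flagged)
  idx <- match(flagged, del$groups)
  rows <- list()
  for (j in idx) {
    g <- del$groups[j]
    for (i in seq_along(fit$beta)) {
      pn <- names(fit$beta)[i]
      if (!del$ok[j]) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g, parameter = pn, with_group = full_sig[i],
          without_group = NA, changed = NA, stringsAsFactors = FALSE)
        next
      }
      wo <- abs(del$beta_del[j, i] / del$se_del[j, i]) >= critical
      rows[[length(rows) + 1]] <- data.frame(
        group = g, parameter = pn, with_group = full_sig[i],
        without_group = wo, changed = (wo != full_sig[i]),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  structure(list(records = records,
                 any_change = isTRUE(any(records$changed, na.rm = TRUE)),
                 critical = critical),
            class = "sig_change")
}

#' Full influence report for a fitted model
#'
#' Runs one round of group-deletion refits and derives DFBETAS, Cook's
#' distances (with their cutoffs and flags) and the significance-change
#' records for every flagged subject.
#'
#' @param fit A converged `lmm_fit`.
#' @return An `influence_report` list: `dfbetas`, `cooks`, `sig_change`,
#'   `n_groups`.
#' @export
influence_report <- function(fit) {
  del <- group_deletion_fits(fit)
  dfb <- dfbetas_by_group(fit, deletions = del)
  ck <- cooks_distance_by_group(fit, deletions = del)
  flagged <- union(dfb$flagged, ck$flagged)
  sig <- significance_change_test(fit, flagged, deletions = del)
  structure(list(dfbetas = dfb, cooks = ck, sig_change = sig,
                 n_groups = length(del$groups)),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("<influence_report> %d groups\n", x$n_groups))
  cat(sprintf("  DFBETAS cutoff %.4f: %d group(s) flagged\n",
              x$dfbetas$cutoff, length(x$dfbetas$flagged)))
  cat(sprintf("  Cook's cutoff %.4f: %d group(s) flagged\n",
              x$cooks$cutoff, length(x$cooks$flagged)))
  cat(sprintf("  significance flips after deletion: %s\n",
              if (x$sig_change$any_change) "YES" else "none"))
  invisible(x)
}
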