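#' Enumerate the all-subsets model space
#'
#' Builds all `2^k` fixed-effect subsets of the candidate predictors
#' (including the empty/null model), ordered by subset size and then
#' lexicographically within size. The space is held compactly as bitmasks
#' so enumerating the full 19-candidate space (524,288 models) is
#' immediate; subsets are materialised on demand via `[[` or
#' `as.list()`. Every candidate appears in exactly `2^(k-1)` subsets — the
#' balance that makes Akaike-weight variable importance a fair contest.
#'
#' @param candidates Character vector of unique predictor names.
#' @param cap Refuse to enumerate more than `2^cap` models (default 21).
#' @return A `model_space` object; `length()` gives the number of models,
#'   `space[[i]]` the i-th predictor subset (character vector).
#' @export
enumerate_model_space <- function(candidates, cap = 21) {
  if (anyDuplicated(candidates))
    stop_invalid("candidate names must be unique")
  k <- length(candidates)
  if (k > cap)
    stop_invalid(paste0(
      "k = %d candidates means 2^%d model fits; raise `cap` only if you ",
      "really intend an exhaustive search of that size"), k, k)
  masks <- seq.int(0L, bitwShiftL(1L, k) - 1L)
  if (k > 0) {
    bits <- vapply(seq_len(k) - 1L,
                   function(b) bitwAnd(bitwShiftR(masks, b), 1L),
                   integer(length(masks)))
    bits <- matrix(bits, nrow = length(masks))
    size <- rowSums(bits)
    # lexicographic order within size: candidate i gets weight 2^(k-i),
    # larger key first
    lexkey <- as.vector(bits %*% 2^((k - 1):0))
    ord <- order(size, -lexkey)
    masks <- masks[ord]
  }
  structure(list(candidates = candidates, masks = masks, k = k),
            class = "model_space")
}

#' @export
length.model_space <- function(x) length(x$masks)

#' @export
`[[.model_space` <- function(x, i) {
  mask <- x$masks[[i]]
  if (x$k == 0) return(character(0))
  x$candidates[bitwAnd(bitwShiftR(mask, seq_len(x$k) - 1L), 1L) == 1L]
}

#' @export
as.list.model_space <- function(x, ...) {
  lapply(seq_along(x$masks), function(i) x[[i]])
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("<model_space> %d candidates, %d models (incl. null)\n",
              x$k, length(x$masks)))
  invisible(x)
}

# Does subset i of the space contain `variable`?
space_contains <- function(space, variable) {
  j <- match(variable, space$candidates)
  if (is.na(j)) stop_invalid("unknown variable '%s'", variable)
  bitwAnd(bitwShiftR(space$masks, j - 1L), 1L) == 1L
}

#' Exhaustive all-subsets mixed-model search
#'
#' Fits one ML mixed model per predictor subset of the enumerated space
#' (always with the `(time_weeks | subject_id)` random structure), storing
#' the log-likelihood, `K`, AIC and BIC of each. Non-converged fits are
#' kept in the record, flagged, and given infinite AIC/BIC so they rank
#' last and carry zero Akaike weight.
#'
#' @param table One complete imputed copy (or a weighted stacked table).
#' @param candidates Candidate predictor names.
#' @param response Response column (default from the table).
#' @param weight Optional scalar observation weight (see [fit_lmm()]);
#'   defaults to the stacked table's weight attribute when present.
#' @param n_for_bic Sample size for BIC (default: subjects in the table).
#' @param cap Passed to [enumerate_model_space()].
#' @param progress_every Log a progress line every this many models
#'   (default 1000; `Inf` silences).
#' @return A `search_result`: data frame `models` (one row per subset:
#'   `model_id`, `subset`, `n_predictors`, `loglik`, `K`, `AIC`, `BIC`,
#'   `converged`, `singular`), the coefficient list, the space, and the
#'   indices of the best AIC/BIC models.
#' @export
search_models <- function(table, candidates, response = NULL,
                          weight = NULL, n_for_bic = NULL, cap = 21,
                          progress_every = 1000) {
  space <- enumerate_model_space(candidates, cap = cap)
  if (is.null(weight)) weight <- attr(table, "w")
  nm <- length(space)
  n_groups <- length(unique(as.data.frame(table)$subject_id))
  n_bic <- n_for_bic %||% n_groups
  loglik <- K <- aic <- bic <- rep(NA_real_, nm)
  conv <- sing <- logical(nm)
  coefs <- vector("list", nm)
  subsets <- character(nm)
  for (i in seq_len(nm)) {
    preds <- space[[i]]
    subsets[i] <- paste(preds, collapse = ";")
    fit <- fit_lmm(table, preds, response = response, weight = weight)
    if (isTRUE(fit$converged)) {
      loglik[i] <- fit$loglik
      K[i] <- fit$K
      ic <- information_criteria(fit, n_bic)
      aic[i] <- ic[["AIC"]]
      bic[i] <- ic[["BIC"]]
      conv[i] <- TRUE
      sing[i] <- fit$singular
      coefs[[i]] <- fit$beta
    } else {
      aic[i] <- bic[i] <- Inf
    }
    if (is.finite(progress_every) && i %% progress_every == 0)
      message(sprintf("search: %d / %d models fitted", i, nm))
  }
  if (mean(!conv) > 0.01)
    warning(sprintf("%.1f%% of the model space failed to converge",
                    100 * mean(!conv)), call. = FALSE)
  models <- data.frame(model_id = seq_len(nm), subset = subsets,
                       n_predictors = vapply(seq_len(nm), function(i)
                         length(space[[i]]), integer(1)),
                       loglik = loglik, K = K, AIC = aic, BIC = bic,
                       converged = conv, singular = sing,
                       stringsAsFactors = FALSE)
  best_aic <- rank_best(models, "AIC")
  best_bic <- rank_best(models, "BIC")
  structure(list(models = models, coefs = coefs, space = space,
                 candidates = candidates,
                 response = response %||% attr(table, "response"),
                 n_for_bic = n_bic,
                 best_aic = best_aic, best_bic = best_bic),
            class = "search_result")
}

# Best model index: smallest criterion, ties broken by smaller K then by
# enumeration (size-then-lexicographic) order.
rank_best <- function(models, criterion) {
  ord <- order(models[[criterion]], models$K, models$model_id)
  ord[1]
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d models over %d candidates (response %s)\n",
              nrow(x$models), length(x$candidates), x$response))
  b <- x$models[x$best_aic, ]
  cat(sprintf("  best by AIC (%.2f): {%s}\n", b$AIC,
              gsub(";", ", ", b$subset)))
  b <- x$models[x$best_bic, ]
  cat(sprintf("  best by BIC (%.2f): {%s}\n", b$BIC,
              gsub(";", ", ", b$subset)))
  invisible(x)
}

#' Combine best-model predictor sets across imputed datasets
#'
#' Three rules for reconciling the (generally different) best subsets
#' found on each imputed copy: keep predictors appearing in `any` of
#' them, in at least `half` (appearance count `>= ceiling(m/2)`), or in
#' `all` of them.
#'
#' @param best_sets List of character vectors, one per imputed dataset.
#' @param rule `"any"`, `"half"` (default) or `"all"`.
#' @return Character vector of selected predictors (in first-appearance
#'   order).
#' @export
select_predictors_across_imputations <- function(best_sets,
                                                 rule = c("half", "any", "all")) {
  rule <- match.arg(rule)
  if (!length(best_sets)) stop_invalid("best_sets must be non-empty")
  all_vars <- unique(unlist(best_sets))
  counts <- vapply(all_vars, function(v)
    sum(vapply(best_sets, function(s) v %in% s, logical(1))), integer(1))
  m <- length(best_sets)
  thr <- switch(rule, any = 1, half = ceiling(m / 2), all = m)
  all_vars[counts >= thr]
}

#' Model-averaged coefficients over a searched space
#'
#' For each candidate the Akaike-weight-weighted mean of its
#' coefficient(s) over the models that contain it, renormalised by the
#' inclusion weight sum `w+` (conditional model averaging). Categorical
#' candidates report one averaged coefficient per non-reference level.
#'
#' @param result A `search_result`.
#' @param weights Per-model Akaike weights aligned with `result$models`
#'   (default: computed from the stored AICs).
#' @return Data frame with `variable`, `coefficient`, `estimate`,
#'   `w_plus`; variables contained in no weighted model get `NA` with a
#'   note.
#' @export
model_averaged_effects <- function(result, weights = NULL) {
  if (is.null(weights)) weights <- akaike_weights(result$models$AIC)
  if (length(weights) != nrow(result$models))
    stop_invalid("weights must align with the searched models")
  rows <- list()
  for (v in result$candidates) {
    inc <- space_contains(result$space, v)
    w_plus <- sum(weights[inc])
    coef_names <- unique(unlist(lapply(result$coefs[inc], function(b)
      grep(paste0("^", v), names(b), value = TRUE))))
    if (w_plus == 0 || !length(coef_names)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, coefficient = v, estimate = NA_real_,
        w_plus = w_plus, stringsAsFactors = FALSE)
      next
    }
    for (cn in coef_names) {
      num <- 0; den <- 0
      for (i in which(inc)) {
        b <- result$coefs[[i]]
        if (!is.null(b) && cn %in% names(b)) {
          num <- num + weights[i] * b[[cn]]
          den <- den + weights[i]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, coefficient = cn,
        estimate = if (den > 0) num / den else NA_real_,
        w_plus = w_plus, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
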