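#' Akaike weights of a model set
#'
#' `delta_i = AIC_i - min(AIC)`, `w_i = exp(-delta_i/2) / sum_r
#' exp(-delta_r/2)`, evaluated with the max-shift (log-sum-exp) trick so
#' large deltas cannot underflow the normalisation. Infinite AICs
#' (non-converged fits) receive weight zero.
#'
#' @param aics Numeric vector of AIC values (`Inf` allowed).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (!length(aics)) stop_invalid("empty AIC vector")
  if (all(!is.finite(aics)))
    stop_invalid("all models non-converged: degenerate model space")
  logw <- -aics / 2
  w <- exp(logw - logsumexp(logw))
  w[!is.finite(aics)] <- 0
  w / sum(w)
}

#' Inclusion / exclusion weight sums for one variable
#'
#' `w+` is the sum of Akaike weights of the models containing the
#' variable, `w-` the sum over the rest; over a balanced enumerated space
#' they sum to one, and `w+` close to 1 marks an indispensable predictor.
#'
#' @param result A `search_result`.
#' @param weights Per-model Akaike weights (default from stored AICs).
#' @param variable Candidate name.
#' @return Named vector `c(w_plus, w_minus)`.
#' @export
riv_weights <- function(result, weights = NULL, variable) {
  if (is.null(weights)) weights <- akaike_weights(result$models$AIC)
  inc <- space_contains(result$space, variable)
  if (!any(inc))
    warning(sprintf("variable '%s' appears in no model: unbalanced space",
                    variable), call. = FALSE)
  c(w_plus = sum(weights[inc]), w_minus = sum(weights[!inc]))
}

#' Per-imputation relative-importance weight table
#'
#' Computes Akaike weights over a searched space and the `w+`/`w-` pair
#' for every candidate.
#'
#' @param result A `search_result`.
#' @param imputation Index of the imputed dataset (bookkeeping only).
#' @return A `weight_table`: list with the per-model data frame
#'   (`AIC`, `delta`, `weight`) and the per-variable data frame
#'   (`variable`, `w_plus`, `w_minus`).
#' @export
riv_table <- function(result, imputation = NA_integer_) {
  w <- akaike_weights(result$models$AIC)
  finite <- is.finite(result$models$AIC)
  per_model <- data.frame(
    model_id = result$models$model_id,
    subset = result$models$subset,
    AIC = result$models$AIC,
    delta = result$models$AIC - min(result$models$AIC[finite]),
    weight = w, stringsAsFactors = FALSE)
  per_var <- do.call(rbind, lapply(result$candidates, function(v) {
    wv <- riv_weights(result, w, v)
    data.frame(variable = v, w_plus = wv[["w_plus"]],
               w_minus = wv[["w_minus"]], stringsAsFactors = FALSE)
  }))
  structure(list(per_model = per_model, per_variable = per_var,
                 candidates = result$candidates, imputation = imputation),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d models, %d candidates%s\n",
              nrow(x$per_model), nrow(x$per_variable),
              if (!is.na(x$imputation))
                sprintf(" (imputation %d)", x$imputation) else ""))
  print(x$per_variable[order(-x$per_variable$w_plus), ], row.names = FALSE)
  invisible(x)
}

#' Average variable importance across imputed datasets
#'
#' Arithmetic mean of `w+` per variable over the per-imputation weight
#' tables, ranked in descending order and labelled by the importance
#' categories. The per-imputation spread is retained so single-imputation
#' anomalies (one copy disagreeing sharply with the rest) remain visible.
#'
#' @param tables List of `weight_table`s over the same candidate set.
#' @return An `importance_table` data frame: one row per variable with
#'   the per-imputation `w+` columns, `average`, `spread` (max - min),
#'   `rank` and `category`.
#' @export
average_riv <- function(tables) {
  if (!length(tables)) stop_invalid("no weight tables given")
  cand <- tables[[1]]$candidates
  if (!length(cand)) {
    out <- data.frame(variable = character(0), average = numeric(0),
                      spread = numeric(0), rank = integer(0),
                      category = character(0), stringsAsFactors = FALSE)
    class(out) <- c("importance_table", "data.frame")
    return(out)
  }
  for (t in tables)
    if (!identical(sort(t$candidates), sort(cand)))
      stop_invalid("weight tables have mismatched candidate sets")
  wp <- vapply(tables, function(t)
    t$per_variable$w_plus[match(cand, t$per_variable$variable)],
    numeric(length(cand)))
  wp <- matrix(wp, nrow = length(cand),
               dimnames = list(cand, paste0("imp", seq_along(tables))))
  avg <- rowMeans(wp)
  out <- data.frame(variable = cand, wp, average = avg,
                    spread = apply(wp, 1, max) - apply(wp, 1, min),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$average), ]
  out$rank <- seq_len(nrow(out))
  out$category <- classify_importance(out$average)
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Importance category of an averaged inclusion weight
#'
#' Left-closed, right-open bands: `w+ >= 0.9` Highly Important;
#' `[0.7, 0.9)` Important; `[0.5, 0.7)` Moderate; `[0.4, 0.5)` Low to
#' Moderate; `< 0.4` Low.
#'
#' @param w_plus_avg Numeric values in `[0, 1]` (vectorised).
#' @return Character vector of category labels.
#' @export
classify_importance <- function(w_plus_avg) {
  if (any(w_plus_avg < 0 | w_plus_avg > 1))
    stop_invalid("w+ must lie in [0, 1]")
  cut_pts <- c(-Inf, 0.4, 0.5, 0.7, 0.9, Inf)
  labels <- c("Low", "Low to Moderate", "Moderate", "Important",
              "Highly Important")
  as.character(cut(w_plus_avg, cut_pts, labels, right = FALSE))
}
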