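#' Forecast-accuracy metrics for observed vs predicted series
#'
#' With forecast error `e_t = Y_t - Yhat_t`:
#' mean error `ME = mean(e)` (bias; negative under systematic
#' over-forecasting), mean absolute deviation `MAD = mean(|e|)`, root
#' mean square error `RMSE = sqrt(mean(e^2))`, mean percentage error
#' `MPE = mean(e / Y)` (a proportion), and mean absolute percentage
#' error `MAPE = mean(|e| / Y) * 100` (a percentage). Pairs with a
#' missing observed or predicted value are dropped and counted; pairs
#' with `Y = 0` are excluded from the percentage metrics and counted.
#'
#' @param observed,predicted Equal-length numeric vectors (ETDRS letters).
#' @return A `forecast_report` (metrics part): `me`, `mad`, `rmse`,
#'   `mpe`, `mape`, `n_pairs`, `n_dropped`, `n_zero_excluded`.
#' @export
forecast_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop_invalid("observed and predicted must have equal length")
  ok <- !is.na(observed) & !is.na(predicted)
  n_dropped <- sum(!ok)
  y <- observed[ok]; yhat <- predicted[ok]
  if (!length(y)) stop_invalid("no valid observation/prediction pairs")
  e <- y - yhat
  nz <- y != 0
  structure(list(
    me = mean(e),
    mad = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    mpe = if (any(nz)) mean(e[nz] / y[nz]) else NA_real_,
    mape = if (any(nz)) mean(abs(e[nz]) / y[nz]) * 100 else NA_real_,
    n_pairs = length(y),
    n_dropped = n_dropped,
    n_zero_excluded = sum(!nz)
  ), class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat(sprintf(paste0("<forecast_report> n = %d pairs\n",
                     "  ME %.4f | MAD %.4f | RMSE %.4f | MPE %.4f | MAPE %.2f%%\n"),
              x$n_pairs, x$me, x$mad, x$rmse, x$mpe, x$mape))
  if (!is.null(x$r2))
    cat(sprintf("  R2 marginal %.3f | conditional %.3f | MAPE < 10%%: %s\n",
                x$r2[["R2_marginal"]], x$r2[["R2_conditional"]],
                if (isTRUE(x$meets_mape_objective)) "yes" else "NO"))
  invisible(x)
}

#' In-sample forecast evaluation of a fitted mixed model
#'
#' Compares the observed response with subject-level predictions (fixed
#' effects plus each subject's predicted random intercept and slope),
#' computes the forecast metrics and the Nakagawa R-squared pair, and
#' flags whether the model meets the sub-10% MAPE objective.
#'
#' @param fit A converged `lmm_fit`.
#' @param table Optional evaluation data (default: the fit's own rows,
#'   i.e. in-sample evaluation).
#' @return A `forecast_report` with `r2` and `meets_mape_objective`
#'   added.
#' @export
evaluate_fit <- function(fit, table = NULL) {
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  if (is.null(table)) {
    obs <- fit$data[[fit$response]]
    pred <- fit$fitted
  } else {
    obs <- as.data.frame(table)[[fit$response]]
    pred <- predict_fitted(fit, table, level = "subject")
  }
  rep <- forecast_metrics(obs, pred)
  rep$r2 <- r2_nakagawa(fit)
  rep$meets_mape_objective <- is.finite(rep$mape) && rep$mape < 10
  rep
}
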