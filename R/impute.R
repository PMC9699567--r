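#' Multiple imputation by bootstrap plus EM (EMB)
#'
#' Creates `m` completed copies of an incomplete cohort. For each copy the
#' subject-level predictor grid is bootstrap-resampled, the
#' multivariate-normal parameters are estimated on the bootstrap sample by
#' [em_fit()], and every subject's missing cells are drawn from the
#' conditional normal given that subject's observed cells under the
#' bootstrap parameters. Observed cells are never touched; binary and
#' categorical cells are mapped back to the nearest level, and bounded
#' continuous columns are clipped. Masked `time_weeks` cells are restored
#' from the subject's position in the visit schedule.
#'
#' @param table An incomplete long-layout `cohort_table` (as produced by
#'   [apply_missingness()]).
#' @param m Number of imputed copies, at least 2 (default 5).
#' @param seed Master seed; per-copy seeds are derived by fixed offsets.
#' @param include_response If `TRUE`, per-visit response columns join the
#'   EM grid and missing responses are imputed too; by default only
#'   predictors are imputed and missing responses are left to be dropped
#'   at model-fit time.
#' @param specs Predictor marginal specs used for bounds when decoding
#'   (default [default_predictor_specs()] for matching names).
#' @param max_retries Bootstrap retries when a resample is degenerate
#'   (a constant column).
#' @return An `imputation_set`: list with `m`, `copies` (complete
#'   `cohort_table`s), `mask`, `f` (missing-cell fraction over the
#'   n-subjects x p-predictors grid), `n`, `p`, `seed`.
#' @export
impute_emb <- function(table, m = 5, seed = 1L, include_response = FALSE,
                       specs = default_predictor_specs(),
                       max_retries = 5) {
  if (!is_count(m) || m < 2) stop_invalid("m must be an integer >= 2")
  df <- as.data.frame(table)
  types <- attr(table, "predictor_types")
  weeks <- attr(table, "visit_weeks")
  enc <- build_encoding(table)
  grid <- subject_grid(table)
  n <- nrow(grid)
  pred_vars <- names(types)            # the p candidate predictors, incl. time

  # f: fraction of missing cells over the n x p predictor grid; a
  # predictor's subject-cell is missing when any of its per-row cells is.
  miss_by_subject <- vapply(pred_vars, function(nm) {
    as.logical(tapply(is.na(df[[nm]]), df$subject_id, any))
  }, logical(n))
  f <- mean(miss_by_subject)
  p <- length(pred_vars)

  X <- encode_grid(grid, enc)
  resp_block <- NULL
  if (include_response) {
    wide <- reshape_cohort(table, "wide")
    resp_cols <- paste0(attr(table, "response"), "_w", weeks)
    resp_block <- as.matrix(as.data.frame(wide)[, resp_cols, drop = FALSE])
    rownames(resp_block) <- as.data.frame(wide)$subject_id
    resp_block <- resp_block[rownames(X), , drop = FALSE]
    X <- cbind(X, resp_block)
  }

  need <- is.na(X)
  copies <- vector("list", m)
  for (k in seq_len(m)) {
    Xk <- X
    if (any(need)) {
      fit <- NULL
      for (try in 0:max_retries) {
        set.seed(derive_seed(seed, 10L * k + try))
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        degenerate <- any(apply(Xb, 2, function(v) {
          v <- v[!is.na(v)]
          length(v) == 0 || stats::sd(v) == 0
        }))
        if (!degenerate) {
          fit <- em_fit(Xb)
          break
        }
      }
      if (is.null(fit))
        stop_invalid("degenerate bootstrap sample after %d retries", max_retries)
      Xk <- draw_conditional(X, fit$mu, fit$sigma)
    }
    copies[[k]] <- rebuild_copy(table, Xk, enc, specs, include_response)
  }
  structure(list(m = m, copies = copies, mask = attr(table, "mask"),
                 f = f, n = n, p = p, seed = seed,
                 include_response = include_response),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d copies, %d subjects, %d predictors\n",
              x$m, x$n, x$p))
  cat(sprintf("  missing-cell fraction f = %.4f (stacking weight (1-f)/m = %.4f)\n",
              x$f, (1 - x$f) / x$m))
  invisible(x)
}

# One conditional-normal draw of the missing cells of every row.
draw_conditional <- function(X, mu, sigma) {
  obs <- !is.na(X)
  pattern <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  for (g in split(seq_len(nrow(X)), pattern)) {
    o <- obs[g[1], ]
    m <- !o
    if (!any(m)) next
    Soo <- sigma[o, o, drop = FALSE]
    Smo <- sigma[m, o, drop = FALSE]
    Smm <- sigma[m, m, drop = FALSE]
    B <- t(safe_solve(Soo, t(Smo)))
    cond_cov <- Smm - B %*% t(Smo)
    cond_cov <- (cond_cov + t(cond_cov)) / 2
    R <- chol(repair_spd(cond_cov, 1e-10)$sigma)
    dev <- sweep(X[g, o, drop = FALSE], 2, mu[o])
    cmean <- matrix(mu[m], length(g), sum(m), byrow = TRUE) + dev %*% t(B)
    Z <- matrix(rnorm(length(g) * sum(m)), length(g), sum(m))
    X[g, m] <- cmean + Z %*% R
  }
  X
}

# Fill the masked cells of the original long table from a completed grid.
rebuild_copy <- function(table, Xk, enc, specs, include_response) {
  df <- as.data.frame(table)
  weeks <- attr(table, "visit_weeks")
  resp <- attr(table, "response")
  pred_cols <- unlist(lapply(enc, `[[`, "cols"), use.names = FALSE)
  decoded <- decode_grid(Xk[, pred_cols, drop = FALSE], enc, specs)
  rownames(decoded) <- rownames(Xk)
  sidx <- match(df$subject_id, rownames(decoded))
  for (nm in names(enc)) {
    nav <- is.na(df[[nm]])
    if (any(nav)) df[[nm]][nav] <- decoded[[nm]][sidx[nav]]
  }
  # time is the visit schedule: restore by within-subject position
  if (anyNA(df$time_weeks) && !is.null(weeks)) {
    pos <- stats::ave(seq_len(nrow(df)), df$subject_id, df$eye,
                      FUN = seq_along)
    nav <- is.na(df$time_weeks)
    df$time_weeks[nav] <- weeks[pos[nav]]
  }
  if (include_response && anyNA(df[[resp]])) {
    resp_cols <- paste0(resp, "_w", weeks)
    sp <- specs[["baseline_va_le"]] %||% list(lower = 0, upper = 100)
    for (j in seq_along(weeks)) {
      nav <- is.na(df[[resp]]) & df$time_weeks == weeks[j]
      v <- Xk[sidx[nav], resp_cols[j]]
      df[[resp]][nav] <- pmin(pmax(v, 0), 100)
    }
  }
  new_cohort_table(df, attr(table, "predictor_types"), response = resp,
                   layout = attr(table, "layout"), visit_weeks = weeks)
}

#' Stack the copies of an imputation set into one weighted table
#'
#' Concatenates the `m` completed copies (a `copy` column records the
#' origin) and attaches the stacked-regression observation weight
#' `w = (1 - f) / m`, where `f` is the missing-cell fraction over the
#' n x p predictor grid. Fitting one mixed model to the stacked table with
#' its log-likelihood scaled by `w` corrects the otherwise understated
#' standard errors.
#'
#' The stacked table describes `m x n` individuals: each copy's subjects
#' become distinct grouping units (`subject_id` is suffixed with the copy
#' index; the original id is kept in `source_subject`). Re-using one
#' grouping unit across copies would let the random intercept absorb the
#' between-copy variation of imputed subject-level covariates and shrink
#' their fixed effects toward zero.
#'
#' @param imps An `imputation_set`.
#' @return A `stacked_table`: the row-bound `cohort_table` with a `copy`
#'   column; attributes `w`, `f`, `m`.
#' @export
stack_imputations <- function(imps) {
  if (!inherits(imps, "imputation_set"))
    stop_invalid("imps must be an imputation_set")
  pieces <- lapply(seq_len(imps$m), function(k) {
    d <- as.data.frame(imps$copies[[k]])
    d$copy <- k
    d$source_subject <- d$subject_id
    d$subject_id <- paste0(d$subject_id, "_c", k)
    d
  })
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL
  w <- (1 - imps$f) / imps$m
  tmpl <- imps$copies[[1]]
  out <- new_cohort_table(df, attr(tmpl, "predictor_types"),
                          response = attr(tmpl, "response"),
                          layout = attr(tmpl, "layout"),
                          visit_weeks = attr(tmpl, "visit_weeks"))
  class(out) <- c("stacked_table", class(out))
  attr(out, "w") <- w
  attr(out, "f") <- imps$f
  attr(out, "m") <- imps$m
  out
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled estimate is the mean of the per-copy estimates; the total
#' variance combines the mean within-imputation variance `W` with the
#' between-imputation variance `B` as `W + (1 + 1/m) B`.
#'
#' @param estimates Numeric vector (one estimate per copy) or matrix with
#'   one row per copy.
#' @param within_variances Squared standard errors, same shape.
#' @return List with `estimate`, `variance`, `se`, and the components
#'   `within`, `between`, `m`.
#' @export
rubin_pool <- function(estimates, within_variances) {
  est <- if (is.matrix(estimates)) estimates else cbind(estimates)
  wv <- if (is.matrix(within_variances)) within_variances else
    cbind(within_variances)
  if (!all(dim(est) == dim(wv)))
    stop_invalid("estimates and within_variances must have equal shape")
  m <- nrow(est)
  if (m < 2) stop_invalid("need m >= 2 imputations to pool")
  pooled <- colMeans(est)
  B <- apply(est, 2, stats::var)
  W <- colMeans(wv)
  total <- W + (1 + 1 / m) * B
  simplify <- !is.matrix(estimates)
  out <- list(estimate = if (simplify) unname(pooled) else pooled,
              variance = if (simplify) unname(total) else total,
              se = sqrt(if (simplify) unname(total) else total),
              within = W, between = B, m = m)
  out
}
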