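#' Expectation-maximisation for a multivariate normal with missing data
#'
#' Maximum-likelihood estimation of the mean vector and covariance matrix
#' of a multivariate normal from data with arbitrary (assumed
#' missing-at-random) missingness patterns. The E-step sweeps each
#' missingness pattern once, filling conditional means and adding the
#' conditional covariance to the cross-product accumulator; the M-step is
#' the closed-form update. The observed-data log-likelihood is recorded at
#' every iteration and is non-decreasing by construction.
#'
#' @param X Numeric matrix (rows = units, columns = variables) with `NA`
#'   for missing entries. Every column needs at least one observed value.
#' @param tol Convergence tolerance on the relative change in
#'   log-likelihood (default `1e-6`).
#' @param max_iter Iteration cap (default 500).
#' @param ridge Diagonal inflation used to repair a non-positive-definite
#'   covariance (default `1e-8`); any repair is recorded in the result.
#' @return List with `mu`, `sigma`, `loglik` (the trace, one entry per
#'   iteration), `converged`, `iterations`, `ridge_used`.
#' @export
em_fit <- function(X, tol = 1e-6, max_iter = 500, ridge = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop_invalid("need at least 2 rows")
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing))
    stop_invalid("column(s) fully missing: %s",
                 paste(colnames(X)[all_missing], collapse = ", "))

  obs <- !is.na(X)
  if (all(obs)) {
    mu <- colMeans(X)
    sigma <- crossprod(sweep(X, 2, mu)) / n      # ML (divisor n)
    ll <- mvn_loglik(X, obs, mu, sigma)
    return(list(mu = mu, sigma = sigma, loglik = ll, converged = TRUE,
                iterations = 1L, ridge_used = FALSE))
  }

  # initialise from available-case moments
  mu <- colMeans(X, na.rm = TRUE)
  sigma <- stats::cov(X, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  sigma <- repair_spd(sigma, ridge)$sigma

  pattern <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern)
  trace <- numeric(0)
  ridge_used <- FALSE
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    for (g in groups) {
      o <- obs[g[1], ]
      m <- !o
      Xg <- X[g, , drop = FALSE]
      if (!any(m)) {
        sum_x <- sum_x + colSums(Xg)
        sum_xx <- sum_xx + crossprod(Xg)
        next
      }
      Soo <- sigma[o, o, drop = FALSE]
      Smo <- sigma[m, o, drop = FALSE]
      Smm <- sigma[m, m, drop = FALSE]
      B <- t(safe_solve(Soo, t(Smo)))                     # S_mo S_oo^-1
      cond_cov <- Smm - B %*% t(Smo)
      dev <- sweep(Xg[, o, drop = FALSE], 2, mu[o])
      Xg[, m] <- matrix(mu[m], nrow(Xg), sum(m), byrow = TRUE) +
        dev %*% t(B)
      sum_x <- sum_x + colSums(Xg)
      cp <- crossprod(Xg)
      cp[m, m] <- cp[m, m] + length(g) * cond_cov
      sum_xx <- sum_xx + cp
    }
    mu_new <- sum_x / n
    sigma_new <- sum_xx / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    rep_res <- repair_spd(sigma_new, ridge)
    sigma_new <- rep_res$sigma
    ridge_used <- ridge_used || rep_res$repaired

    mu <- mu_new; sigma <- sigma_new
    ll <- mvn_loglik(X, obs, mu, sigma)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  list(mu = mu, sigma = sigma, loglik = trace, converged = converged,
       iterations = length(trace), ridge_used = ridge_used)
}

# Observed-data log-likelihood under N(mu, sigma), pattern-wise.
mvn_loglik <- function(X, obs, mu, sigma) {
  pattern <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(X)), pattern)
  ll <- 0
  for (g in groups) {
    o <- obs[g[1], ]
    if (!any(o)) next
    Xo <- X[g, o, drop = FALSE]
    So <- sigma[o, o, drop = FALSE]
    R <- tryCatch(chol(So),
                  error = function(e) chol(repair_spd(So, 1e-10)$sigma))
    dev <- sweep(Xo, 2, mu[o])
    z <- dev %*% backsolve(R, diag(sum(o)))
    ll <- ll + sum(-0.5 * rowSums(z^2)) -
      length(g) * (sum(log(diag(R))) + 0.5 * sum(o) * log(2 * pi))
  }
  ll
}

# Linear solve against a covariance sub-block, with escalating diagonal
# ridge when the block is numerically singular (small-sample EM).
safe_solve <- function(A, B) {
  r <- 0
  scale <- mean(diag(A)) + 1e-12
  for (k in 1:10) {
    out <- tryCatch(solve(A + diag(r, nrow(A)), B),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
    r <- if (r == 0) 1e-10 * scale else r * 100
  }
  stop_invalid("covariance block is singular beyond ridge repair")
}

# Escalating-ridge repair to a symmetric positive-definite matrix.
repair_spd <- function(sigma, ridge) {
  repaired <- FALSE
  r <- ridge
  for (k in 1:12) {
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (ok) break
    sigma <- sigma + diag(r, nrow(sigma))
    r <- r * 10
    repaired <- TRUE
  }
  list(sigma = sigma, repaired = repaired)
}
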