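# Internal numerical helpers shared across the inference machinery.

#' Log of the sum of exponentials
#'
#' Numerically stable computation of \code{log(sum(exp(x)))}.
#'
#' @param x numeric vector (may contain \code{-Inf}).
#' @return a scalar.
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log of the mean of exponentials
#' @param x numeric vector of log values.
#' @return a scalar, \code{log(mean(exp(x)))}.
#' @keywords internal
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Central finite-difference Hessian of a scalar function f at x.
# Uses a fixed step on the log-parameter scale.
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) {
      for (j in seq(i + 1L, d)) {
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h^2)
      }
    }
  }
  H
}

# Multivariate t draws: n samples from t_df(mu, Sigma) given the upper
# Cholesky factor R of Sigma (Sigma = R'R).  Returns an n x d matrix.
rmvt_chol <- function(n, mu, R, df) {
  d <- length(mu)
  Z <- matrix(stats::rnorm(n * d), n, d) %*% R
  u <- stats::rchisq(n, df) / df
  sweep(Z / sqrt(u), 2L, mu, "+")
}

# Multivariate t log-density at the rows of X, same parametrization.
dmvt_chol <- function(X, mu, R, df) {
  d <- length(mu)
  dev <- sweep(X, 2L, mu, "-")
  # Mahalanobis via triangular solve: Sigma^{-1} = R^{-1} R^{-T}
  z <- t(backsolve(R, t(dev), transpose = TRUE))
  maha <- rowSums(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(R))) - ((df + d) / 2) * log1p(maha / df)
}

# Weighted quantiles are not needed; importance samples are resampled
# instead (see forecast_accrual).

`%||%` <- function(a, b) if (is.null(a)) b else a
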