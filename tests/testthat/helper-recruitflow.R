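# Shared fixtures and independent oracles for the test suite.

# Small three-center toy data set with staggered initiations.
toy_trial <- function(census = 5L) {
  trial_data(list(a = c(1L, 0L, 2L, 0L, 1L),
                  b = c(0L, 0L, 1L),
                  c = c(2L, 1L, 0L, 0L)),
             c(a = 0L, b = 2L, c = 1L), census_day = census)
}

# Independent marginal log-likelihood oracle: per center, numerically
# marginalizes the product of daily Poisson pmfs over the gamma random
# effect by generalized Gauss-Laguerre quadrature (shape alpha - 1), with
# no use of the closed-form marginal.
oracle_loglik <- function(data, curve, alpha, phi, theta = NULL, nodes = 40) {
  gl <- pracma::gaussLaguerre(nodes, alpha - 1)
  total <- 0
  for (y in data$counts) {
    tau <- length(y)
    if (tau == 0L) next
    dG <- diff(if (curve$kappa > 0) G_kappa(curve, theta, 0:tau)
               else as.numeric(0:tau))
    s <- sum(dG) + alpha / phi
    # integrand = dgamma(lambda) * prod_t dpois(y_t; lambda dG_t)
    #           = lambda^(alpha-1) e^(-s lambda) * h(lambda)
    log_h <- function(lam)
      sum(y * log(lam * dG)) - sum(lgamma(y + 1)) +
        alpha * log(alpha / phi) - lgamma(alpha)
    lh <- vapply(gl$x / s, log_h, numeric(1))
    total <- total + log(sum(gl$w * exp(lh))) - alpha * log(s)
  }
  total
}

# Time-homogeneous Poisson-gamma marginal log-likelihood (per-center total
# counts over tau_c days), written directly from the gamma-Poisson mixture:
# n_c ~ NegBin(shape alpha, mean phi tau_c), plus the multinomial term for
# the within-period day pattern (uniform over days).
pg_homogeneous_loglik <- function(data, alpha, phi) {
  total <- 0
  for (y in data$counts) {
    tau <- length(y)
    if (tau == 0L) next
    n <- sum(y)
    total <- total + stats::dnbinom(n, size = alpha, mu = phi * tau,
                                    log = TRUE) +
      lgamma(n + 1) - sum(lgamma(y + 1)) - n * log(tau)
  }
  total
}
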