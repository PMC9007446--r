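grid_kappas <- c(0, 0.5, 1, 2, Inf)

test_that("marginal likelihood matches analytic and quadrature oracles", {
  # one center, one day, zero counts, alpha = phi = 1:
  # integral of e^-lambda * e^-lambda dlambda = 1/2
  td1 <- trial_data(list(a = 0L), c(a = 0L), 1)
  expect_equal(log_likelihood(c(log_alpha = 0, log_phi = 0),
                              curve_model(0, 1), td1),
               log(0.5), tolerance = 1e-12)

  # every grid curve-shape against Gauss-Laguerre marginalization on the
  # three-center toy
  td <- toy_trial()
  for (k in grid_kappas) {
    cm <- curve_model(k, 4)
    p <- c(log_alpha = log(1.3), log_phi = log(0.5), log_theta = log(0.03))
    ll <- log_likelihood(p, cm, td)
    orc <- oracle_loglik(td, cm, alpha = 1.3, phi = 0.5, theta = 0.03)
    expect_equal(ll, orc, tolerance = 1e-6,
                 label = sprintf("kappa=%s", format(k)))
  }
})

test_that("kappa = 0 reduces to the time-homogeneous Poisson-gamma model", {
  td <- toy_trial()
  p <- c(log_alpha = log(0.8), log_phi = log(0.4))
  expect_equal(log_likelihood(p, curve_model(0, 4), td),
               pg_homogeneous_loglik(td, 0.8, 0.4), tolerance = 1e-10)
})

test_that("likelihood is invariant to the curve-shape scale convention", {
  # multiplying g by c and dividing phi by c leaves the model unchanged;
  # re-normalizing at a different tau_norm rescales g by a constant, so
  # compensating phi must reproduce the log-likelihood exactly
  td <- toy_trial()
  theta <- 0.05
  for (k in c(0.5, 1, 2, Inf)) {
    cm_a <- curve_model(k, 4)
    cm_b <- curve_model(k, 8)
    # scale of g changes by ratio r = G_a(x)/G_b(x) uniformly in x
    r <- G_kappa(cm_a, theta, 2) / G_kappa(cm_b, theta, 2)
    p_a <- c(log_alpha = log(1.1), log_phi = log(0.6),
             log_theta = log(theta))
    p_b <- c(log_alpha = log(1.1), log_phi = log(0.6 * r),
             log_theta = log(theta))
    expect_equal(log_likelihood(p_a, cm_a, td),
                 log_likelihood(p_b, cm_b, td), tolerance = 1e-9,
                 label = sprintf("kappa=%s", format(k)))
  }
})

test_that("prior density components are correct and normalized", {
  pr <- prior_spec()
  # kappa = 0: normal on log_alpha plus uniform on log_phi only
  p0 <- c(log_alpha = 0.5, log_phi = 1)
  expect_equal(log_prior(p0, curve_model(0, 100), pr),
               dnorm(0.5, 0.2, 2, log = TRUE) - log(16))
  # outside the phi support: -Inf, not an error
  expect_identical(log_prior(c(log_alpha = 0, log_phi = 9),
                             curve_model(0, 100), pr), -Inf)

  # exponential tail with a flat Beta(1,1): the induced density of
  # log(theta) is t0 * theta * exp(-theta t0)
  pr1 <- prior_spec(beta_a = 1, beta_b = 1)
  cmI <- curve_model(Inf, 100)
  for (lt in c(-6, -4.5, -3)) {
    th <- exp(lt)
    got <- log_prior(c(log_alpha = 0.2, log_phi = 0, log_theta = lt),
                     cmI, pr1) -
      log_prior(c(log_alpha = 0.2, log_phi = 0), curve_model(0, 100), pr1)
    expect_equal(got, log(pr1$t0 * th * exp(-th * pr1$t0)), tolerance = 1e-12)
  }

  # the log_theta prior integrates to 1 for every decaying shape
  for (k in c(0.5, 1, 2, Inf)) {
    cm <- curve_model(k, 100)
    base <- log_prior(c(log_alpha = 0.2, log_phi = 0),
                      curve_model(0, 100), pr)
    dens <- function(lt) vapply(lt, function(v)
      exp(log_prior(c(log_alpha = 0.2, log_phi = 0, log_theta = v),
                    cm, pr) - base), numeric(1))
    Z <- integrate(dens, -20, 20, rel.tol = 1e-9)$value
    expect_equal(Z, 1, tolerance = 1e-4, label = sprintf("kappa=%s", k))
  }
})

test_that("posterior mode satisfies the first-order condition", {
  sim <- simulate_trial(sim_config(n_centers = 60, study_length = 250,
                                   phi = 0.05, kappa = 2, theta = 0.02,
                                   seed = 21))
  cm <- curve_model(2, mean(observation_days(sim)))
  md <- find_mode(cm, sim, prior_spec(), n_starts = 2)
  f <- function(p) {
    names(p) <- names(md$mode)
    log_likelihood(p, cm, sim) + log_prior(p, cm, prior_spec())
  }
  h <- 1e-5
  for (i in seq_along(md$mode)) {
    e <- replace(numeric(3), i, h)
    grad <- (f(md$mode + e) - f(md$mode - e)) / (2 * h)
    expect_lt(abs(grad), 1e-2)
  }
  expect_true(all(eigen(-md$hessian, only.values = TRUE)$values > 0))
})

test_that("flat-likelihood toy puts the mode for log_theta at its prior mode", {
  # an empty-ish data set gives the likelihood no information about theta
  td <- trial_data(list(a = integer(2) ), c(a = 0L), 2)
  cm <- curve_model(Inf, 2)
  pr <- prior_spec()
  set.seed(2)
  md <- find_mode(cm, td, pr, n_starts = 3)
  # prior mode of log_theta: maximize the induced density numerically
  opt <- optimize(function(lt)
    log_prior(c(log_alpha = md$mode[["log_alpha"]],
                log_phi = md$mode[["log_phi"]], log_theta = lt), cm, pr),
    c(-15, 5), maximum = TRUE)
  expect_equal(md$mode[["log_theta"]], opt$maximum, tolerance = 0.05)
})

test_that("importance sampling with target = proposal has ESS = M", {
  # when the posterior kernel equals the proposal density all weights are
  # equal; emulate by weighting a t sample against itself
  set.seed(9)
  mu <- c(0, 1); R <- chol(diag(c(1, 2)))
  X <- recruitflow:::rmvt_chol(500, mu, R, 4)
  lw <- recruitflow:::dmvt_chol(X, mu, R, 4) -
    recruitflow:::dmvt_chol(X, mu, R, 4)
  w <- exp(lw - max(lw))
  expect_equal(sum(w)^2 / sum(w^2), 500)
})

test_that("multivariate t sampler and density agree with univariate t", {
  mu <- 0.7; sc <- 1.9
  R <- matrix(sqrt(sc), 1, 1)
  x <- matrix(seq(-3, 3, by = 0.5), ncol = 1)
  got <- recruitflow:::dmvt_chol(x + mu, mu, R, 4)
  want <- dt((x) / sqrt(sc), df = 4, log = TRUE) - 0.5 * log(sc)
  expect_equal(got, as.numeric(want), tolerance = 1e-12)
  set.seed(4)
  draws <- recruitflow:::rmvt_chol(40000, mu, R, 4)
  expect_equal(median(draws), mu, tolerance = 0.03)
})

test_that("marginal likelihood agrees with 2-D grid quadrature (kappa=0)", {
  td <- toy_trial()
  cm <- curve_model(0, 4)
  pr <- prior_spec()
  fit <- importance_fit(cm, td, pr, M = 4000, seed = 11, n_starts = 2)
  # brute-force evidence over (log_alpha, log_phi)
  la <- seq(-6, 6, length.out = 220)
  lp <- seq(-7.99, 7.99, length.out = 260)
  lg <- outer(la, lp, Vectorize(function(a, p) {
    pp <- c(log_alpha = a, log_phi = p)
    log_likelihood(pp, cm, td) + log_prior(pp, cm, pr)
  }))
  m <- max(lg)
  Z <- m + log(sum(exp(lg - m)) * diff(la)[1] * diff(lp)[1])
  expect_equal(fit$log_marginal_likelihood, Z, tolerance = 0.05)
  expect_gt(fit$ess, 0.3 * 4000)
})

test_that("importance-sampling logZ replication error matches its weights", {
  td <- toy_trial()
  cm <- curve_model(0, 4)
  zs <- sapply(1:6, function(s)
    importance_fit(cm, td, M = 1500, seed = 100 + s,
                   n_starts = 1)$log_marginal_likelihood)
  expect_lt(sd(zs), 0.05)
})

test_that("model probabilities are a softmax of evidence", {
  td <- toy_trial()
  f1 <- importance_fit(curve_model(0, 4), td, M = 500, seed = 1, n_starts = 1)
  expect_equal(unname(model_probabilities(list(f1))), 1)

  f2 <- f1; f2$log_marginal_likelihood <- f1$log_marginal_likelihood
  expect_equal(unname(model_probabilities(list(f1, f2))), c(0.5, 0.5))
  f2$log_marginal_likelihood <- f1$log_marginal_likelihood - log(3)
  expect_equal(unname(model_probabilities(list(f1, f2))), c(0.75, 0.25))

  # refuse to mix fits of different data sets
  f3 <- importance_fit(curve_model(0, 2),
                       trial_data(list(z = c(1L, 1L)), c(z = 0L), 2),
                       M = 500, seed = 2, n_starts = 1)
  expect_error(model_probabilities(list(f1, f3)), "same data")
})

test_that("alpha/theta and phi/theta stay nearly orthogonal on equal-tau data", {
  sim <- simulate_trial(sim_config(n_centers = 80, study_length = 150,
                                   initiation = rep(0, 80), phi = 0.08,
                                   kappa = 2, theta = 0.03, seed = 31))
  cm <- curve_model(2, 150)
  md <- find_mode(cm, sim, prior_spec(), n_starts = 2)
  H <- md$hessian
  gm <- function(i, j) abs(H[i, j]) / sqrt(abs(H[i, i] * H[j, j]))
  expect_lt(gm(1, 3), 0.05)  # log_alpha vs log_theta
  expect_lt(gm(2, 3), 0.05)  # log_phi vs log_theta
})
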