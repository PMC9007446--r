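test_that("random-effect posterior follows the conjugate update", {
  cm <- curve_model(0, 10)
  p <- c(log_alpha = 0, log_phi = 0)
  # unopened center: prior gamma
  r0 <- re_posterior(p, cm, n_c = 0, tau_c = 0)
  expect_equal(r0$alpha_star, 1)
  expect_equal(r0$phi_star, 1)

  # alpha = 1, phi = 1, n = 2, G(tau) = 1: shape 3, rate 2, mean 1.5
  r <- re_posterior(p, cm, n_c = 2, tau_c = 1)
  expect_equal(r$alpha_star, 3)
  expect_equal(r$phi_star, 1.5)

  # posterior mean matches a dense grid posterior of lambda
  lam <- seq(1e-6, 20, length.out = 40001)
  post <- dgamma(lam, 1, 1) * dpois(2, lam)  # G(tau)=1 interval, 2 events
  m_grid <- sum(lam * post) / sum(post)
  expect_equal(r$phi_star, m_grid, tolerance = 1e-3)
})

test_that("one-interval predictive is the stated negative binomial", {
  # geometric special case: shape 1, mean 1 -> P(0) = 1/2
  rep1 <- list(alpha_star = 1, phi_star = 1)
  expect_equal(predictive_pmf(rep1, G_plus = 1, 0), 0.5)

  rep2 <- list(alpha_star = 2.7, phi_star = 0.8)
  n <- 0:500
  pmf <- predictive_pmf(rep2, G_plus = 2.5, n)
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
  expect_equal(sum(n * pmf), 0.8 * 2.5, tolerance = 1e-9)
  expect_error(predictive_pmf(rep2, G_plus = 0, 1), "positive")
})

test_that("sampled counts match the closed-form predictive (chi-square GoF)", {
  # draw Poisson counts over a gamma posterior and compare to the
  # negative binomial pmf
  set.seed(77)
  alpha_star <- 2.2; phi_star <- 1.4; G_plus <- 1.8
  n_draw <- 1e5
  lam <- rgamma(n_draw, shape = alpha_star, rate = alpha_star / phi_star)
  y <- rpois(n_draw, lam * G_plus)
  tab <- tabulate(pmin(y, 12) + 1L, nbins = 13L)
  p_theo <- predictive_pmf(list(alpha_star = alpha_star,
                                phi_star = phi_star), G_plus, 0:11)
  p_theo <- c(p_theo, 1 - sum(p_theo))
  gof <- chisq.test(tab, p = p_theo)
  expect_gt(gof$p.value, 0.01)
})

test_that("forecast paths are monotone and reproduce the NB mean", {
  sim <- simulate_trial(sim_config(n_centers = 30, study_length = 120,
                                   phi = 0.08, kappa = 0, theta = 0.01,
                                   seed = 41))
  obs <- truncate_trial(sim, 80)
  fit <- importance_fit(curve_model(0, mean(observation_days(obs))), obs,
                        M = 2000, seed = 5, n_starts = 2)
  fc <- forecast_accrual(fit, obs, horizon = 81, n_paths = 3e4, seed = 6)
  expect_true(all(fc$paths[, 1] >= totals(obs)$n_total))

  # day-1-ahead mean: weighted-average over the posterior of the summed
  # NB means of all open centers (kappa = 0 so G+ = 1)
  w <- exp(fit$log_weights - max(fit$log_weights)); w <- w / sum(w)
  tau <- observation_days(obs); n_per <- totals(obs)$per_center
  mean_theo <- 0
  for (m in seq_len(nrow(fit$samples))) {
    a <- exp(fit$samples[m, "log_alpha"]); ph <- exp(fit$samples[m, "log_phi"])
    mean_theo <- mean_theo +
      w[m] * sum(ph * (a + n_per[tau > 0]) / (a + ph * tau[tau > 0]))
  }
  inc <- mean(fc$paths[, 1] - totals(obs)$n_total)
  se <- sd(fc$paths[, 1]) / sqrt(nrow(fc$paths))
  expect_lt(abs(inc - mean_theo), 4 * se)
})

test_that("longer horizons and path monotonicity along the calendar", {
  sim <- simulate_trial(sim_config(n_centers = 25, study_length = 150,
                                   phi = 0.05, seed = 51))
  obs <- truncate_trial(sim, 100)
  fit <- fit_recruitment(obs, kappas = c(0, 2), M = 800, seed = 3,
                         n_starts = 2)
  fc <- forecast_accrual(fit, obs, horizon = 150, n_paths = 300, seed = 4)
  expect_true(all(apply(fc$paths, 1L, function(r) all(diff(r) >= 0))))
  expect_true(all(fc$quantiles$lower95 <= fc$quantiles$median))
  expect_true(all(fc$quantiles$median <= fc$quantiles$upper95))
})

test_that("scheduled centers add accrual and deterministic openings count", {
  sim <- simulate_trial(sim_config(n_centers = 20, study_length = 100,
                                   phi = 0.05,
                                   deterministic_first_recruitment = TRUE,
                                   seed = 61))
  obs <- truncate_trial(sim, 70)
  fit <- fit_recruitment(obs, kappas = 0, M = 500, seed = 7, n_starts = 1)
  sch <- initiation_schedule(c("N1", "N2"), c(75L, 80L), obs)
  fc0 <- forecast_accrual(fit, obs, horizon = 100, n_paths = 400, seed = 8)
  fc1 <- forecast_accrual(fit, obs, horizon = 100, n_paths = 400, seed = 8,
                          schedule = sch)
  # each scheduled center contributes its deterministic initiation recruit
  # plus nonnegative stochastic recruitment
  expect_gte(mean(fc1$paths[, ncol(fc1$paths)]) -
               mean(fc0$paths[, ncol(fc0$paths)]), 2)
})

test_that("time-to-target censors at the horizon and is monotone in target", {
  paths <- matrix(c(5, 10, 15, 20,
                    2,  4,  6,  8), nrow = 2, byrow = TRUE)
  fc <- structure(list(paths = paths, days = 101:104, census_day = 100L,
                       horizon = 104L, accrual_at_census = 0L),
                  class = "accrual_forecast")
  tt <- time_to_target(fc, 15)
  expect_equal(tt$day, c(103, 104))
  expect_equal(tt$censored, c(FALSE, TRUE))
  # first forecast day hit
  expect_equal(time_to_target(fc, 2)$day, c(101, 101))
  # monotone in the target
  t1 <- time_to_target(fc, 6); t2 <- time_to_target(fc, 8)
  expect_true(all(t2$day >= t1$day))
  expect_error(time_to_target(fc, 0), "already reached")
  expect_warning(time_to_target(fc, 1000), "censored")
})
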