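# Exact conjugate posterior-predictive forecasting.
#
# Conditional on (alpha, phi, theta), each center's random effect has a
# gamma posterior in closed form; future daily counts given the random
# effect are Poisson, so one-interval predictive counts are negative
# binomial and accrual paths are simulated exactly with no further
# approximation.  Bayesian model averaging mixes these predictions over
# the curve-shape grid with posterior model probabilities.

#' Random-effect posterior for one center
#'
#' Gamma posterior of the center recruitment rate \eqn{\lambda_c} given
#' hyperparameters: shape \eqn{\alpha^* = \alpha + n_c} and mean
#' \eqn{\phi^* = \phi (\alpha + n_c) / (\alpha + \phi G(\tau_c))}, i.e.
#' rate \eqn{\alpha^*/\phi^* = \alpha/\phi + G(\tau_c)}.  For a center not
#' yet opened (\code{n_c = tau_c = 0}) this is the prior
#' \eqn{Gamma(\alpha, \alpha/\phi)}.
#'
#' @param params named log-parameter vector (\code{log_alpha},
#'   \code{log_phi}, and \code{log_theta} when the curve has one).
#' @param curve a \code{\link{curve_model}}.
#' @param n_c observed total recruits at the center.
#' @param tau_c observed days at the center.
#' @return list with \code{alpha_star} and \code{phi_star}.
#' @export
re_posterior <- function(params, curve, n_c, tau_c) {
  stopifnot(n_c >= 0, tau_c >= 0)
  alpha <- exp(params[["log_alpha"]])
  phi <- exp(params[["log_phi"]])
  G_tau <- if (tau_c > 0) {
    theta <- if (curve$kappa > 0) exp(params[["log_theta"]]) else NULL
    if (curve$kappa > 0) G_kappa(curve, theta, tau_c) else tau_c
  } else 0
  alpha_star <- alpha + n_c
  phi_star <- phi * (alpha + n_c) / (alpha + phi * G_tau)
  list(alpha_star = alpha_star, phi_star = phi_star)
}

#' Posterior-predictive count distribution for one interval
#'
#' Negative binomial pmf of the recruitment count of a center over a future
#' interval with integrated intensity \code{G_plus}, after marginalizing
#' the gamma random-effect posterior: shape \code{alpha_star} and mean
#' \code{phi_star * G_plus}.
#'
#' @param rep a random-effect posterior from \code{\link{re_posterior}}.
#' @param G_plus integrated intensity over the target interval (\code{> 0}).
#' @param n non-negative integer counts (vectorized).
#' @return probabilities.
#' @export
predictive_pmf <- function(rep, G_plus, n) {
  if (G_plus <= 0) stop("`G_plus` must be positive")
  if (any(n < 0) || any(n != round(n))) stop("`n` must be non-negative integers")
  stats::dnbinom(n, size = rep$alpha_star, mu = rep$phi_star * G_plus)
}

#' Forecast accrual by posterior-predictive simulation
#'
#' Simulates \code{n_paths} future accrual paths from the census day to the
#' horizon.  Each path (i) picks a curve-shape model with its posterior
#' model probability, (ii) draws hyperparameters from that model's
#' importance sample by weighted resampling, (iii) draws every center's
#' rate from its gamma posterior (the prior gamma for centers in the future
#' initiation schedule), and (iv) simulates daily Poisson counts with means
#' \code{lambda_c * [G(t) - G(t-1)]} on each center's future local days.
#' When the data carry the deterministic-first-recruitment convention, one
#' recruit is added at each scheduled center's initiation day.
#'
#' @param fit a \code{"bma_fit"} from \code{\link{fit_recruitment}} (a
#'   single \code{"model_fit"} is also accepted and treated as a one-model
#'   average).
#' @param data the \code{\link{trial_data}} the fit was computed on.
#' @param horizon calendar day up to which to forecast (\code{>
#'   data$census_day}).
#' @param schedule optional \code{\link{initiation_schedule}} of future
#'   center openings.
#' @param n_paths number of posterior-predictive paths.
#' @param target optional enrollment target; when given, per-path
#'   time-to-target days are extracted (right-censored at the horizon).
#' @param seed optional integer seed.
#' @return an object of class \code{"accrual_forecast"} with the path
#'   matrix (\code{n_paths} by forecast days, cumulative total accrual),
#'   per-day quantiles (2.5/50/97.5\%), and optionally time-to-target
#'   draws.
#' @export
forecast_accrual <- function(fit, data, horizon, schedule = NULL,
                             n_paths = 1000, target = NULL, seed = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (inherits(fit, "model_fit"))
    fit <- structure(list(fits = list(fit), model_probs = 1,
                          tau_norm = fit$curve$tau_norm),
                     class = "bma_fit")
  stopifnot(inherits(fit, "bma_fit"))
  if (!length(fit$fits)) stop("empty model list")
  horizon <- as.integer(horizon)
  census <- data$census_day
  if (horizon <= census) stop("`horizon` must be after the census day")
  if (!is.null(seed)) set.seed(seed)
  H <- horizon - census
  days <- census + seq_len(H)

  # center bookkeeping: open centers (tau > 0), pending centers already in
  # the data but not yet initiated, plus the scheduled future centers
  tau <- observation_days(data)
  n_per <- totals(data)$per_center
  if (data$first_recruitment_deterministic) {
    adj <- vapply(model_counts(data), sum, numeric(1))
    n_per <- as.integer(adj)  # likelihood-scale totals
    names(n_per) <- data$center_ids
  }
  init_all <- data$initiation_day
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "initiation_schedule"))
    init_all <- c(init_all,
                  stats::setNames(schedule$day, schedule$center_id))
    tau <- c(tau, stats::setNames(rep(0L, nrow(schedule)), schedule$center_id))
    n_per <- c(n_per, stats::setNames(rep(0L, nrow(schedule)), schedule$center_id))
  }
  # keep centers that have any future local days before the horizon
  keep <- names(init_all)[init_all < horizon]
  init_all <- init_all[keep]; tau <- tau[keep]; n_per <- n_per[keep]
  nC <- length(init_all)

  # future local-day cells, flattened once (theta-independent)
  start_loc <- pmax(tau, census - init_all, 0)  # last observed local day
  end_loc <- horizon - init_all
  cell_center <- integer(0); cell_local <- integer(0); cell_cal <- integer(0)
  for (i in seq_len(nC)) {
    if (end_loc[i] <= start_loc[i]) next
    tt <- seq.int(start_loc[i] + 1L, end_loc[i])
    cell_center <- c(cell_center, rep.int(i, length(tt)))
    cell_local <- c(cell_local, tt)
    cell_cal <- c(cell_cal, init_all[i] + tt)
  }
  cal_idx <- cell_cal - census
  max_loc <- if (length(cell_local)) max(cell_local) else 1L

  # deterministic initiation recruits for centers opening in the forecast
  # window (the recruit lands on the first local day, calendar init + 1)
  det_daily <- numeric(H)
  if (data$first_recruitment_deterministic) {
    opening <- init_all[tau == 0 & init_all >= census & init_all < horizon]
    for (d in opening + 1L) det_daily[d - census] <- det_daily[d - census] + 1
  }

  # per-model resampling indices
  K <- length(fit$fits)
  ks <- sample.int(K, n_paths, replace = TRUE, prob = fit$model_probs)
  idx <- integer(n_paths)
  for (k in unique(ks)) {
    f <- fit$fits[[k]]
    w <- exp(f$log_weights - max(f$log_weights))
    sel <- which(ks == k)
    idx[sel] <- sample.int(nrow(f$samples), length(sel), replace = TRUE,
                           prob = w)
  }

  obs_total <- totals(data)$n_total
  paths <- matrix(0, n_paths, H)
  for (s in seq_len(n_paths)) {
    f <- fit$fits[[ks[s]]]
    p <- f$samples[idx[s], ]
    names(p) <- colnames(f$samples)
    alpha <- exp(p[["log_alpha"]]); phi <- exp(p[["log_phi"]])
    if (f$curve$kappa > 0) {
      theta <- exp(p[["log_theta"]])
      Gt <- G_kappa(f$curve, theta, 0:max_loc)
      dG <- diff(Gt)
      G_tau <- Gt[pmin(tau, max_loc) + 1]
      G_tau[tau > max_loc] <- G_kappa(f$curve, theta, tau[tau > max_loc])
    } else {
      dG <- rep(1, max_loc)
      G_tau <- tau
    }
    rate <- alpha / phi + G_tau
    lam <- stats::rgamma(nC, shape = alpha + n_per, rate = rate)
    mu <- lam[cell_center] * dG[cell_local]
    y <- stats::rpois(length(mu), mu)
    daily <- numeric(H)
    if (length(y)) {
      agg <- rowsum(y, cal_idx)
      daily[as.integer(rownames(agg))] <- agg
    }
    paths[s, ] <- cumsum(daily + det_daily)
  }
  paths <- paths + obs_total

  qs <- apply(paths, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  out <- list(paths = paths, days = days,
              quantiles = data.frame(day = days, lower95 = qs[1, ],
                                     median = qs[2, ], upper95 = qs[3, ]),
              census_day = census, horizon = horizon,
              accrual_at_census = obs_total)
  class(out) <- "accrual_forecast"
  if (!is.null(target)) {
    ttt <- time_to_target(out, target)
    out$target <- target
    out$time_to_target <- ttt
  }
  out
}

#' @export
print.accrual_forecast <- function(x, ...) {
  cat(sprintf("Accrual forecast: days %d-%d, %d paths\n",
              x$census_day + 1L, x$horizon, nrow(x$paths)))
  last <- x$quantiles[nrow(x$quantiles), ]
  cat(sprintf("  accrual at census: %d\n", x$accrual_at_census))
  cat(sprintf("  final accrual: median %.0f, 95%% interval (%.0f, %.0f)\n",
              last$median, last$lower95, last$upper95))
  if (!is.null(x$time_to_target)) {
    tt <- x$time_to_target
    cat(sprintf("  time to target %d: %.0f%% of paths censored at horizon\n",
                x$target, 100 * mean(tt$censored)))
    if (any(!tt$censored))
      cat(sprintf("    median completion day %.0f\n",
                  stats::median(tt$day[!tt$censored])))
  }
  invisible(x)
}

#' Time until the enrollment target is reached
#'
#' For each sampled accrual path, the first calendar day on which the
#' cumulative accrual reaches the target.  Paths not reaching the target by
#' the horizon are right-censored at the horizon and flagged.
#'
#' @param forecast an \code{"accrual_forecast"}.
#' @param target enrollment target, greater than the accrual at the census.
#' @return list with per-path \code{day} and logical \code{censored};
#'   a warning is issued when every path is censored.
#' @export
time_to_target <- function(forecast, target) {
  stopifnot(inherits(forecast, "accrual_forecast"))
  if (target <= forecast$accrual_at_census)
    stop("target already reached at the census day")
  hit <- apply(forecast$paths >= target, 1L, function(r)
    if (any(r)) which.max(r) else NA_integer_)
  censored <- is.na(hit)
  day <- ifelse(censored, forecast$horizon, forecast$census_day + hit)
  if (all(censored))
    warning("no path reaches the target by the horizon; all draws censored")
  list(day = as.numeric(day), censored = censored)
}
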