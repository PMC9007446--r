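# QQ model-validation diagnostics.
#
# Both diagnostics compare observed data to the modal model fixed at its
# posterior parameter means.  They return paired quantile data; plotting is
# left to the caller (plot a QQ line with plot(qq$theoretical, qq$observed)).

post_mean_params <- function(fit) {
  s <- summary(fit)
  stats::setNames(s$mean, s$parameter)
}

#' Random-effect distribution diagnostic
#'
#' Under the model, the posterior means of the per-center random effects
#' (computed at the posterior-mean hyperparameters) should approximately
#' follow the hierarchical \code{Gamma(alpha, alpha/phi)} distribution.
#' Departures, notably multimodality of the true rate distribution, bend
#' the QQ pairing away from the identity line.
#'
#' @param fit a \code{"model_fit"} (use the modal model of a
#'   \code{"bma_fit"}).
#' @param data the \code{\link{trial_data}} the fit was computed on.
#' @return an object of class \code{"qq_data"}: sorted observed per-center
#'   posterior-mean rates, theoretical gamma quantiles at plotting
#'   positions \code{(i - 0.5)/C}, and the fitted hyperparameters.
#' @export
qq_random_effects <- function(fit, data) {
  stopifnot(inherits(fit, "model_fit"), inherits(data, "trial_data"))
  pm <- post_mean_params(fit)
  tau <- observation_days(data)
  open <- names(tau)[tau > 0]
  if (length(open) < 10)
    warning("fewer than 10 initiated centers: the diagnostic has little power")
  if (!length(open)) stop("no initiated centers")
  n_per <- vapply(model_counts(data)[open], sum, numeric(1))
  G_tau <- if (fit$curve$kappa > 0)
    G_kappa(fit$curve, pm[["theta"]], tau[open]) else as.numeric(tau[open])
  phi_star <- pm[["phi"]] * (pm[["alpha"]] + n_per) /
    (pm[["alpha"]] + pm[["phi"]] * G_tau)
  C <- length(open)
  pp <- (seq_len(C) - 0.5) / C
  structure(list(observed = sort(unname(phi_star)),
                 theoretical = stats::qgamma(pp, shape = pm[["alpha"]],
                                             rate = pm[["alpha"]] / pm[["phi"]]),
                 label = "random-effect posterior means vs hierarchical gamma",
                 params = pm),
            class = "qq_data")
}

#' Initial-period recruitment diagnostic
#'
#' Under the model, each center's total recruitment over its first
#' \code{t_prime} days follows a negative binomial with shape \code{alpha}
#' and mean \code{phi * G(t_prime)}.  Comparing observed initial-period
#' totals (centers observed for at least \code{t_prime} days) with the
#' theoretical quantiles shows whether the fitted decay captures early
#' recruitment; a homogeneous fit to decaying data under-predicts it.
#'
#' @inheritParams qq_random_effects
#' @param t_prime initial-period length in days (default 60, two months):
#'   long enough for decay to show, short enough that many centers qualify.
#' @return an object of class \code{"qq_data"}.
#' @export
qq_initial_period <- function(fit, data, t_prime = 60) {
  stopifnot(inherits(fit, "model_fit"), inherits(data, "trial_data"))
  pm <- post_mean_params(fit)
  tau <- observation_days(data)
  elig <- names(tau)[tau >= t_prime]
  if (!length(elig))
    stop("no center has been recruiting for at least t_prime days")
  obs <- vapply(model_counts(data)[elig], function(y)
    sum(y[seq_len(t_prime)]), numeric(1))
  G_tp <- if (fit$curve$kappa > 0)
    G_kappa(fit$curve, pm[["theta"]], t_prime) else t_prime
  m <- length(elig)
  pp <- (seq_len(m) - 0.5) / m
  theo <- stats::qnbinom(pp, size = pm[["alpha"]],
                         mu = pm[["phi"]] * G_tp)
  structure(list(observed = sort(unname(obs)), theoretical = theo,
                 label = sprintf("initial %d-day totals vs negative binomial",
                                 t_prime),
                 params = pm),
            class = "qq_data")
}

#' @export
print.qq_data <- function(x, ...) {
  cat("QQ diagnostic:", x$label, "\n")
  cat(sprintf("  %d points; max |observed - theoretical| = %.4g\n",
              length(x$observed), max(abs(x$observed - x$theoretical))))
  invisible(x)
}
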