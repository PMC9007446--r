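# Bayesian inference for the inhomogeneous Poisson-gamma recruitment model.
#
# Hierarchy: lambda_c ~ Gamma(alpha, alpha/phi) i.i.d. across centers;
# N_c(t) | lambda_c ~ Pois(lambda_c [G(t) - G(t-1)]) on center-local days.
# Marginalizing lambda_c gives a closed-form likelihood in (alpha, phi,
# theta).  Inference is on the log parameters; each curve-shape kappa
# defines one model, combined by Bayesian model averaging.

#' Prior specification for the recruitment model
#'
#' Independent priors on the log parameters: \code{log(alpha) ~
#' N(alpha_mean, alpha_sd^2)} (weakly informative; center heterogeneity is
#' similar across trials), \code{log(phi) ~ U(phi_bounds)} (vague; mean
#' center recruitment varies by orders of magnitude between trials), and
#' for models with a decay parameter, a prior on \code{log(theta)} induced
#' by placing \code{Beta(beta_a, beta_b)} on the intensity drop-off ratio
#' \code{R_kappa = g(t0)/g(0)} after \code{t0} days (an interpretable
#' quantity; a near-uniform Beta(1.1, 1.1) expresses little information
#' beyond excluding no-decay and total-decay extremes).
#'
#' @param alpha_mean,alpha_sd normal prior mean and sd for \code{log(alpha)}.
#' @param phi_bounds length-2 uniform prior support for \code{log(phi)}.
#' @param beta_a,beta_b Beta prior shapes for the drop-off ratio.
#' @param t0 drop-off reference horizon in days (default 120, i.e. 4 months
#'   of 30 days).
#' @return an object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(alpha_mean = 0.2, alpha_sd = 2, phi_bounds = c(-8, 8),
                       beta_a = 1.1, beta_b = 1.1, t0 = 120) {
  stopifnot(alpha_sd > 0, length(phi_bounds) == 2L,
            phi_bounds[1] < phi_bounds[2], beta_a > 0, beta_b > 0, t0 > 0)
  structure(list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 phi_bounds = phi_bounds, beta_a = beta_a, beta_b = beta_b,
                 t0 = t0),
            class = "prior_spec")
}

# Precomputed likelihood context: everything about the data the likelihood
# needs, flattened for vectorized evaluation.
lik_context <- function(data) {
  cnts <- model_counts(data)
  open <- which(lengths(cnts) > 0L)
  tau <- lengths(cnts)[open]
  n_c <- vapply(cnts[open], sum, numeric(1))
  # flatten positive-count cells: local day index and count
  tv <- integer(0); yv <- numeric(0)
  for (y in cnts[open]) {
    pos <- which(y > 0L)
    tv <- c(tv, pos)
    yv <- c(yv, y[pos])
  }
  lfact <- sum(lgamma(yv + 1))
  list(tau = as.numeric(tau), n_c = n_c, tv = tv, yv = yv,
       max_tau = if (length(tau)) max(tau) else 0,
       lfact_const = lfact, C_open = length(open),
       n_total = sum(n_c))
}

#' Log-likelihood of the recruitment model
#'
#' Evaluates the marginal (random effects integrated out) log-likelihood of
#' the daily count data under the curve-shape model.  Parameters are given
#' on the log scale.  Centers not yet initiated contribute nothing.
#'
#' @param params named numeric vector with elements \code{log_alpha},
#'   \code{log_phi} and, for \code{kappa > 0}, \code{log_theta}.
#' @param curve a \code{\link{curve_model}}.
#' @param data a \code{\link{trial_data}} object.
#' @return the log-likelihood (a scalar).
#' @export
log_likelihood <- function(params, curve, data) {
  stopifnot(inherits(data, "trial_data"))
  ld <- lik_context(data)
  log_lik_ctx(params, curve, ld)
}

log_lik_ctx <- function(params, curve, ld) {
  if (any(!is.finite(params))) stop("parameters must be finite")
  alpha <- exp(params[["log_alpha"]])
  phi <- exp(params[["log_phi"]])
  if (ld$C_open == 0L) return(0)
  if (curve$kappa > 0) {
    theta <- exp(params[["log_theta"]])
    Gt <- G_kappa(curve, theta, 0:ld$max_tau)
    dG <- diff(Gt)
    shape_term <- sum(ld$yv * log(dG[ld$tv]))
    G_tau <- Gt[ld$tau + 1]
  } else {
    shape_term <- 0
    G_tau <- ld$tau
  }
  rate0 <- alpha / phi
  sum(alpha * log(rate0) - lgamma(alpha) + lgamma(alpha + ld$n_c) -
        (alpha + ld$n_c) * log(G_tau + rate0)) +
    shape_term - ld$lfact_const
}

#' Log prior density
#'
#' Joint log prior of the log parameters under a \code{\link{prior_spec}}.
#' The \code{log_theta} component is the Beta drop-off prior transported to
#' the log-theta scale by change of variables.  Returns \code{-Inf} (not an
#' error) when \code{log_phi} falls outside its uniform support.
#'
#' @inheritParams log_likelihood
#' @param prior a \code{\link{prior_spec}}.
#' @return the log prior density (a scalar, possibly \code{-Inf}).
#' @export
log_prior <- function(params, curve, prior) {
  stopifnot(inherits(prior, "prior_spec"), inherits(curve, "curve_model"))
  la <- params[["log_alpha"]]
  lp <- params[["log_phi"]]
  out <- stats::dnorm(la, prior$alpha_mean, prior$alpha_sd, log = TRUE)
  if (lp < prior$phi_bounds[1] || lp > prior$phi_bounds[2]) return(-Inf)
  out <- out - log(diff(prior$phi_bounds))
  if (curve$kappa > 0) {
    lt <- params[["log_theta"]]
    theta <- exp(lt)
    t0 <- prior$t0
    R <- drop_off_ratio(curve$kappa, theta, t0)
    # |dR/dtheta|: t0 (1 + theta t0 / k)^(-k-1) for finite k, t0 e^(-theta t0)
    # for the exponential tail; plus the Jacobian of theta = exp(log_theta).
    log_dR <- if (is.infinite(curve$kappa)) log(t0) - theta * t0
    else log(t0) - (curve$kappa + 1) * log1p(theta * t0 / curve$kappa)
    out <- out + stats::dbeta(R, prior$beta_a, prior$beta_b, log = TRUE) +
      log_dR + lt
  }
  out
}

default_init <- function(curve, data, prior) {
  ld <- lik_context(data)
  rate <- ld$n_total / max(sum(ld$tau), 1)
  lphi <- min(max(log(max(rate, 1e-6)), prior$phi_bounds[1] + 0.5),
              prior$phi_bounds[2] - 0.5)
  p <- c(log_alpha = prior$alpha_mean, log_phi = lphi)
  if (curve$kappa > 0) p <- c(p, log_theta = log(1 / prior$t0))
  p
}

#' Posterior mode and Hessian
#'
#' Maximizes the log posterior (log-likelihood plus log prior) in the log
#' parameters by quasi-Newton optimization from several jittered starting
#' points, and returns the mode together with the central finite-difference
#' Hessian there.  The Hessian must be negative definite; if not, the
#' search is retried from new jittered starts.
#'
#' @inheritParams log_prior
#' @param data a \code{\link{trial_data}} object with at least one
#'   initiated center.
#' @param init optional named starting vector; defaults to moment-based
#'   values (prior mean for \code{log_alpha}, log mean per-center-day rate
#'   for \code{log_phi}, \code{log(1/t0)} for \code{log_theta}).
#' @param n_starts number of jittered starting points.
#' @return list with \code{mode} (named vector), \code{hessian}, and
#'   \code{log_post} at the mode.
#' @export
find_mode <- function(curve, data, prior = prior_spec(), init = NULL,
                      n_starts = 5) {
  ld <- lik_context(data)
  if (ld$C_open == 0L) stop("no initiated centers: nothing to fit")
  if (is.null(init)) init <- default_init(curve, data, prior)
  d <- length(init)
  nlpost <- function(p) {
    names(p) <- names(init)
    v <- log_lik_ctx(p, curve, ld) + log_prior(p, curve, prior)
    if (!is.finite(v)) 1e10 else -v
  }
  eps <- 1e-3
  lower <- c(-20, prior$phi_bounds[1] + eps, -20)[seq_len(d)]
  upper <- c(20, prior$phi_bounds[2] - eps, 10)[seq_len(d)]
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- init + if (s == 1) 0 else stats::rnorm(d, 0, 0.5)
    p0 <- pmin(pmax(p0, lower), upper)
    opt <- tryCatch(
      stats::optim(p0, nlpost, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("posterior mode search failed from all starts")
  mode <- stats::setNames(best$par, names(init))
  f <- function(p) -nlpost(p)
  H <- fd_hessian(f, mode)
  if (any(eigen(-H, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    # retry from extra jittered starts before giving up
    for (s in seq_len(3)) {
      p0 <- pmin(pmax(mode + stats::rnorm(d, 0, 0.25), lower), upper)
      opt <- tryCatch(
        stats::optim(p0, nlpost, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(opt) && opt$value <= best$value + 1e-8) {
        mode <- stats::setNames(opt$par, names(init))
        H <- fd_hessian(f, mode)
        if (all(eigen(-H, symmetric = TRUE,
                      only.values = TRUE)$values > 0)) break
      }
    }
    if (any(eigen(-H, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("Hessian at the located mode is not negative definite; ",
           "log posterior value ", format(-best$value))
  }
  list(mode = mode, hessian = H, log_post = -best$value)
}

#' Importance-sampling fit of one curve-shape model
#'
#' Draws \code{M} samples from a multivariate t proposal on 4 degrees of
#' freedom centered at the posterior mode with shape matrix the inverse of
#' the negated Hessian, computes importance weights against the
#' unnormalized posterior, and estimates the log marginal likelihood as the
#' log mean weight.  The effective sample size
#' \eqn{(\sum w)^2 / \sum w^2} measures the reliability of the sample; a
#' warning is issued when it falls below \code{0.1 * M} (rerun with a
#' larger \code{M} in that case).
#'
#' @inheritParams find_mode
#' @param M number of importance samples.
#' @param seed optional integer seed.
#' @param proposal_df degrees of freedom of the t proposal.
#' @return an object of class \code{"model_fit"}: the curve, mode, Hessian,
#'   sample matrix, log weights, log marginal likelihood, and ESS.
#' @export
importance_fit <- function(curve, data, prior = prior_spec(), M = 1e4,
                           seed = NULL, init = NULL, n_starts = 5,
                           proposal_df = 4) {
  if (!is.null(seed)) set.seed(seed)
  ld <- lik_context(data)
  md <- find_mode(curve, data, prior, init = init, n_starts = n_starts)
  Sigma <- solve(-md$hessian)
  Sigma <- (Sigma + t(Sigma)) / 2
  ch <- tryCatch(chol(Sigma), error = function(e) chol(Sigma + 1e-8 * diag(nrow(Sigma))))
  X <- rmvt_chol(M, md$mode, ch, proposal_df)
  colnames(X) <- names(md$mode)
  log_q <- dmvt_chol(X, md$mode, ch, proposal_df)
  log_target <- apply(X, 1L, function(p) {
    names(p) <- names(md$mode)
    lpr <- log_prior(p, curve, prior)
    if (!is.finite(lpr)) return(-Inf)
    log_lik_ctx(p, curve, ld) + lpr
  })
  log_w <- log_target - log_q
  logZ <- log_mean_exp(log_w)
  w <- exp(log_w - max(log_w))
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 0.1 * M)
    warning(sprintf("low effective sample size (%.0f of %d); rerun with more samples",
                    ess, M))
  structure(
    list(curve = curve, mode = md$mode, hessian = md$hessian,
         samples = X, log_weights = log_w,
         log_marginal_likelihood = logZ, ess = ess, M = M,
         prior = prior,
         data_fingerprint = data_fingerprint(ld)),
    class = "model_fit")
}

data_fingerprint <- function(ld) {
  c(C = ld$C_open, n_total = ld$n_total, sum_tau = sum(ld$tau))
}

#' Posterior summaries of a fitted model
#'
#' Importance-weighted posterior means and equal-tailed 95\% credible
#' intervals of the natural-scale parameters.
#'
#' @param object a \code{"model_fit"}.
#' @param ... unused.
#' @return a data frame with one row per parameter.
#' @export
summary.model_fit <- function(object, ...) {
  w <- exp(object$log_weights - max(object$log_weights))
  w <- w / sum(w)
  nat <- exp(object$samples)
  colnames(nat) <- sub("^log_", "", colnames(object$samples))
  out <- lapply(colnames(nat), function(nm) {
    x <- nat[, nm]
    o <- order(x)
    cw <- cumsum(w[o])
    q <- function(p) x[o][which.max(cw >= p)]
    data.frame(parameter = nm, mean = sum(w * x),
               lower95 = q(0.025), upper95 = q(0.975))
  })
  do.call(rbind, out)
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Curve-shape model kappa = %s (tau_norm = %.1f)\n",
              format(x$curve$kappa), x$curve$tau_norm))
  cat(sprintf("  log marginal likelihood: %.3f   ESS: %.0f / %d\n",
              x$log_marginal_likelihood, x$ess, x$M))
  print(summary(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Posterior model probabilities
#'
#' Normalized posterior probabilities of a set of fitted curve-shape
#' models, proportional to marginal likelihood times prior model
#' probability.
#'
#' @param fits list of \code{"model_fit"} objects fitted to the same data.
#' @param prior_probs prior model probabilities (default equal); must sum
#'   to 1.
#' @return numeric vector summing to 1, named by kappa.
#' @export
model_probabilities <- function(fits, prior_probs = NULL) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "model_fit")))
  fps <- vapply(fits, `[[`, numeric(3), "data_fingerprint")
  if (length(fits) > 1L && any(apply(fps, 1L, function(r) length(unique(r))) != 1))
    stop("model fits do not share the same data")
  K <- length(fits)
  if (is.null(prior_probs)) prior_probs <- rep(1 / K, K)
  if (abs(sum(prior_probs) - 1) > 1e-8 || any(prior_probs < 0))
    stop("`prior_probs` must be a probability vector")
  lz <- vapply(fits, `[[`, numeric(1), "log_marginal_likelihood") +
    log(prior_probs)
  p <- exp(lz - log_sum_exp(lz))
  stats::setNames(p, vapply(fits, function(f) format(f$curve$kappa), ""))
}

#' Fit the curve-shape model family by Bayesian model averaging
#'
#' Fits each curve-shape in \code{kappas} to the data by importance
#' sampling and combines them with posterior model probabilities (equal
#' prior model probabilities by default).  The normalization horizon is the
#' mean observation length over initiated centers.
#'
#' @inheritParams importance_fit
#' @param kappas model grid of tail parameters (default
#'   \code{c(0, 0.5, 1, 2, Inf)}).
#' @param prior_probs prior model probabilities.
#' @return an object of class \code{"bma_fit"}: list of per-model fits,
#'   model probabilities, and the shared normalization horizon.
#' @examples
#' \donttest{
#' sim <- simulate_trial(sim_config(n_centers = 40, study_length = 200,
#'                                  seed = 1))
#' fit <- fit_recruitment(sim, M = 1000, seed = 2)
#' fit
#' }
#' @export
fit_recruitment <- function(data, kappas = c(0, 0.5, 1, 2, Inf),
                            prior = prior_spec(), M = 1e4, seed = NULL,
                            n_starts = 5, prior_probs = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (!is.null(seed)) set.seed(seed)
  tau <- observation_days(data)
  tau <- tau[tau > 0]
  if (!length(tau)) stop("no initiated centers: nothing to fit")
  tau_norm <- mean(tau)
  fits <- lapply(kappas, function(k)
    importance_fit(curve_model(k, tau_norm), data, prior, M = M,
                   n_starts = n_starts))
  probs <- model_probabilities(fits, prior_probs)
  structure(list(fits = fits, model_probs = probs, tau_norm = tau_norm,
                 kappas = kappas),
            class = "bma_fit")
}

#' @export
print.bma_fit <- function(x, ...) {
  cat("Bayesian model-averaged recruitment fit\n")
  cat(sprintf("  normalization horizon tau_norm = %.1f days\n\n", x$tau_norm))
  rows <- lapply(seq_along(x$fits), function(i) {
    f <- x$fits[[i]]
    s <- summary(f)
    fmt <- function(nm) {
      r <- s[s$parameter == nm, ]
      if (!nrow(r)) return("-")
      sprintf("%.3f (%.3f, %.3f)", r$mean, r$lower95, r$upper95)
    }
    data.frame(kappa = format(f$curve$kappa), alpha = fmt("alpha"),
               phi = fmt("phi"), theta = fmt("theta"),
               post_prob = sprintf("%.3g", x$model_probs[i]),
               ESS = sprintf("%.0f", f$ess))
  })
  print(do.call(rbind, rows), row.names = FALSE)
  invisible(x)
}

#' The modal (highest posterior probability) model of a BMA fit
#' @param fit a \code{"bma_fit"}.
#' @return the \code{"model_fit"} with the largest posterior probability.
#' @export
modal_model <- function(fit) {
  stopifnot(inherits(fit, "bma_fit"))
  fit$fits[[which.max(fit$model_probs)]]
}
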