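# Trial simulator: generates multi-center recruitment data from the
# decaying-intensity Poisson-gamma model and from deliberately
# misspecified variants (gamma-mixture random effects, Weibull-shaped
# intensity) for robustness studies.

#' Simulation configuration
#'
#' Describes a simulated multi-center trial.  The defaults reproduce the
#' reference simulation design: a 600-day study with 200 centers, random
#' effects \code{Gamma(alpha, alpha/phi)} with \code{alpha = 1.4},
#' \code{phi = 0.01}, and a decaying intensity with \code{kappa = 2.7},
#' \code{theta = 0.02} (a tail value deliberately outside the inference
#' grid), normalized at the mean observation length of the design.
#'
#' @param n_centers number of centers.
#' @param study_length trial length in days.
#' @param initiation \code{"uniform"} (i.i.d. uniform on the first 80\% of
#'   the study), \code{"clumped"} (openings bunched roughly every 60 days),
#'   or an explicit integer vector of initiation days.
#' @param alpha gamma random-effect shape.
#' @param phi mean recruitment rate; for the mixture this is
#'   \code{E[lambda] = (phi1 + phi2)/2}.
#' @param re_distribution \code{"gamma"} or \code{"gamma_mixture"} (equal
#'   mixture of \code{Gamma(alpha, alpha/phi1)} and
#'   \code{Gamma(alpha, alpha/phi2)}).
#' @param phi_ratio mixture mean ratio \code{phi2/phi1} (used only for the
#'   mixture; default 10).
#' @param intensity \code{"kappa"} (decaying curve-shape family) or
#'   \code{"weibull"} (intensity proportional to a Weibull density; peaks
#'   after initiation, a shape outside the model family).
#' @param kappa,theta curve-shape parameters (kappa may be any value
#'   \code{>= 0} or \code{Inf}; the discrete grid restriction applies to
#'   inference, not simulation).
#' @param weibull_theta,weibull_k Weibull intensity scale (days) and shape.
#' @param deterministic_first_recruitment if \code{TRUE}, one deterministic
#'   recruit is added on each center's first local day, emulating data sets
#'   where initiation days are taken to be first-recruitment days.
#' @param seed optional integer seed stored in the config.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_centers = 200, study_length = 600,
                       initiation = "uniform", alpha = 1.4, phi = 0.01,
                       re_distribution = c("gamma", "gamma_mixture"),
                       phi_ratio = 10,
                       intensity = c("kappa", "weibull"),
                       kappa = 2.7, theta = 0.02,
                       weibull_theta = 30, weibull_k = 1.5,
                       deterministic_first_recruitment = FALSE,
                       seed = NULL) {
  re_distribution <- match.arg(re_distribution)
  intensity <- match.arg(intensity)
  stopifnot(n_centers >= 1, study_length >= 2, alpha > 0, phi > 0,
            phi_ratio > 0, theta > 0, weibull_theta > 0, weibull_k > 0,
            kappa >= 0)
  structure(list(n_centers = as.integer(n_centers),
                 study_length = as.integer(study_length),
                 initiation = initiation, alpha = alpha, phi = phi,
                 re_distribution = re_distribution, phi_ratio = phi_ratio,
                 intensity = intensity, kappa = kappa, theta = theta,
                 weibull_theta = weibull_theta, weibull_k = weibull_k,
                 deterministic_first_recruitment =
                   isTRUE(deterministic_first_recruitment),
                 seed = seed),
            class = "sim_config")
}

#' Generate a center-initiation schedule
#'
#' @param scheme \code{"uniform"}, \code{"clumped"}, or an explicit integer
#'   vector of days (returned as given).
#' @param n_centers number of centers.
#' @param study_length study length in days; openings are placed within the
#'   first 80\% of it.
#' @param seed optional integer seed.
#' @return integer vector of initiation days.
#' @export
make_schedule <- function(scheme, n_centers, study_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(scheme)) {
    stopifnot(length(scheme) == n_centers, all(scheme >= 0))
    return(as.integer(scheme))
  }
  last <- floor(0.8 * study_length)
  switch(scheme,
    uniform = sample.int(last + 1L, n_centers, replace = TRUE) - 1L,
    clumped = {
      clumps <- seq(0L, last, by = 60L)
      centers <- sample(clumps, n_centers, replace = TRUE)
      jitter <- sample.int(15L, n_centers, replace = TRUE) - 8L  # +/- 7 days
      pmax(centers + jitter, 0L)
    },
    stop("unknown initiation scheme: ", scheme))
}

# Weibull-density-shaped integrated intensity, normalized to tau_norm
G_weibull <- function(t, theta, k, tau_norm) {
  tau_norm * (-expm1(-(t / theta)^k)) / (-expm1(-(tau_norm / theta)^k))
}

#' Simulate a multi-center recruitment trial
#'
#' Draws per-center recruitment rates from the configured random-effect
#' law, then daily counts \code{Pois(lambda_c [G(t) - G(t-1)])} on each
#' center's local days up to the end of the study.  The intensity is
#' normalized at the mean observation length of the generated design.
#' Ground truth (rates, initiation days, parameters) is attached as
#' attribute \code{"truth"} for recovery studies.  Use
#' \code{\link{truncate_trial}} to form an interim census data set.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional integer seed (overrides the one in the config).
#' @return a \code{\link{trial_data}} with census at the end of the study.
#' @examples
#' sim <- simulate_trial(sim_config(n_centers = 20, study_length = 100,
#'                                  seed = 42))
#' totals(sim)$n_total
#' @export
simulate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  C <- config$n_centers
  L <- config$study_length
  init <- make_schedule(config$initiation, C, L)
  tau <- pmax(L - init, 0L)
  tau_norm <- mean(tau[tau > 0])

  lambda <- switch(config$re_distribution,
    gamma = stats::rgamma(C, shape = config$alpha,
                          rate = config$alpha / config$phi),
    gamma_mixture = {
      # E[lambda] = (phi1 + phi2)/2 = phi with phi2 = phi_ratio * phi1
      phi1 <- 2 * config$phi / (1 + config$phi_ratio)
      phi2 <- config$phi_ratio * phi1
      comp <- sample(c(phi1, phi2), C, replace = TRUE)
      stats::rgamma(C, shape = config$alpha, rate = config$alpha / comp)
    })

  max_tau <- max(tau)
  Gt <- switch(config$intensity,
    kappa = if (config$kappa == 0) as.numeric(0:max_tau)
            else G_kappa(curve_model(config$kappa, tau_norm), config$theta,
                         0:max_tau),
    weibull = G_weibull(0:max_tau, config$weibull_theta, config$weibull_k,
                        tau_norm))
  dG <- diff(Gt)

  ids <- sprintf("C%03d", seq_len(C))
  counts <- vector("list", C)
  for (i in seq_len(C)) {
    if (tau[i] == 0L) { counts[[i]] <- integer(0); next }
    y <- stats::rpois(tau[i], lambda[i] * dG[seq_len(tau[i])])
    if (config$deterministic_first_recruitment) y[1L] <- y[1L] + 1L
    counts[[i]] <- y
  }
  names(counts) <- ids
  out <- trial_data(counts, stats::setNames(init, ids), census_day = L,
                    config$deterministic_first_recruitment)
  attr(out, "truth") <- list(lambda = stats::setNames(lambda, ids),
                             initiation = stats::setNames(init, ids),
                             tau_norm = tau_norm, config = config)
  out
}
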