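# Normalized decaying intensity curve-shape family.
#
# The intensity profile since center initiation is
#   g_kappa(t; theta) proportional to (1 + theta t / kappa)^(-kappa),
# with kappa = 0 the constant profile, kappa -> Inf the exponential tail
# exp(-theta t).  Each shape is normalized so that its integral over a
# representative horizon tau_norm equals tau_norm, which decouples the
# shape parameter theta from the magnitude parameters of the hierarchical
# gamma random effects.

KAPPA1_TOL <- 1e-6

#' Intensity curve-shape model
#'
#' A member of the decaying curve-shape family, identified by the tail
#' parameter \code{kappa} and the normalization horizon \code{tau_norm}.
#'
#' @param kappa tail-heaviness parameter, \code{>= 0}; \code{Inf} selects
#'   the exponential-tail shape.  The recommended model grid is
#'   \code{c(0, 0.5, 1, 2, Inf)}: heavy power-law tails through to
#'   exponential decay, with \code{kappa = 0} the time-homogeneous model.
#' @param tau_norm normalization horizon in days (\code{> 0}); typically
#'   the mean observation length across initiated centers.
#' @return an object of class \code{"curve_model"}.
#' @examples
#' cm <- curve_model(2, tau_norm = 300)
#' g_kappa(cm, theta = 0.02, t = c(0, 150, 300))
#' @export
curve_model <- function(kappa, tau_norm) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop("`kappa` must be a single value >= 0 (Inf allowed)")
  if (length(tau_norm) != 1L || !is.finite(tau_norm) || tau_norm <= 0)
    stop("`tau_norm` must be a single positive number")
  structure(list(kappa = as.numeric(kappa), tau_norm = as.numeric(tau_norm)),
            class = "curve_model")
}

#' @export
print.curve_model <- function(x, ...) {
  cat(sprintf("Intensity curve-shape: kappa = %s, tau_norm = %g\n",
              format(x$kappa), x$tau_norm))
  invisible(x)
}

check_theta <- function(curve, theta) {
  if (curve$kappa == 0) return(invisible(TRUE))
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("`theta` must be a single positive number for kappa > 0")
  invisible(TRUE)
}

#' Normalized intensity curve-shape
#'
#' Evaluates the normalized intensity profile \eqn{g_\kappa(t;\theta)}.
#' The profile integrates to \code{tau_norm} over \code{[0, tau_norm]}.
#'
#' @param curve a \code{\link{curve_model}}.
#' @param theta decay-speed parameter (\code{> 0}); ignored when
#'   \code{kappa = 0}.
#' @param t non-negative times since center initiation (vectorized); values
#'   beyond \code{tau_norm} are allowed (the normalization only fixes the
#'   scale on \code{[0, tau_norm]}).
#' @return numeric vector of intensities.
#' @export
g_kappa <- function(curve, theta, t) {
  stopifnot(inherits(curve, "curve_model"))
  check_theta(curve, theta)
  if (any(t < 0)) stop("`t` must be non-negative")
  k <- curve$kappa
  tb <- curve$tau_norm
  if (k == 0) return(rep(1, length(t)))
  if (is.infinite(k))
    return(theta * exp(-theta * t) * tb / (-expm1(-theta * tb)))
  if (abs(k - 1) < KAPPA1_TOL)
    return(theta / (1 + theta * t) * tb / log1p(theta * tb))
  # generic finite kappa: unnormalized (1 + theta t / k)^(-k), normalizing
  # constant integral_0^tau = (k / (theta (1 - k))) * expm1((1-k) log1p(theta tau / k))
  num <- exp(-k * log1p(theta * t / k))
  denom <- k / (theta * (1 - k)) * expm1((1 - k) * log1p(theta * tb / k))
  num * tb / denom
}

#' Integrated intensity curve-shape
#'
#' Evaluates \eqn{G_\kappa(t;\theta) = \int_0^t g_\kappa(s;\theta) ds}
#' using closed forms.  Satisfies \code{G(0) = 0} and
#' \code{G(tau_norm) = tau_norm}.
#'
#' @inheritParams g_kappa
#' @return numeric vector of integrated intensities.
#' @export
G_kappa <- function(curve, theta, t) {
  stopifnot(inherits(curve, "curve_model"))
  check_theta(curve, theta)
  if (any(t < 0)) stop("`t` must be non-negative")
  k <- curve$kappa
  tb <- curve$tau_norm
  if (k == 0) return(as.numeric(t))
  if (is.infinite(k))
    return(tb * expm1(-theta * t) / expm1(-theta * tb))
  if (abs(k - 1) < KAPPA1_TOL)
    return(tb * log1p(theta * t) / log1p(theta * tb))
  tb * expm1((1 - k) * log1p(theta * t / k)) /
    expm1((1 - k) * log1p(theta * tb / k))
}

#' Intensity drop-off ratio
#'
#' The ratio \eqn{R_\kappa = g_\kappa(t_0;\theta) / g_\kappa(0;\theta)}
#' of the intensity after \code{t0} days to the intensity at initiation:
#' \code{(1 + theta t0 / kappa)^(-kappa)} for finite \code{kappa},
#' \code{exp(-theta t0)} for \code{kappa = Inf}.  Strictly decreasing in
#' \code{theta}; this is the quantity given a Beta prior when constructing
#' the decay-parameter prior.
#'
#' @param kappa tail parameter, \code{> 0} (the constant shape has no
#'   drop-off parameter).
#' @param theta decay-speed parameter (\code{> 0}, vectorized).
#' @param t0 reference horizon in days (\code{> 0}).
#' @return values in \code{(0, 1)}.
#' @export
drop_off_ratio <- function(kappa, theta, t0) {
  if (length(kappa) != 1L || is.na(kappa) || kappa <= 0)
    stop("`kappa` must be positive (the constant shape has no drop-off)")
  if (any(theta <= 0) || t0 <= 0) stop("`theta` and `t0` must be positive")
  if (is.infinite(kappa)) exp(-theta * t0)
  else exp(-kappa * log1p(theta * t0 / kappa))
}
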