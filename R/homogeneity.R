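# Tests for decay in recruitment rates.
#
# Each center's daily count series is split in half around its own midpoint
# (dropping the middle day when the series length is odd), the first and
# second halves are summed across centers into X1 and X2, and homogeneity
# (equal halves) is tested one-sidedly against decay (X1 mean > X2 mean).

#' Center-aligned half-period counts
#'
#' Splits each center's daily count series into first and second halves of
#' equal length (removing the middle observation when the length is odd)
#' and aggregates across centers.
#'
#' @param data a \code{\link{trial_data}} object; at least one center must
#'   have two or more observed days.
#' @return list with aggregate half sums \code{x1}, \code{x2} and
#'   \code{per_center_halves}, a named list of two-element lists
#'   (\code{first}, \code{second}) of daily counts.
#' @export
split_centers <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  usable <- data$center_ids[lengths(data$counts) >= 2L]
  if (!length(usable))
    stop("no center has been observed for at least 2 days")
  halves <- lapply(data$counts[usable], function(y) {
    m <- length(y) %/% 2L
    if (length(y) %% 2L == 1L) y <- y[-(m + 1L)]  # drop the middle day
    list(first = y[seq_len(m)], second = y[m + seq_len(m)])
  })
  x1 <- sum(vapply(halves, function(h) sum(h$first), numeric(1)))
  x2 <- sum(vapply(halves, function(h) sum(h$second), numeric(1)))
  list(x1 = as.integer(x1), x2 = as.integer(x2), per_center_halves = halves)
}

#' One-sided Poisson likelihood-ratio test for rate decay
#'
#' Tests equality of the means of two Poisson counts against the one-sided
#' alternative that the first mean is larger.  The statistic is
#' \deqn{T_L = 2[x_1 \log x_1 + x_2 \log x_2 - (x_1+x_2)\log\{(x_1+x_2)/2\}]}
#' when \eqn{x_1 > x_2} and zero otherwise; under the null it is
#' asymptotically a 50/50 mixture of a point mass at zero and a chi-squared
#' on one degree of freedom, so the p-value is
#' \eqn{\frac{1}{2}\Pr(\chi^2_1 > T_L)} for a positive statistic and 1 at
#' zero.
#'
#' @param x1 aggregate first-half count.
#' @param x2 aggregate second-half count.
#' @return list with \code{statistic} and \code{p_value}.
#' @examples
#' lrt_decay(100, 70)
#' @export
lrt_decay <- function(x1, x2) {
  if (length(x1) != 1L || length(x2) != 1L || x1 < 0 || x2 < 0 ||
      x1 != round(x1) || x2 != round(x2))
    stop("`x1` and `x2` must be single non-negative integers")
  if (x1 + x2 == 0) stop("both counts are zero: no information")
  stat <- if (x1 > x2) {
    xlogx <- function(x) if (x > 0) x * log(x) else 0
    2 * (xlogx(x1) + xlogx(x2) - xlogx(x1 + x2) + (x1 + x2) * log(2))
  } else 0
  p <- if (stat > 0) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(statistic = stat, p_value = p)
}

# Bootstrap engine shared by the test and the power study.  For one center
# with an even-length (middle-removed) series of 2m daily counts, a
# bootstrap replicate resamples the 2m days i.i.d. from their empirical
# distribution and takes (sum of first m) - (sum of last m).  Equivalently,
# both half sums are i.i.d. sums of m draws from the empirical value
# distribution, which we draw as value-weighted multinomial counts.
# `halves` is the per_center_halves structure from split_centers().
bst_draws <- function(halves, n_boot) {
  D <- numeric(n_boot)
  for (h in halves) {
    y <- c(h$first, h$second)
    m <- length(h$first)
    tab <- table(y)
    vals <- as.numeric(names(tab))
    if (length(vals) == 1L) next  # no resampling variation in this center
    pr <- as.numeric(tab) / length(y)
    a <- drop(vals %*% stats::rmultinom(n_boot, m, pr))
    b <- drop(vals %*% stats::rmultinom(n_boot, m, pr))
    D <- D + (a - b)
  }
  D
}

#' Non-parametric bootstrap test for rate decay
#'
#' Tests for decay assuming only that daily counts within each center are
#' i.i.d. under the null.  The observed statistic is \eqn{D = X_1 - X_2}
#' (difference of aggregate half sums).  Each bootstrap replicate resamples
#' every center's (middle-removed) daily counts with replacement, re-splits
#' them into halves and recomputes the statistic; the p-value is the
#' finite-sample-corrected upper tail proportion
#' \eqn{(1 + \#\{D^* \ge D\}) / (B + 1)}.
#'
#' @param data a \code{\link{trial_data}} object.
#' @param n_boot number of bootstrap replicates (\code{>= 100}).
#' @param seed optional integer seed.
#' @return list with \code{observed_diff}, \code{p_value}, \code{x1},
#'   \code{x2}.
#' @export
bootstrap_decay_test <- function(data, n_boot = 1000, seed = NULL) {
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  sp <- split_centers(data)
  D_obs <- sp$x1 - sp$x2
  if (sp$x1 + sp$x2 == 0)  # degenerate: no events, no resampling variation
    return(list(observed_diff = 0L, p_value = 1, x1 = 0L, x2 = 0L))
  D_star <- bst_draws(sp$per_center_halves, n_boot)
  p <- (1 + sum(D_star >= D_obs)) / (n_boot + 1)
  list(observed_diff = as.integer(D_obs), p_value = p,
       x1 = sp$x1, x2 = sp$x2)
}

#' Monte-Carlo power study for the decay tests
#'
#' Estimates the rejection rate at level \code{level} of either decay test
#' under Poisson sampling, on the grid of aggregate first-half expectation
#' \code{mu1} and decay ratio \code{R} (second-half expectation
#' \code{R * mu1}).
#'
#' For the likelihood-ratio test, the aggregate sums are drawn directly:
#' \code{X1 ~ Pois(mu1)}, \code{X2 ~ Pois(R * mu1)}.  For the bootstrap
#' test, each replicate generates \code{n_centers} centers with
#' \code{2 * days_per_half} days of i.i.d. Poisson daily counts whose
#' aggregate half means equal \code{mu1} and \code{R * mu1}.
#'
#' @param mu1 aggregate expectation of the first-half sum.
#' @param R ratio of second-half to first-half expectation, in (0, 1].
#' @param test \code{"lrt"} or \code{"bst"}.
#' @param n_reps number of Monte-Carlo test replicates.
#' @param n_boot bootstrap replicates per test (bst only).
#' @param n_centers,days_per_half data structure for the bst design.
#' @param level significance level.
#' @param seed optional integer seed.
#' @return estimated power (a proportion).
#' @export
power_study <- function(mu1, R, test = c("lrt", "bst"), n_reps = 1e5,
                        n_boot = 1000, n_centers = 20, days_per_half = 30,
                        level = 0.05, seed = NULL) {
  test <- match.arg(test)
  stopifnot(mu1 > 0, R > 0, R <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (test == "lrt") {
    x1 <- stats::rpois(n_reps, mu1)
    x2 <- stats::rpois(n_reps, R * mu1)
    # vectorized statistic; p < level iff T_L exceeds the mixture critical
    # value 0.5 P(chi2_1 > T) < level  <=>  T > qchisq(1 - 2*level, 1)
    xlx <- function(x) ifelse(x > 0, x * log(x), 0)
    stat <- ifelse(x1 > x2,
                   2 * (xlx(x1) + xlx(x2) - xlx(x1 + x2) + (x1 + x2) * log(2)),
                   0)
    crit <- stats::qchisq(1 - 2 * level, df = 1)
    return(mean(stat > crit & stat > 0))
  }
  # bst: i.i.d. Poisson daily counts, aggregate first-half mean mu1
  r1 <- mu1 / (n_centers * days_per_half)
  r2 <- R * r1
  m <- days_per_half
  rej <- 0L
  for (rep in seq_len(n_reps)) {
    D_obs <- 0
    D_star <- numeric(n_boot)
    for (cc in seq_len(n_centers)) {
      y <- c(stats::rpois(m, r1), stats::rpois(m, r2))
      D_obs <- D_obs + sum(y[seq_len(m)]) - sum(y[m + seq_len(m)])
      tab <- tabulate(y + 1L)
      vals <- which(tab > 0L) - 1L
      if (length(vals) == 1L) next
      pr <- tab[tab > 0L] / (2 * m)
      a <- drop(vals %*% stats::rmultinom(n_boot, m, pr))
      b <- drop(vals %*% stats::rmultinom(n_boot, m, pr))
      D_star <- D_star + (a - b)
    }
    p <- (1 + sum(D_star >= D_obs)) / (n_boot + 1)
    if (p < level) rej <- rej + 1L
  }
  rej / n_reps
}
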