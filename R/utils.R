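# --- truncated-distribution helpers used by the cohort generator -----------
#
# Chronic headache-day counts and attack durations are simulated from
# truncated normal / lognormal distributions. Truncation shifts the mean, so
# the location parameter is solved numerically (uniroot) such that the
# *truncated* mean equals the calibration target.

tnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  # far outside the window the truncated mean degenerates to the near bound
  if (!is.finite(z) || z < 1e-12) {
    return(if (mu < (lo + hi) / 2) lo else hi)
  }
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

tnorm_location <- function(target, sd, lo, hi) {
  stats::uniroot(
    function(mu) tnorm_mean(mu, sd, lo, hi) - target,
    interval = c(lo - 10 * sd, hi + 10 * sd), tol = 1e-10
  )$root
}

rtnorm <- function(n, mu, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mu, sd)
  p_hi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mu, sd)
}

# mean of lognormal(mu, sigma) truncated to [lo, hi]
tlnorm_mean <- function(mu, sigma, lo, hi) {
  denom <- stats::plnorm(hi, mu, sigma) - stats::plnorm(lo, mu, sigma)
  if (!is.finite(denom) || denom < 1e-12) {
    return(if (mu < (log(lo) + log(hi)) / 2) lo else hi)
  }
  num <- exp(mu + sigma^2 / 2) *
    (stats::pnorm((log(hi) - mu - sigma^2) / sigma) -
       stats::pnorm((log(lo) - mu - sigma^2) / sigma))
  num / denom
}

tlnorm_location <- function(target, sigma, lo, hi) {
  stats::uniroot(
    function(mu) tlnorm_mean(mu, sigma, lo, hi) - target,
    interval = c(log(lo) - 5, log(hi) + 5), tol = 1e-10
  )$root
}

rtlnorm <- function(n, mu, sigma, lo, hi) {
  p_lo <- stats::plnorm(lo, mu, sigma)
  p_hi <- stats::plnorm(hi, mu, sigma)
  stats::qlnorm(stats::runif(n, p_lo, p_hi), mu, sigma)
}

# lognormal sigma matching a coefficient of variation sd/mean
lnorm_sigma_from_cv <- function(mean, sd) sqrt(log(1 + (sd / mean)^2))

# negative-binomial size parameter matching a mean/sd pair (requires sd^2 > mean)
nbinom_size <- function(mean, sd) {
  stopifnot(sd^2 > mean)
  mean^2 / (sd^2 - mean)
}
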