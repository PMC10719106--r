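# Internal helpers: seed scoping, logit-scale calibration, truncated normals.

`%||%` <- function(a, b) if (is.null(a)) b else a

ARM_LEVELS <- c("placebo", "health", "low_cash", "high_cash")
TREATED_ARMS <- c("health", "low_cash", "high_cash")

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seeds spawned from one master seed (kept < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Marginal success probability of a logistic-normal cluster model
#'
#' For a binary outcome with cluster-level random intercepts,
#' `P(y = 1) = E[plogis(mu + sigma * Z)]` with `Z ~ N(0, 1)`. Computed by
#' adaptive quadrature.
#'
#' @param mu Conditional (cluster-median) log-odds.
#' @param sigma Random-intercept standard deviation on the logit scale.
#' @return A probability in (0, 1).
#' @export
marginal_rate <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  if (sigma < 1e-10) return(stats::plogis(mu))
  stats::integrate(function(z) stats::plogis(mu + sigma * z) * stats::dnorm(z),
                   -9, 9, rel.tol = 1e-10)$value
}

#' Observed-scale (ANOVA) intracluster correlation of a logistic-normal model
#'
#' The ICC of the 0/1 outcome itself: `var(p_c) / (pbar * (1 - pbar))` where
#' `p_c = plogis(mu + sigma * Z)`. This is the quantity the one-way ANOVA
#' estimator targets, and is smaller than the latent-scale ICC
#' `sigma^2 / (sigma^2 + pi^2/3)` for the same `sigma`.
#'
#' @inheritParams marginal_rate
#' @return ICC in [0, 1).
#' @export
observed_icc <- function(mu, sigma) {
  if (sigma < 1e-10) return(0)
  p1 <- marginal_rate(mu, sigma)
  p2 <- stats::integrate(function(z) stats::plogis(mu + sigma * z)^2 * stats::dnorm(z),
                         -9, 9, rel.tol = 1e-10)$value
  (p2 - p1^2) / (p1 * (1 - p1))
}

#' Conditional log-odds that yields a target marginal rate
#'
#' Solves `E[plogis(mu + sigma Z)] = p` for `mu`, so that arm-level marginal
#' rates can be fixed exactly regardless of the cluster-intercept scale.
#'
#' @param p Target marginal probability.
#' @param sigma Logit-scale random-intercept SD.
#' @return The conditional log-odds `mu`.
#' @export
mu_for_marginal <- function(p, sigma) {
  stopifnot(p > 0, p < 1, sigma >= 0)
  if (sigma < 1e-10) return(stats::qlogis(p))
  stats::uniroot(function(mu) marginal_rate(mu, sigma) - p,
                 lower = stats::qlogis(p) - 6 * sigma - 1,
                 upper = stats::qlogis(p) + 6 * sigma + 1,
                 tol = 1e-10)$root
}

#' Random-intercept SD calibrated to an observed-scale ICC
#'
#' Finds `sigma` such that the logistic-normal model with marginal rate `p`
#' has observed-scale ICC `icc` (the marginal rate is held at `p` by
#' re-solving `mu` at each trial `sigma`).
#'
#' @param icc Target ANOVA-scale ICC in [0, 1).
#' @param p Marginal success probability at which to calibrate.
#' @return The logit-scale SD `sigma >= 0`.
#' @seealso [sigma_for_latent_icc()] for the latent-logistic convention.
#' @export
sigma_for_observed_icc <- function(icc, p) {
  stopifnot(icc >= 0, icc < 1, p > 0, p < 1)
  if (icc < 1e-12) return(0)
  f <- function(sigma) observed_icc(mu_for_marginal(p, sigma), sigma) - icc
  stats::uniroot(f, lower = 1e-6, upper = 12, extendInt = "upX", tol = 1e-9)$root
}

#' Random-intercept SD for a latent-scale ICC
#'
#' Inverts `icc = sigma^2 / (sigma^2 + pi^2/3)`, the ICC of the latent
#' logistic variable.
#'
#' @param icc Latent-scale ICC in [0, 1).
#' @return `sigma`.
#' @export
sigma_for_latent_icc <- function(icc) {
  stopifnot(icc >= 0, icc < 1)
  sqrt(icc / (1 - icc) * pi^2 / 3)
}

#' Latent-scale ICC implied by a random-intercept SD
#' @param sigma Logit-scale SD.
#' @return ICC in [0, 1).
#' @export
latent_icc <- function(sigma) sigma^2 / (sigma^2 + pi^2 / 3)

# Moments of a normal(mu, sigma) truncated below at `lower`.
tnorm_moments <- function(mu, sigma, lower) {
  a <- (lower - mu) / sigma
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) so the lower-truncated normal has the target moments.
tnorm_params <- function(mean, sd, lower = 0) {
  stopifnot(mean > lower, sd > 0)
  obj <- function(th) {
    mo <- tnorm_moments(th[1], exp(th[2]), lower)
    sum((mo - c(mean, sd))^2)
  }
  o <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  list(mu = o$par[1], sigma = exp(o$par[2]), value = o$value)
}

# Inverse-CDF sampler for the lower-truncated normal.
rtnorm <- function(n, mu, sigma, lower) {
  p0 <- stats::pnorm(lower, mu, sigma)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mu, sigma)
}

# Draw n values from a truncated normal whose *truncated* moments match
# (mean, sd); used to emulate published covariate summary rows.
rtnorm_matched <- function(n, mean, sd, lower = 0) {
  th <- tnorm_params(mean, sd, lower)
  rtnorm(n, th$mu, th$sigma, lower)
}

assert_cols <- function(df, cols, what = "records") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
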