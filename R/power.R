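# Simulation-based and closed-form power for the four-arm clustered design.

#' Design effect of cluster sampling
#'
#' `1 + (m - 1) * icc`: the variance inflation of a cluster sample of size
#' `m` relative to independent sampling.
#'
#' @param m Cluster size.
#' @param icc Intracluster correlation.
#' @return The design effect.
#' @export
design_effect <- function(m, icc) 1 + (m - 1) * icc

#' Simulation-based power of the four-arm clustered design
#'
#' Per replicate: villages are grouped into quadruplets and the four arms
#' assigned within each quadruplet through the design's own assignment law
#' ([assign_arms()]); village-level success probabilities follow the
#' logistic-normal model calibrated so the observed-scale ICC equals `icc`
#' and marginal rates equal `baseline_rate` (placebo, health) and
#' `baseline_rate + effect` (both cash arms); the pooled-cash versus placebo
#' contrast is tested with the cluster-robust t-test
#' ([diff_in_means_clustered()]) at level `alpha`. Power is the rejection
#' fraction.
#'
#' `n_villages` is rounded to a whole number of quadruplets (310 villages
#' becomes 78 quadruplets = 312 villages, mirroring the fielded design).
#'
#' @param n_villages Total villages across arms.
#' @param per_village Participants per village.
#' @param baseline_rate Placebo-arm success probability.
#' @param effect Absolute difference in proportions added to the cash arms
#'   (0.06 means 6 percentage points).
#' @param icc Observed-scale ICC of the outcome.
#' @param alpha Two-sided test level.
#' @param reps Number of simulated trials (>= 100).
#' @param seed Integer seed.
#' @return Object of class `power_result`: list with `power`, `mc_se`,
#'   `n_villages` (as used), `per_village`, `effect`, `icc_assumed`,
#'   `alpha`, `reps`, `analytic` (the closed-form benchmark).
#' @export
simulate_power <- function(n_villages = 310, per_village = 21,
                           baseline_rate = 0.36, effect = 0.06, icc = 0.02,
                           alpha = 0.05, reps = 500, seed = 1L) {
  stopifnot(reps >= 100)
  if (baseline_rate + effect <= 0 || baseline_rate + effect >= 1 ||
      baseline_rate <= 0 || baseline_rate >= 1) {
    stop("baseline_rate and baseline_rate + effect must lie in (0, 1)")
  }
  n_quads <- max(1L, as.integer(round(n_villages / 4)))
  n_v <- 4L * n_quads
  sigma <- sigma_for_observed_icc(icc, baseline_rate)
  mu <- c(placebo = mu_for_marginal(baseline_rate, sigma),
          health = mu_for_marginal(baseline_rate, sigma),
          low_cash = mu_for_marginal(baseline_rate + effect, sigma),
          high_cash = mu_for_marginal(baseline_rate + effect, sigma))
  members <- matrix(seq_len(n_v), nrow = 4L)
  rej <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      arms <- unlist(lapply(seq_len(n_quads), function(q) {
        assign_arms(members[, q])$arm
      }), use.names = FALSE)
      u <- stats::rnorm(n_v, 0, sigma)
      pc <- stats::plogis(mu[arms] + u)
      k <- stats::rbinom(n_v, per_village, pc)
      grp <- ifelse(arms %in% c("low_cash", "high_cash"), 1L,
                    ifelse(arms == "placebo", 2L, NA_integer_))
      keep <- !is.na(grp)
      st <- diff_from_cluster_stats(rep(per_village, sum(keep)),
                                    (k / per_village)[keep], grp[keep])
      as.numeric(st$p < alpha)
    }, numeric(1))
  })
  power <- mean(rej)
  n_eff <- n_quads * per_village / design_effect(per_village, icc)
  structure(list(
    power = power,
    mc_se = sqrt(power * (1 - power) / reps),
    n_villages = n_v, per_village = per_village,
    baseline_rate = baseline_rate, effect = effect, icc_assumed = icc,
    alpha = alpha, reps = reps,
    analytic = analytic_power(2 * n_eff, n_eff, baseline_rate, effect, alpha)
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Simulated power %.3f (MC SE %.3f) | %d villages x %d, effect %.2f, ICC %.2f, alpha %.2f, %d reps\n",
    x$power, x$mc_se, x$n_villages, x$per_village, x$effect, x$icc_assumed,
    x$alpha, x$reps))
  cat(sprintf("Closed-form benchmark: %.3f\n", x$analytic))
  invisible(x)
}

#' Closed-form two-proportion power with effective sample sizes
#'
#' Normal-approximation power of the two-sided two-proportion test after the
#' cluster design effect has been absorbed into the effective sample sizes
#' (`n_eff = n / (1 + (m - 1) icc)`). Arm a is the treated arm at
#' `baseline_rate + effect`.
#'
#' @param n_eff_a,n_eff_b Effective sample sizes of the two arms
#'   (`n_eff_b` defaults to `n_eff_a`).
#' @param baseline_rate Control-arm success probability.
#' @param effect Absolute risk difference.
#' @param alpha Two-sided level.
#' @return The power (a probability).
#' @export
analytic_power <- function(n_eff_a, n_eff_b = n_eff_a, baseline_rate,
                           effect, alpha = 0.05) {
  p1 <- baseline_rate + effect
  p0 <- baseline_rate
  stopifnot(p1 > 0, p1 < 1, p0 > 0, p0 < 1)
  se <- sqrt(p1 * (1 - p1) / n_eff_a + p0 * (1 - p0) / n_eff_b)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(effect) / se - z) + stats::pnorm(-abs(effect) / se - z)
}
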