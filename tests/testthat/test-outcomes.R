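test_that("latent and observed ICC calibrations are consistent", {
  expect_equal(latent_icc(sigma_for_latent_icc(0.15)), 0.15, tolerance = 1e-12)
  expect_equal(sigma_for_observed_icc(0, 0.5), 0)
  for (rho in c(0.05, 0.15, 0.64)) {
    s <- sigma_for_observed_icc(rho, 0.4)
    expect_equal(observed_icc(mu_for_marginal(0.4, s), s), rho, tolerance = 1e-7)
    # observed-scale ICC needs more latent variance than the latent-scale one
    expect_gt(s, sigma_for_latent_icc(rho) - 1e-9)
  }
  # marginal rate held at target while sigma varies
  expect_equal(marginal_rate(mu_for_marginal(0.746, 2.5), 2.5), 0.746,
               tolerance = 1e-9)
})

test_that("null outcome model gives rate one half and near-zero ICC", {
  params <- uniform_params(flat_rates(0.5), icc = 0)
  tr <- sim_trial(params, quads_per_district = 13, per_village = 19, seed = 3)
  y <- tr$records$intention
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / length(y)))
  ic <- icc_anova(tr$records, "intention")
  expect_lt(abs(ic$icc), 0.02)
})

test_that("ANOVA ICC recovers the observed-scale calibration target", {
  d <- simulate_clustered_binary(310, 19, p = 0.746, icc = 0.15, seed = 21)
  ic <- icc_anova(d, "y")
  expect_gt(ic$icc, 0.12)
  expect_lt(ic$icc, 0.18)
  # weaker clustering level
  d2 <- simulate_clustered_binary(310, 19, p = 0.5, icc = 0.05, seed = 22)
  expect_lt(abs(icc_anova(d2, "y")$icc - 0.05), 0.03)
})

test_that("arm-rate calibration reproduces a 12.3-point verified contrast", {
  params <- uniform_params(
    c(placebo = 0.284, health = 0.216, low_cash = 0.407, high_cash = 0.259),
    icc = 0.02)
  tr <- sim_trial(params, quads_per_district = 17, per_village = 21, seed = 9)
  d <- diff_in_means_clustered(tr$records, "verified_vax", "low_cash", "placebo")
  expect_lt(abs(d$diff - 12.3), 4)
  expect_lt(abs(d$rate_b - 28.4), 3)
})

test_that("outcome simulation is deterministic and masks consistently", {
  params <- trial_outcome_params()
  tr <- sim_trial(params, quads_per_district = 3, per_village = 10, seed = 5)
  rec2 <- simulate_outcomes(tr$records[, !(names(tr$records) %in%
    c("intention", "reported_vax", "verified_vax"))], tr$plan, params, seed = 7)
  rec3 <- simulate_outcomes(tr$records[, !(names(tr$records) %in%
    c("intention", "reported_vax", "verified_vax"))], tr$plan, params, seed = 7)
  expect_identical(rec2, rec3)

  att <- simulate_attrition(rec2, seed = 11)
  expect_true(all(is.na(att$reported_vax) == (att$recontacted == 0)))
  expect_true(all(is.na(att$verified_vax) == (att$verified_status_found == 0)))

  # unassigned village errors
  bad <- rec2
  bad$village_id[1] <- "nowhere"
  bad$arm <- NULL
  expect_error(simulate_outcomes(bad, tr$plan, params, seed = 1),
               "without an assigned arm")
})

test_that("untreated spillover residents have no intention outcome", {
  params <- trial_outcome_params()
  v <- toy_villages(n = 12, districts = "D1")
  plan <- randomize_trial(v, 3, seed = 2)
  rec <- sim_records(plan, per_village = 8, seed = 3)
  un <- rec[rec$village_id %in% unique(rec$village_id), ][1:24, ]
  un$individual_id <- paste0(un$individual_id, "_u")
  un$untreated_spillover <- TRUE
  un$video <- "none"
  rec <- dplyr::bind_rows(rec, un)
  out <- simulate_outcomes(rec, plan, params, seed = 4)
  expect_true(all(is.na(out$intention[out$untreated_spillover])))
  expect_true(all(!is.na(out$verified_vax[out$untreated_spillover])))
})

test_that("misreport link ties reported to verified at the configured flip rates", {
  params <- trial_outcome_params(misreport = list(fp = 0.155, fn = 0.05))
  tr <- sim_trial(params, quads_per_district = 13, per_village = 21, seed = 13)
  r <- tr$records
  # P(reported = 1) = P(v=1)(1-fn) + P(v=0) fp
  pv <- mean(r$verified_vax)
  expected <- pv * 0.95 + (1 - pv) * 0.155
  expect_lt(abs(mean(r$reported_vax) - expected), 0.02)
  # flips are directional: few verified-positives report negative
  expect_lt(mean(r$reported_vax[r$verified_vax == 1] == 0), 0.08)
})

test_that("attrition hits the configured retention rates and MAR-on-arm is detectable", {
  params <- trial_outcome_params()
  tr <- sim_trial(params, quads_per_district = 13, per_village = 21, seed = 15)
  att <- simulate_attrition(tr$records, seed = 16)
  n <- nrow(att)
  expect_equal(n, 6552L)  # 312 villages x 21
  # ~30% recontact attrition, ~48% verification attrition at trial size
  expect_gt(sum(att$recontacted), round(0.695 * n) - 3 * sqrt(n * 0.7 * 0.3))
  expect_lt(sum(att$recontacted), round(0.695 * n) + 3 * sqrt(n * 0.7 * 0.3))
  expect_lt(abs(mean(att$verified_status_found) - 3075 / 5900), 0.03)

  pa <- trial_attrition_params(
    recontact = list(intercept = stats::qlogis(0.70),
                     arm = c(health = 0, low_cash = -0.8, high_cash = 0)))
  att2 <- simulate_attrition(tr$records, pa, seed = 17)
  fit <- attrition_logit(att2, "recontact")
  row <- fit$or_table[fit$or_table$term == "low_cash", ]
  expect_lt(row$or_high, 1)  # differential attrition detected
  expect_lt(row$estimate, 0)
})
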