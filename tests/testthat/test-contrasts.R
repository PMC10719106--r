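mk_counts <- function(successes, n, label = "x") {
  tibble::tibble(video = label, y = rep(c(1L, 0L), c(successes, n - successes)))
}

test_that("arm rates reproduce printed count arithmetic", {
  expect_equal(round(arm_rate(mk_counts(1895, 2669), "y", "x")$rate, 1), 71.0)
  expect_equal(round(arm_rate(mk_counts(672, 1850), "y", "x")$rate, 1), 36.3)
  expect_equal(arm_rate(mk_counts(0, 50), "y", "x")$rate, 0)
  r <- arm_rate(mk_counts(10, 40), "y", "x")
  expect_equal(r$successes, 10)
  expect_equal(r$n, 40)
  expect_error(arm_rate(mk_counts(1, 2), "y", "absent"), "no observed")
  # missing outcomes drop out of the denominator
  d <- mk_counts(5, 10)
  d$y[1:2] <- NA
  expect_equal(arm_rate(d, "y", "x")$n, 8)
})

test_that("pooled rates are sample-size weighted", {
  expect_equal(round(pooled_rate(c(40.7, 25.9), c(548, 510)), 1), 33.6)
  expect_equal(round(pooled_rate(c(28.4, 21.6, 40.7, 25.9),
                                 c(1544, 473, 548, 510)), 1), 29.1)
  expect_equal(pooled_rate(55.5, 123), 55.5)
  expect_error(pooled_rate(c(1, 2), 3), "equal length")
  expect_error(pooled_rate(c(1, 2), c(3, 0)), "positive")
})

test_that("cluster-robust difference in means equals the weighted cluster-mean regression", {
  set.seed(42)
  d <- tibble::tibble(
    village_id = rep(sprintf("c%d", 1:6), times = c(5, 8, 12, 6, 9, 10)),
    video = rep(c("a", "b"), times = c(25, 25)),
    y = rbinom(50, 1, rep(c(0.7, 0.5, 0.6, 0.3, 0.45, 0.35), times = c(5, 8, 12, 6, 9, 10)))
  )
  est <- diff_in_means_clustered(d, "y", "a", "b")

  # independent oracle: weighted OLS of cluster means on the arm dummy
  cm <- aggregate(y ~ video + village_id, data = d, FUN = mean)
  cw <- aggregate(y ~ video + village_id, data = d, FUN = length)
  fit <- lm(cm$y ~ I(cm$video == "a"), weights = cw$y)
  sm <- summary(fit)
  expect_equal(est$diff, 100 * unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(est$se, 100 * sm$coefficients[2, 2], tolerance = 1e-12)
  expect_equal(est$df, fit$df.residual)
  expect_equal(est$p_value, sm$coefficients[2, 4], tolerance = 1e-12)

  # t CI brackets the estimate
  expect_lte(est$ci_low, est$diff)
  expect_gte(est$ci_high, est$diff)
})

test_that("degenerate contrasts behave: identical arms, too few clusters", {
  d <- tibble::tibble(village_id = rep(c("c1", "c2", "c3", "c4"), each = 4),
                      video = rep(c("a", "b"), each = 8),
                      y = rep(c(1, 0, 1, 0), each = 4))
  est <- diff_in_means_clustered(d, "y", "a", "b")
  expect_equal(est$diff, 0)
  expect_equal(est$p_value, 1)
  d1 <- d[d$village_id != "c2", ]
  expect_error(diff_in_means_clustered(d1, "y", "a", "b"), "at least 2 clusters")
})

test_that("arm counts partition the sample", {
  params <- trial_outcome_params()
  tr <- sim_trial(params, quads_per_district = 3, districts = c("D1", "D2"),
                  per_village = 21, seed = 19)
  rates <- dplyr::bind_rows(lapply(arm_levels(), function(a) {
    arm_rate(tr$records, "intention", a)
  }))
  expect_equal(sum(rates$n), nrow(tr$records))
  expect_equal(sum(rates$successes), sum(tr$records$intention))
})

test_that("ANOVA ICC: limits, null, undefined case, and CI methods", {
  # between-cluster variation only: ICC = 1 exactly (MSW = 0)
  d1 <- tibble::tibble(village_id = rep(1:10, each = 6),
                       y = rep(rep(c(0, 1), 5), each = 6))
  expect_equal(icc_anova(d1, "y")$icc, 1)

  # i.i.d. Bernoulli ignoring clusters: ICC within 0 +/- 0.02
  set.seed(8)
  d2 <- tibble::tibble(village_id = rep(1:310, each = 19),
                       y = rbinom(310 * 19, 1, 0.4))
  ic2 <- icc_anova(d2, "y")
  expect_lt(abs(ic2$icc), 0.02)
  expect_lte(ic2$ci_low, ic2$icc)
  expect_gte(ic2$ci_high, ic2$icc)

  # all-constant outcome is undefined and flagged
  d3 <- tibble::tibble(village_id = rep(1:4, each = 3), y = rep(1, 12))
  expect_warning(ic3 <- icc_anova(d3, "y"), "undefined")
  expect_true(is.na(ic3$icc))

  # bootstrap CI agrees roughly with Smith CI on calibrated data
  d4 <- simulate_clustered_binary(150, 19, 0.7, 0.15, seed = 33)
  s <- icc_anova(d4, "y")
  b <- icc_anova(d4, "y", ci = "bootstrap", boot = 300, seed = 34)
  expect_equal(b$icc, s$icc)
  expect_lt(abs(b$ci_low - s$ci_low), 0.05)
  expect_lt(abs(b$ci_high - s$ci_high), 0.05)
})

test_that("standardized mean differences follow the published conventions", {
  # continuous: exact SMD from moment-standardized samples
  set.seed(12)
  std <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  d <- tibble::tibble(
    arm = rep(c("placebo", "high_cash"), each = 400),
    age = c(std(400, 37.3, 16.1), std(400, 38.4, 16.8)),
    female = rep(c(0.541, 0.619) >= 0.5, each = 400) * 1L
  )
  tab <- smd_balance(d, c("age"), arm_pairs = list(c("high_cash", "placebo")))
  expect_equal(tab$smd, (38.4 - 37.3) / sqrt((16.1^2 + 16.8^2) / 2),
               tolerance = 1e-10)
  expect_false(tab$flag)

  # identical distributions: SMD exactly zero; antisymmetry under pair swap
  d2 <- d
  d2$age <- rep(std(400, 40, 10), 2)
  t0 <- smd_balance(d2, "age", arm_pairs = list(c("placebo", "high_cash")))
  expect_equal(t0$smd, 0)
  tswap <- smd_balance(d, "age", arm_pairs = list(c("placebo", "high_cash")))
  expect_equal(tswap$smd, -tab$smd)

  # binary covariates use raw proportion differences
  tb <- smd_balance(d, "female", arm_pairs = list(c("high_cash", "placebo")))
  expect_true(tb$binary)
  expect_equal(tb$smd, mean(d$female[d$arm == "high_cash"]) -
                 mean(d$female[d$arm == "placebo"]))

  # boundary: a shift of exactly 0.1 pooled SD is flagged
  d3 <- tibble::tibble(arm = rep(c("a", "b"), each = 500),
                       x = c(std(500, 0, 1), std(500, 0.1, 1)))
  expect_true(smd_balance(d3, "x", arm_pairs = list(c("b", "a")))$flag)

  # zero pooled SD: undefined, flagged
  d4 <- tibble::tibble(arm = rep(c("a", "b"), each = 5), x = rep(2.5, 10))
  t4 <- smd_balance(d4, "x", arm_pairs = list(c("a", "b")))
  expect_true(is.na(t4$smd) && t4$flag)
})
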