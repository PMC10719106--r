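# Cluster-level arm contrast that depends on the assignment only through
# the village arm labels (enumerable exactly over arm permutations).
stat_arm_diff <- function(rec) {
  vm <- tapply(rec$y, rec$village_id, mean)
  va <- tapply(as.character(rec$arm), rec$village_id, `[`, 1)
  mean(vm[va == "low_cash"]) - mean(vm[va == "placebo"])
}

perm4 <- function() {
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  g[apply(g, 1, function(r) length(unique(r)) == 4L), , drop = FALSE]
}

test_that("a constant statistic yields p = 1", {
  v <- toy_villages(n = 8, districts = "D1")
  plan <- randomize_trial(v, 2, seed = 71)
  rec <- sim_records(plan, per_village = 4, seed = 72)
  rec$y <- 1L
  res <- ri_pvalue(rec, plan, function(r) 0, B = 50, seed = 73)
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo RI matches exhaustive enumeration on a 2-quadruplet toy", {
  v <- toy_villages(n = 8, districts = "D1")
  plan <- randomize_trial(v, 2, seed = 75)
  rec <- sim_records(plan, per_village = 4, seed = 76)
  # fixed outcomes with real between-village variation
  vm_true <- c(0.9, 0.1, 0.6, 0.4, 0.8, 0.2, 0.7, 0.3)
  rec$y <- rep(NA_real_, nrow(rec))
  for (i in seq_along(unique(rec$village_id))) {
    rec$y[rec$village_id == unique(rec$village_id)[i]] <-
      rep(c(1, 0), c(round(4 * vm_true[i]), 4 - round(4 * vm_true[i])))
  }
  t_obs <- stat_arm_diff(rec)

  # exact null law: all 24 x 24 within-quadruplet arm permutations
  sel <- plan$selected_quads
  p24 <- perm4()
  vm <- tapply(rec$y, rec$village_id, mean)
  stats_all <- numeric(0)
  for (i in seq_len(nrow(p24))) {
    for (j in seq_len(nrow(p24))) {
      arms <- character(0)
      arms[as.character(sel$members[[1]])] <- arm_levels()[p24[i, ]]
      arms[as.character(sel$members[[2]])] <- arm_levels()[p24[j, ]]
      a <- arms[names(vm)]
      stats_all <- c(stats_all,
                     mean(vm[a == "low_cash"]) - mean(vm[a == "placebo"]))
    }
  }
  p_exact <- mean(abs(stats_all) >= abs(t_obs) - 1e-12)

  res <- ri_pvalue(rec, plan, stat_arm_diff, B = 4000, seed = 77)
  expect_equal(res$observed, t_obs)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1 / 1000
  expect_lt(abs(res$p_value - p_exact), tol)
})

test_that("re-randomization replays the design's assignment law", {
  v <- toy_villages(n = 20, districts = "D1")
  plan <- randomize_trial(v, 5, seed = 81)
  rec <- sim_records(plan, per_village = 8, seed = 82)
  inds <- rec[, c("individual_id", "village_id")]
  r1 <- redraw_assignment(plan, inds, seed = 5)
  r2 <- redraw_assignment(plan, inds, seed = 5)
  expect_identical(r1, r2)
  r3 <- redraw_assignment(plan, inds, seed = 6)
  expect_false(identical(r1$arm_assignment$arm, r3$arm_assignment$arm))
  # every redraw is a valid plan: 4 distinct arms per quadruplet,
  # round(0.25 n) embedded placebos per treated village
  quad_of <- plan$villages$quad_id[match(r1$arm_assignment$village_id,
                                         plan$villages$village_id)]
  expect_true(all(tapply(r1$arm_assignment$arm, quad_of,
                         function(a) length(unique(a))) == 4))
  merged <- merge(r1$videos, r1$arm_assignment, by = "village_id")
  emb <- tapply(merged$video == "placebo", merged$village_id, sum)
  arm_v <- tapply(as.character(merged$arm), merged$village_id, `[`, 1)
  expect_true(all(emb[arm_v == "placebo"] == 8))
  expect_true(all(emb[arm_v != "placebo"] == round(0.25 * 8)))
})

test_that("RI p-values are super-uniform under the sharp null", {
  v <- toy_villages(n = 20, districts = c("D1", "D2", "D3", "D4"))
  plan <- randomize_trial(v, 5, seed = 85)
  params <- uniform_params(flat_rates(0.4), icc = 0.1)
  stat <- ri_stat_diff("verified_vax", "cash", "placebo")
  trials <- 150
  pv <- vapply(seq_len(trials), function(r) {
    rec <- sim_records(plan, per_village = 8, seed = 9000 + r)
    rec <- simulate_outcomes(rec, plan, params, seed = 9500 + r)
    ri_pvalue(rec, plan, stat, B = 99, seed = 10000 + r)$p_value
  }, numeric(1))
  for (t in c(0.05, 0.10, 0.25, 0.50)) {
    expect_lte(mean(pv <= t), t + 2.8 * sqrt(t * (1 - t) / trials) + 1 / 100)
  }
})

test_that("RI detects a strong low-cash effect at trial scale", {
  odds0 <- 0.284 / 0.716
  p_lc <- 2 * odds0 / (1 + 2 * odds0)  # marginal odds ratio exactly 2
  params <- uniform_params(
    c(placebo = 0.284, health = 0.284, low_cash = p_lc, high_cash = p_lc),
    icc = 0.15)
  stat <- ri_stat_diff("verified_vax", "cash", "placebo")
  runs <- 12
  hit <- vapply(seq_len(runs), function(r) {
    tr <- sim_trial(params, quads_per_district = 13, per_village = 21,
                    seed = 300 + r)
    ri_pvalue(tr$records, tr$plan, stat, B = 199, seed = 400 + r)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
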