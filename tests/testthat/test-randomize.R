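test_that("quadruplets group consecutive population-ranked villages and report leftovers", {
  v <- tibble::tibble(
    village_id = sprintf("v%d", 1:8),
    district_id = "D1",
    population = c(800, 700, 600, 500, 400, 300, 200, 100)[c(3, 1, 5, 7, 2, 4, 6, 8)]
  )
  fq <- form_quadruplets(v)
  expect_equal(nrow(fq$quadruplets), 2L)
  pops <- function(ids) sort(v$population[match(ids, v$village_id)])
  expect_equal(pops(fq$quadruplets$members[[1]]), c(500, 600, 700, 800))
  expect_equal(pops(fq$quadruplets$members[[2]]), c(100, 200, 300, 400))
  expect_equal(nrow(fq$excluded), 0L)
  expect_equal(sum(fq$quadruplets$pop_share), 1)

  v9 <- dplyr::bind_rows(v, tibble::tibble(village_id = "v9", district_id = "D1",
                                           population = 50))
  fq9 <- form_quadruplets(v9)
  expect_equal(nrow(fq9$quadruplets), 2L)
  expect_equal(fq9$excluded$village_id, "v9")

  # count = floor(n/4) across a range of district sizes
  for (n in c(4, 7, 13, 202)) {
    vv <- tibble::tibble(village_id = sprintf("x%03d", seq_len(n)),
                         district_id = "D1", population = n + seq_len(n))
    expect_equal(nrow(form_quadruplets(vv)$quadruplets), n %/% 4)
  }
  expect_error(form_quadruplets(v[1:3, ]), "at least 4")

  # population ties broken by village id: deterministic membership
  vt <- toy_villages(n = 8, districts = "D1", ties = TRUE)
  m1 <- form_quadruplets(vt)$quadruplets$members
  expect_equal(m1[[1]], sort(vt$village_id)[1:4])
})

test_that("weighted quadruplet sampling follows the population-share law", {
  q <- tibble::tibble(quad_id = c("a", "b"), district_id = "D1",
                      members = list(1:4, 5:8), population = c(100, 0.0001),
                      pop_share = c(1, 0))
  expect_equal(sample_quadruplets(q, 1, seed = 3)$quad_id, "a")
  q3 <- tibble::tibble(quad_id = c("a", "b", "c"), district_id = "D1",
                       members = list(1:4, 5:8, 9:12),
                       population = c(50, 30, 20), pop_share = c(0.5, 0.3, 0.2))
  expect_setequal(sample_quadruplets(q3, 3, seed = 1)$quad_id, q3$quad_id)
  expect_error(sample_quadruplets(q3, 4), "exceeds")
  qbad <- q3
  qbad$pop_share[2] <- NaN
  expect_error(sample_quadruplets(qbad, 1), "finite")

  n <- 1e4
  first <- withr::with_seed(42, replicate(n, sample_quadruplets(q3, 1)$quad_id))
  freq <- table(factor(first, levels = q3$quad_id)) / n
  se <- sqrt(q3$pop_share * (1 - q3$pop_share) / n)
  expect_true(all(abs(as.numeric(freq) - q3$pop_share) < 3 * se))
})

test_that("arm assignment is a uniform permutation of the four arms", {
  expect_setequal(assign_arms(letters[1:4], seed = 5)$arm, arm_levels())
  expect_error(assign_arms(letters[1:3]), "exactly 4")
  expect_error(assign_arms(c("a", "a", "b", "c")), "distinct")
  expect_identical(assign_arms(letters[1:4], seed = 9),
                   assign_arms(letters[1:4], seed = 9))

  n <- 24000
  perms <- withr::with_seed(7, replicate(n, paste(sample(arm_levels()), collapse = ",")))
  freq <- table(perms) / n
  expect_equal(length(freq), 24L)
  se <- sqrt((1 / 24) * (23 / 24) / n)
  expect_true(all(abs(as.numeric(freq) - 1 / 24) < 3.5 * se))
})

test_that("embedded placebo counts follow the round(0.25 n) rule", {
  expect_equal(assign_individual_videos("placebo", 21), rep("placebo", 21))
  v21 <- assign_individual_videos("low_cash", 21, seed = 2)
  expect_equal(sum(v21 == "placebo"), 5L)
  expect_equal(sum(v21 == "low_cash"), 16L)
  expect_length(assign_individual_videos("health", 0), 0L)
  for (n in 1:40) {
    v <- assign_individual_videos("high_cash", n, seed = n)
    expect_equal(sum(v == "placebo"), round(0.25 * n))
    expect_true(all(v %in% c("placebo", "high_cash")))
  }
})

test_that("a full plan is reproducible, balanced within quadruplets, and k per district", {
  v <- toy_villages(n = 53, districts = c("D1", "D2", "D3"))
  p1 <- randomize_trial(v, quads_per_district = 5, seed = 77)
  p2 <- randomize_trial(v, quads_per_district = 5, seed = 77)
  expect_identical(p1$villages, p2$villages)
  expect_identical(p1$arm_assignment, p2$arm_assignment)
  p3 <- randomize_trial(v, quads_per_district = 5, seed = 78)
  expect_false(identical(p1$arm_assignment$arm, p3$arm_assignment$arm))

  arms_per_quad <- tapply(p1$arm_assignment$arm, p1$arm_assignment$quad_id,
                          function(a) length(unique(a)))
  expect_true(all(arms_per_quad == 4))
  sel <- p1$villages[p1$villages$selected, ]
  expect_equal(as.vector(table(sel$district_id)), rep(20L, 3))
  # leftovers: 53 = 13*4 + 1 per district
  expect_equal(nrow(p1$excluded), 3L)

  # videos: reproducible and 25% embedded in treated villages
  rec <- sim_records(p1, per_village = 20, seed = 5)
  expect_identical(rec$video, sim_records(p1, per_village = 20, seed = 5)$video)
  by_village <- split(rec, rec$village_id)
  for (b in by_village) {
    if (b$arm[1] == "placebo") {
      expect_true(all(b$video == "placebo"))
    } else {
      expect_equal(sum(b$video == "placebo"), 5L)  # round(0.25 * 20)
      expect_true(all(b$video %in% c("placebo", b$arm[1])))
    }
  }
})

test_that("village selection probability is proportional to quadruplet population share", {
  q3 <- tibble::tibble(quad_id = c("a", "b", "c"), district_id = "D1",
                       members = list(1:4, 5:8, 9:12),
                       population = c(500, 300, 200), pop_share = c(0.5, 0.3, 0.2))
  n <- 4000
  k2 <- withr::with_seed(11, replicate(n, sample_quadruplets(q3, 2)$quad_id))
  freq <- table(factor(k2, levels = q3$quad_id)) / n
  # inclusion probability of each quad in a sequential 2-of-3 weighted draw
  p <- q3$pop_share
  incl <- vapply(1:3, function(i) {
    p[i] + sum(vapply(setdiff(1:3, i), function(j) p[j] * p[i] / (1 - p[j]),
                      numeric(1)))
  }, numeric(1))
  se <- sqrt(incl * (1 - incl) / n)
  expect_true(all(abs(as.numeric(freq) - incl) < 3.5 * se))
})
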