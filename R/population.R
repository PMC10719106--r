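# Synthetic population: villages, clinics, participants and covariates with
# the marginal structure of the trial's published summary tables.

#' Default generator configuration
#'
#' Encodes the study conditions of the six-district design: 13 quadruplets
#' selected per district (312 villages), 21 treated participants per village,
#' a truncated log-normal village-population law on [30, 5428] whose
#' truncated median is 1,040, covariate marginals matched to the published
#' phase-I summary table, outcome models calibrated to the published arm
#' rates and intracluster correlations, and attrition rates of ~30%
#' (recontact) and ~48% (verification).
#'
#' @param ... Named overrides of any top-level config entry.
#' @return An object of class `trial_config` (a named list).
#' @export
trial_config <- function(...) {
  cfg <- list(
    n_districts = 6L,
    villages_per_district = 200L,
    quads_per_district = 13L,
    per_village = 21L,
    n_untreated_per_village = 4L,
    n_clinics_per_district = 5L,
    population = list(sdlog = 1.0, min = 30, max = 5428, median = 1040),
    covariates = list(
      female = 0.571,
      age = list(mean = 37.4, sd = 16.4, min = 18),
      household_size = list(mean = 5.0, sd = 2.7, min = 1),
      children_u18 = list(mean = 1.8, sd = 2.2, min = 0),
      employment = c(full = 0.590, part = 0.137, unemployed = 0.126, other = 0.147),
      weekly_food_spend = list(mean = 161.6, sd = 99.7, min = 0),
      weekly_nonfood_spend = list(mean = 37.1, sd = 52.1, min = 0),
      finances_score = c(0.25, 0.35, 0.28, 0.09, 0.03),  # 1..5; mean 2.3, sd ~1
      education = c(none = 0.181, low = 0.196, medium = 0.443, high = 0.180),
      whatsapp = 0.284,
      dist_clinic = list(mean = 5.6, sd = 4.4, min = 0)
    ),
    outcomes = trial_outcome_params(),
    attrition = trial_attrition_params(),
    region = list(lat0 = 7.9, lon0 = -1.2, district_spread = 1.2, village_spread = 0.25)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg$population$meanlog <- solve_pop_meanlog(cfg$population)
  class(cfg) <- "trial_config"
  cfg
}

# meanlog of the truncated log-normal such that the truncated median hits the
# configured value.
solve_pop_meanlog <- function(pop) {
  if (!is.finite(pop$sdlog) || pop$sdlog <= 0) {
    stop("population law is degenerate (sdlog <= 0)")
  }
  trunc_median <- function(meanlog) {
    p0 <- stats::plnorm(pop$min, meanlog, pop$sdlog)
    p1 <- stats::plnorm(pop$max, meanlog, pop$sdlog)
    stats::qlnorm(p0 + 0.5 * (p1 - p0), meanlog, pop$sdlog)
  }
  stats::uniroot(function(m) trunc_median(m) - pop$median,
                 lower = log(pop$median) - 2, upper = log(pop$median) + 2,
                 tol = 1e-10)$root
}

#' Generate a synthetic village table
#'
#' Village populations are drawn from a log-normal truncated to
#' `[30, 5428]`, with `meanlog` solved so the truncated median equals 1,040.
#' Coordinates are scattered around per-district centroids so that
#' distance-to-clinic computations have something to chew on.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return Tibble: `village_id`, `district_id`, `population`, `lat`, `lon`.
#' @export
generate_villages <- function(config = trial_config(), seed = 1L) {
  pop <- config$population
  if (pop$sdlog <= 0) stop("population law is degenerate (sdlog <= 0)")
  n_d <- config$n_districts
  n_v <- config$villages_per_district
  with_seed(seed, {
    district_id <- rep(sprintf("D%d", seq_len(n_d)), each = n_v)
    p0 <- stats::plnorm(pop$min, pop$meanlog, pop$sdlog)
    p1 <- stats::plnorm(pop$max, pop$meanlog, pop$sdlog)
    u <- stats::runif(n_d * n_v, p0, p1)
    population <- round(stats::qlnorm(u, pop$meanlog, pop$sdlog))
    population <- pmin(pmax(population, pop$min), pop$max)
    reg <- config$region
    dlat <- reg$lat0 + reg$district_spread * stats::rnorm(n_d)
    dlon <- reg$lon0 + reg$district_spread * stats::rnorm(n_d)
    tibble::tibble(
      village_id = sprintf("%s_v%03d", district_id, rep(seq_len(n_v), n_d)),
      district_id = district_id,
      population = as.numeric(population),
      lat = rep(dlat, each = n_v) + reg$village_spread * stats::rnorm(n_d * n_v),
      lon = rep(dlon, each = n_v) + reg$village_spread * stats::rnorm(n_d * n_v)
    )
  })
}

#' Generate district health-clinic coordinates
#'
#' @param villages Village table (used for district centroids).
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return Tibble: `clinic_id`, `district_id`, `lat`, `lon`.
#' @export
generate_clinics <- function(villages, config = trial_config(), seed = 1L) {
  with_seed(seed, {
    out <- lapply(unique(villages$district_id), function(d) {
      v <- villages[villages$district_id == d, ]
      k <- config$n_clinics_per_district
      tibble::tibble(
        clinic_id = sprintf("%s_c%d", d, seq_len(k)),
        district_id = d,
        lat = mean(v$lat) + 0.3 * stats::rnorm(k),
        lon = mean(v$lon) + 0.3 * stats::rnorm(k)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Generate participants and covariates for a set of villages
#'
#' Draws `config$per_village` treated participants per village (plus
#' `config$n_untreated_per_village` untreated spillover-sample residents when
#' `include_untreated = TRUE`). Binary covariates are Bernoulli at the
#' published proportions; continuous covariates are truncated normals whose
#' *truncated* moments are matched to the published mean/SD rows; counts are
#' rounded truncated normals. Covariates are drawn independently — the
#' summary table publishes marginals only.
#'
#' @param villages Village rows to populate (must have `village_id`,
#'   `district_id`; `lat`/`lon` used when `clinics` is supplied).
#' @param config A [trial_config()].
#' @param clinics Optional clinic table from [generate_clinics()]; when
#'   present, `dist_clinic_km` is the haversine distance from the
#'   participant's jittered location to the nearest clinic in the district,
#'   otherwise it is drawn from the published access distribution.
#' @param include_untreated Add the untreated spillover-sample residents?
#' @param seed Integer seed.
#' @return Tibble of individual records (one row per participant, without
#'   videos or outcomes; see [assign_videos()], [simulate_outcomes()]).
#' @export
generate_individuals <- function(villages, config = trial_config(),
                                 clinics = NULL, include_untreated = FALSE,
                                 seed = 1L) {
  assert_cols(villages, c("village_id", "district_id"), "villages")
  n_tr <- config$per_village
  n_un <- if (include_untreated) config$n_untreated_per_village else 0L
  m <- n_tr + n_un
  n <- nrow(villages) * m
  cv <- config$covariates
  with_seed(seed, {
    rec <- tibble::tibble(
      individual_id = sprintf("%s_i%02d", rep(villages$village_id, each = m),
                              rep(seq_len(m), nrow(villages))),
      village_id = rep(villages$village_id, each = m),
      district_id = rep(villages$district_id, each = m),
      untreated_spillover = rep(c(rep(FALSE, n_tr), rep(TRUE, n_un)), nrow(villages)),
      female = stats::rbinom(n, 1, cv$female),
      age = rtnorm_matched(n, cv$age$mean, cv$age$sd, cv$age$min),
      household_size = pmax(1, round(rtnorm_matched(n, cv$household_size$mean,
                                                    cv$household_size$sd, 0.5))),
      children_u18 = round(rtnorm_matched(n, cv$children_u18$mean,
                                          cv$children_u18$sd, 0)),
      employment = sample(names(cv$employment), n, replace = TRUE,
                          prob = cv$employment),
      weekly_food_spend = rtnorm_matched(n, cv$weekly_food_spend$mean,
                                         cv$weekly_food_spend$sd, 0),
      weekly_nonfood_spend = rtnorm_matched(n, cv$weekly_nonfood_spend$mean,
                                            cv$weekly_nonfood_spend$sd, 0),
      finances_score = sample(1:5, n, replace = TRUE, prob = cv$finances_score),
      education = sample(names(cv$education), n, replace = TRUE,
                         prob = cv$education),
      whatsapp = stats::rbinom(n, 1, cv$whatsapp)
    )
    if (!is.null(clinics) && all(c("lat", "lon") %in% names(villages))) {
      plat <- rep(villages$lat, each = m) + 0.02 * stats::rnorm(n)
      plon <- rep(villages$lon, each = m) + 0.02 * stats::rnorm(n)
      rec$dist_clinic_km <- nearest_clinic_km(cbind(plat, plon),
                                              clinics[, c("lat", "lon")])
    } else {
      rec$dist_clinic_km <- rtnorm_matched(n, cv$dist_clinic$mean,
                                           cv$dist_clinic$sd, cv$dist_clinic$min)
    }
    rec
  })
}
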