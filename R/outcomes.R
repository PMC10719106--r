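# Clustered binary outcomes: logistic-normal random-intercept generator
# calibrated so marginal arm rates and the observed-scale (ANOVA) ICC hit
# their targets exactly in expectation; attrition as logit missingness.

#' Parameters of one clustered binary outcome model
#'
#' The data-generating process is a logistic-normal random-intercept model:
#' individual `i` in village `c` (district `d`) succeeds with probability
#' `plogis(mu_arm + gamma + omega' x_i + u_c + u_d)`, where `u_c`, `u_d` are
#' normal latent intercepts. Calibration works backwards from targets: given
#' per-arm marginal rates and a target ICC, the total latent SD is solved by
#' quadrature (observed/ANOVA scale via [sigma_for_observed_icc()], or latent
#' scale via [sigma_for_latent_icc()]), then each arm's conditional log-odds
#' is solved so its marginal rate is exact ([mu_for_marginal()]). Spillover
#' terms (`gamma`) for embedded placebos and untreated residents are likewise
#' derived from target marginal rates when given as rates.
#'
#' @param rates Named numeric: marginal success rate per arm
#'   (`placebo`, `health`, `low_cash`, `high_cash`).
#' @param icc Target intracluster correlation.
#' @param icc_scale `"observed"` (ANOVA, 0/1 scale — the reporting
#'   convention) or `"latent"` (latent-logistic scale).
#' @param district_share Fraction of the latent between-cluster variance
#'   carried by a district-level intercept (villages of one district share
#'   it). At village-level ANOVA both components count as between-village
#'   variance, so the total calibration is unchanged.
#' @param embedded_rates Optional named rates (`health`, `low_cash`,
#'   `high_cash`) for embedded-placebo individuals in treated villages; NULL
#'   means no within-village spillover (gamma = 0).
#' @param untreated_rates Optional named rates for untreated spillover-sample
#'   residents by village arm (including `placebo`).
#' @param omega Optional named log-odds effects of centered covariates
#'   (supported names: `age`, `female`, `dist_clinic_km`,
#'   `weekly_food_spend`).
#' @param beta Optional named per-arm log-odds effects overriding the
#'   rate-based calibration of the treated arms (placebo baseline still from
#'   `rates["placebo"]`).
#' @return Object of class `outcome_params`.
#' @export
outcome_params <- function(rates, icc, icc_scale = c("observed", "latent"),
                           district_share = 0, embedded_rates = NULL,
                           untreated_rates = NULL, omega = NULL, beta = NULL) {
  icc_scale <- match.arg(icc_scale)
  stopifnot(all(ARM_LEVELS %in% names(rates)), icc >= 0, icc < 1,
            district_share >= 0, district_share <= 1)
  rates <- rates[ARM_LEVELS]
  pbar <- mean(rates)
  sigma <- switch(icc_scale,
                  observed = sigma_for_observed_icc(icc, pbar),
                  latent = sigma_for_latent_icc(icc))
  mu <- vapply(rates, function(p) mu_for_marginal(p, sigma), numeric(1))
  if (!is.null(beta)) {
    mu[names(beta)] <- mu[["placebo"]] + beta
  }
  gamma_e <- c(health = 0, low_cash = 0, high_cash = 0)
  if (!is.null(embedded_rates)) {
    g <- vapply(embedded_rates, function(p) mu_for_marginal(p, sigma), numeric(1)) -
      mu[["placebo"]]
    gamma_e[names(embedded_rates)] <- g
  }
  gamma_u <- c(placebo = 0, health = 0, low_cash = 0, high_cash = 0)
  if (!is.null(untreated_rates)) {
    g <- vapply(untreated_rates, function(p) mu_for_marginal(p, sigma), numeric(1)) -
      mu[["placebo"]]
    gamma_u[names(untreated_rates)] <- g
  }
  structure(list(
    rates = rates, icc = icc, icc_scale = icc_scale,
    sigma_total = sigma,
    sigma_village = sqrt(1 - district_share) * sigma,
    sigma_district = sqrt(district_share) * sigma,
    mu = mu, gamma_embedded = gamma_e, gamma_untreated = gamma_u,
    omega = omega
  ), class = "outcome_params")
}

#' Default outcome models calibrated to the published trial
#'
#' Three outcome models: vaccination intention (ICC 0.15), reported
#' vaccination (ICC 0.06) and record-verified vaccination (ICC 0.64, with
#' 80% of the latent between-cluster variance at the district level — the
#' verification-coverage interpretation of that extreme ICC). Arm rates are
#' the published per-arm percentages; spillover rates for the verified and
#' reported outcomes come from the published embedded-placebo and
#' untreated-sample panels. `misreport = NULL` keeps the three outcomes
#' independently calibrated; supplying `list(fp = , fn = )` instead derives
#' the reported outcome from the verified one by directional flips.
#'
#' @param misreport NULL, or `list(fp, fn)`: probabilities that an
#'   unvaccinated (vaccinated) person reports the opposite.
#' @return Named list of [outcome_params()] plus the `misreport` setting.
#' @export
trial_outcome_params <- function(misreport = NULL) {
  list(
    intention = outcome_params(
      rates = c(placebo = 0.710, health = 0.725, low_cash = 0.817, high_cash = 0.782),
      icc = 0.15),
    reported = outcome_params(
      rates = c(placebo = 0.363, health = 0.385, low_cash = 0.419, high_cash = 0.381),
      icc = 0.06,
      embedded_rates = c(health = 0.328, low_cash = 0.380, high_cash = 0.380)),
    verified = outcome_params(
      rates = c(placebo = 0.284, health = 0.216, low_cash = 0.407, high_cash = 0.259),
      icc = 0.64, district_share = 0.8,
      embedded_rates = c(health = 0.228, low_cash = 0.383, high_cash = 0.263),
      untreated_rates = c(placebo = 0.298, health = 0.196, low_cash = 0.383,
                          high_cash = 0.319)),
    misreport = misreport
  )
}

#' Default attrition models
#'
#' Intercept-only logit missingness matched to the published retention
#' counts: 4,101/5,900 recontacted (phase II/III) and 3,075/5,900 with
#' verified status found (phase IV). Arm and covariate coefficients default
#' to zero (attrition was similar across arms); set them to create
#' differential (MAR) attrition.
#'
#' @param recontact,verification Lists with `intercept`, optional named `arm`
#'   log-odds (`health`, `low_cash`, `high_cash`) and optional named `omega`
#'   covariate log-odds (same names as in [outcome_params()]).
#' @return List of the two phase models.
#' @export
trial_attrition_params <- function(
    recontact = list(intercept = stats::qlogis(4101 / 5900)),
    verification = list(intercept = stats::qlogis(3075 / 5900))) {
  fill <- function(m) {
    m$arm <- (m$arm %||% c(health = 0, low_cash = 0, high_cash = 0))
    m$omega <- m$omega %||% NULL
    m
  }
  list(recontact = fill(recontact), verification = fill(verification))
}

# Centering constants for omega covariates (published phase-I means).
OMEGA_CENTERS <- c(age = 37.4, female = 0.571, dist_clinic_km = 5.6,
                   weekly_food_spend = 161.6)

omega_term <- function(records, omega) {
  if (is.null(omega) || !length(omega)) return(0)
  bad <- setdiff(names(omega), names(OMEGA_CENTERS))
  if (length(bad)) stop("unsupported omega covariate(s): ", paste(bad, collapse = ", "))
  out <- 0
  for (nm in names(omega)) {
    out <- out + omega[[nm]] * (records[[nm]] - OMEGA_CENTERS[[nm]])
  }
  out
}

#' Simulate the three clustered binary outcomes
#'
#' Draws village (and, for the verified model, district) latent intercepts,
#' forms each individual's linear predictor from their video, their
#' village's arm (spillover terms for embedded placebos and untreated
#' residents) and any covariate effects, and draws Bernoulli outcomes.
#' Untreated spillover-sample residents have no intention outcome (they were
#' not shown a video).
#'
#' @param records Individual table with `village_id`, `district_id`, `video`,
#'   `arm`, `untreated_spillover` (see [generate_individuals()],
#'   [assign_videos()]); `arm` is taken from `plan` if absent.
#' @param plan Optional `trial_plan` supplying village arms.
#' @param params Outcome parameter list from [trial_outcome_params()].
#' @param seed Integer seed.
#' @return `records` with columns `intention`, `reported_vax`,
#'   `verified_vax` added.
#' @export
simulate_outcomes <- function(records, plan = NULL,
                              params = trial_outcome_params(), seed = 1L) {
  if (!"arm" %in% names(records)) {
    if (is.null(plan)) stop("records lack an `arm` column and no plan was given")
    records$arm <- plan$arm_assignment$arm[
      match(records$village_id, plan$arm_assignment$village_id)]
  }
  if (any(is.na(records$arm))) {
    stop("some records belong to villages without an assigned arm")
  }
  assert_cols(records, c("village_id", "district_id", "video"))
  if (!"untreated_spillover" %in% names(records)) records$untreated_spillover <- FALSE

  draw_one <- function(p, rec) {
    vids <- unique(rec$village_id)
    dists <- unique(rec$district_id)
    u_v <- stats::rnorm(length(vids), 0, p$sigma_village)
    u_d <- stats::rnorm(length(dists), 0, p$sigma_district)
    lp <- u_v[match(rec$village_id, vids)] + u_d[match(rec$district_id, dists)]
    base <- numeric(nrow(rec))
    trt <- !rec$untreated_spillover
    own <- trt & rec$video == rec$arm & rec$arm != "placebo"
    emb <- trt & rec$video == "placebo" & rec$arm != "placebo"
    plc <- trt & rec$arm == "placebo"
    base[own] <- p$mu[rec$video[own]]
    base[emb] <- p$mu[["placebo"]] + p$gamma_embedded[rec$arm[emb]]
    base[plc] <- p$mu[["placebo"]]
    base[!trt] <- p$mu[["placebo"]] + p$gamma_untreated[rec$arm[!trt]]
    lp <- lp + base + omega_term(rec, p$omega)
    stats::rbinom(nrow(rec), 1, stats::plogis(lp))
  }

  with_seed(seed, {
    records$intention <- draw_one(params$intention, records)
    records$intention[records$untreated_spillover] <- NA_integer_
    records$verified_vax <- draw_one(params$verified, records)
    if (is.null(params$misreport)) {
      records$reported_vax <- draw_one(params$reported, records)
    } else {
      fp <- params$misreport$fp
      fn <- params$misreport$fn
      v <- records$verified_vax
      flip <- stats::runif(length(v))
      records$reported_vax <- ifelse(v == 1, as.integer(flip > fn),
                                     as.integer(flip < fp))
    }
    records
  })
}

#' Simulate attrition and mask unobserved outcomes
#'
#' Recontact (phase II/III) and verification (phase IV) indicators are drawn
#' from logit models on treatment video and (optionally) covariates;
#' `reported_vax` is set missing for non-recontacted records and
#' `verified_vax` for records whose status was not found.
#'
#' @param records Output of [simulate_outcomes()].
#' @param params List from [trial_attrition_params()].
#' @param seed Integer seed.
#' @return `records` with `recontacted`, `verified_status_found` added and
#'   outcome columns masked accordingly.
#' @export
simulate_attrition <- function(records, params = trial_attrition_params(),
                               seed = 1L) {
  assert_cols(records, c("video", "reported_vax", "verified_vax"))
  lp_of <- function(m) {
    lp <- m$intercept + omega_term(records, m$omega)
    for (a in names(m$arm)) lp <- lp + m$arm[[a]] * (records$video == a)
    lp
  }
  with_seed(seed, {
    records$recontacted <- stats::rbinom(nrow(records), 1,
                                         stats::plogis(lp_of(params$recontact)))
    records$verified_status_found <- stats::rbinom(nrow(records), 1,
                                                   stats::plogis(lp_of(params$verification)))
    records$reported_vax[records$recontacted == 0] <- NA_integer_
    records$verified_vax[records$verified_status_found == 0] <- NA_integer_
    records
  })
}

#' Simulate i.i.d. clusters of a calibrated clustered binary outcome
#'
#' Convenience generator used by the power module and in calibration checks:
#' `n_clusters` villages of `size` individuals with marginal rate `p` and
#' observed-scale ICC `icc`, via the logistic-normal model.
#'
#' @param n_clusters,size Number of clusters and individuals per cluster.
#' @param p Marginal success probability.
#' @param icc Target observed-scale ICC.
#' @param seed Integer seed.
#' @return Tibble with `village_id` and binary `y`.
#' @export
simulate_clustered_binary <- function(n_clusters, size, p, icc, seed = NULL) {
  sigma <- sigma_for_observed_icc(icc, p)
  mu <- mu_for_marginal(p, sigma)
  with_seed(seed, {
    pc <- stats::plogis(mu + sigma * stats::rnorm(n_clusters))
    k <- stats::rbinom(n_clusters, size, pc)
    tibble::tibble(
      village_id = rep(seq_len(n_clusters), each = size),
      y = as.integer(sequence(rep(size, n_clusters)) <= rep(k, each = size))
    )
  })
}
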