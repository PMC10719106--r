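# Attrition diagnostics and inverse-probability-weighted re-estimation.

#' Differential-attrition logit models
#'
#' Logistic regression of a retention indicator on treatment video dummies,
#' optionally plus covariates and fixed effects, with village-clustered
#' covariance — the three model forms of the published attrition analysis.
#' Note that village fixed effects absorb the village-level treatment
#' dummies, so `fe = "village"` reports covariate effects within villages
#' and drops the arm terms; `fe = "quadruplet"` keeps arms identified while
#' absorbing block effects. Villages (or quadruplets) contributing a single
#' observation are dropped with a warning under fixed effects.
#'
#' @param records Individual table with `recontacted` /
#'   `verified_status_found`, `video`, `arm` and covariates.
#' @param phase `"recontact"` (phase II/III) or `"verification"` (phase IV).
#' @param covariates Optional character vector of covariate terms.
#' @param fe `"none"`, `"quadruplet"` or `"village"`; fixed effects require
#'   the corresponding id column (`quad_id` / `village_id`).
#' @return A `cluster_logit` fit.
#' @export
attrition_logit <- function(records, phase = c("recontact", "verification"),
                            covariates = NULL, fe = c("none", "quadruplet", "village")) {
  phase <- match.arg(phase)
  fe <- match.arg(fe)
  outcome <- switch(phase, recontact = "recontacted",
                    verification = "verified_status_found")
  records <- add_design_dummies(records)
  assert_cols(records, outcome)
  terms <- c("health", "low_cash", "high_cash", covariates)
  if (fe == "village") {
    terms <- c(covariates, "factor(village_id)")
  } else if (fe == "quadruplet") {
    assert_cols(records, "quad_id")
    terms <- c(terms, "factor(quad_id)")
  }
  if (fe != "none") {
    fev <- if (fe == "village") "village_id" else "quad_id"
    cnt <- table(records[[fev]])
    single <- names(cnt)[cnt < 2]
    if (length(single)) {
      warning(sprintf("dropping %d %s(s) with a single observation under fixed effects",
                      length(single), fe))
      records <- records[!(records[[fev]] %in% single), , drop = FALSE]
    }
  }
  spec <- stats::reformulate(terms, response = outcome)
  fit_logistic_clustered(records, spec)
}

#' Inverse-probability-weighted re-estimation under attrition
#'
#' Fits (or accepts) a retention model, computes weights `1 / p_hat` for
#' retained records, trims them at a configurable quantile (default the
#' 99th; `trim = 1` leaves them untrimmed), and recomputes the cluster-robust
#' arm contrasts and the logistic model with those weights.
#'
#' @param records Individual table (post-attrition).
#' @param outcome Outcome column to re-analyse (e.g. `"reported_vax"`).
#' @param phase Which retention indicator governs missingness of `outcome`.
#' @param attrition_fit Optional `cluster_logit` retention model; by default
#'   one is fitted on video dummies plus `covariates`.
#' @param covariates Covariates for the default retention model and kept in
#'   the weighted outcome model.
#' @param trim Quantile at which weights are capped (in (0, 1]).
#' @param contrast_arms List of 2-vectors of video labels to contrast;
#'   default each treated video versus placebo.
#' @return List: `weights` (tibble id/weight on retained rows), `contrasts`
#'   (weighted `DiffEstimate` rows), `fit` (weighted `cluster_logit`),
#'   `trim_bound`.
#' @export
ipw_reestimate <- function(records, outcome, phase = c("recontact", "verification"),
                           attrition_fit = NULL, covariates = NULL, trim = 0.99,
                           contrast_arms = NULL) {
  phase <- match.arg(phase)
  stopifnot(trim > 0, trim <= 1)
  records <- add_design_dummies(records)
  ret_col <- switch(phase, recontact = "recontacted",
                    verification = "verified_status_found")
  assert_cols(records, c(outcome, ret_col))
  if (is.null(attrition_fit)) {
    attrition_fit <- attrition_logit(records, phase, covariates = covariates)
  }
  p_hat <- stats::predict(attrition_fit$glm, newdata = as.data.frame(records),
                          type = "response")
  retained <- records[[ret_col]] == 1
  if (any(retained & (is.na(p_hat) | p_hat <= 0))) {
    stop("a retained record has predicted retention probability 0; IPW undefined")
  }
  w <- ifelse(retained, 1 / p_hat, NA_real_)
  bound <- stats::quantile(w[retained], trim, na.rm = TRUE)
  w_trim <- pmin(w, bound)
  records$.ipw <- w_trim
  d <- records[retained, , drop = FALSE]

  if (is.null(contrast_arms)) {
    contrast_arms <- lapply(TREATED_ARMS, function(a) c(a, "placebo"))
  }
  contrasts <- dplyr::bind_rows(lapply(contrast_arms, function(pr) {
    diff_in_means_clustered(d, outcome, pr[1], pr[2], weights = ".ipw")
  }))
  covs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  fit <- fit_logistic_clustered(
    d, sprintf("%s ~ health + low_cash + high_cash %s", outcome, covs),
    weights = ".ipw")
  list(
    weights = tibble::tibble(individual_id = d$individual_id, weight = d$.ipw),
    contrasts = contrasts, fit = fit, trim_bound = unname(bound),
    attrition_fit = attrition_fit
  )
}
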