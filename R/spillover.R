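# Spillover estimands: embedded-placebo and untreated-sample contrasts, and
# the corresponding restricted logistic model forms.

#' Spillover contrasts from embedded placebos and untreated residents
#'
#' Two families of design-based spillover estimands:
#' * embedded-placebo contrasts — participants shown the placebo video inside
#'   health / low-cash / high-cash villages versus participants in
#'   placebo-assigned villages;
#' * untreated-sample contrasts — untreated residents of treated villages
#'   versus untreated residents of placebo villages.
#'
#' Each contrast is a cluster-robust difference in means
#' ([diff_in_means_clustered()]). Alongside, three logistic model forms are
#' fitted with village-clustered covariance: the full treated-sample model
#' with embedded-placebo dummies (`~ health + cash + health_placebo +
#' cash_placebo`), the placebo-video-restricted model (`~ health_placebo +
#' cash_placebo`) and the untreated-sample model (`~ health + cash` on
#' village arm). A missing stratum skips that contrast with a warning.
#'
#' @param records Individual table with `video`, `arm`,
#'   `untreated_spillover` and the outcome.
#' @param outcome Outcome column (default `"verified_vax"`).
#' @param covariates Optional character vector of extra model terms.
#' @return List with `contrasts` (tibble of `DiffEstimate` rows labelled by
#'   `family` and `village_arm`) and `fits` (named list of `cluster_logit`:
#'   `embedded_full`, `embedded_restricted`, `untreated`).
#' @export
spillover_contrasts <- function(records, outcome = "verified_vax",
                                covariates = NULL) {
  records <- add_design_dummies(records)
  tr <- records[!records$untreated_spillover, , drop = FALSE]
  un <- records[records$untreated_spillover, , drop = FALSE]

  rows <- list()
  for (a in TREATED_ARMS) {
    emb <- tr[tr$video == "placebo" & tr$arm == a, , drop = FALSE]
    ctrl <- tr[tr$arm == "placebo", , drop = FALSE]
    if (!nrow(emb) || !sum(!is.na(emb[[outcome]]))) {
      warning(sprintf("no embedded placebos with observed %s in %s villages; contrast skipped",
                      outcome, a))
      next
    }
    emb$.grp <- "embedded"
    ctrl$.grp <- "control"
    est <- diff_in_means_clustered(dplyr::bind_rows(emb, ctrl), outcome,
                                   "embedded", "control", group = ".grp")
    est$family <- "embedded_placebo"
    est$village_arm <- a
    rows[[length(rows) + 1L]] <- est
  }
  if (nrow(un)) {
    for (a in TREATED_ARMS) {
      g1 <- un[un$arm == a, , drop = FALSE]
      g0 <- un[un$arm == "placebo", , drop = FALSE]
      if (!nrow(g1) || !nrow(g0) || !sum(!is.na(g1[[outcome]])) ||
          !sum(!is.na(g0[[outcome]]))) {
        warning(sprintf("untreated-sample stratum missing for %s; contrast skipped", a))
        next
      }
      g1$.grp <- "untreated_treated"
      g0$.grp <- "untreated_placebo"
      est <- diff_in_means_clustered(dplyr::bind_rows(g1, g0), outcome,
                                     "untreated_treated", "untreated_placebo",
                                     group = ".grp")
      est$family <- "untreated_sample"
      est$village_arm <- a
      rows[[length(rows) + 1L]] <- est
    }
  }

  covs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  fits <- list()
  fits$embedded_full <- fit_logistic_clustered(
    tr, sprintf("%s ~ health + cash + health_placebo + cash_placebo %s", outcome, covs))
  pl <- tr[tr$video == "placebo", , drop = FALSE]
  fits$embedded_restricted <- fit_logistic_clustered(
    pl, sprintf("%s ~ health_placebo + cash_placebo %s", outcome, covs))
  if (nrow(un) && sum(!is.na(un[[outcome]])) > 0) {
    un$health_arm <- as.integer(un$arm == "health")
    un$cash_arm <- as.integer(un$arm %in% c("low_cash", "high_cash"))
    terms <- c("health_arm", "cash_arm")
    present <- vapply(terms, function(t) stats::var(un[[t]]) > 0, logical(1))
    if (!all(present)) {
      warning("untreated-sample stratum absent for: ",
              paste(terms[!present], collapse = ", "),
              "; term dropped from the untreated model")
    }
    if (any(present)) {
      fits$untreated <- fit_logistic_clustered(
        un, sprintf("%s ~ %s %s", outcome,
                    paste(terms[present], collapse = " + "), covs))
    }
  }
  list(contrasts = dplyr::bind_rows(rows), fits = fits)
}
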