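# Logistic regression with village-clustered sandwich covariance (CR1) and
# odds-ratio tables; the workhorse behind all multi-variable models.

#' Parse a model-spec string of the form "outcome ~ terms | cluster"
#'
#' @param spec A formula or a character string; a `| cluster` suffix names
#'   the clustering column.
#' @return List with `formula` and `cluster` (NULL if not given).
#' @export
parse_model_spec <- function(spec) {
  if (inherits(spec, "formula")) return(list(formula = spec, cluster = NULL))
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, "|", fixed = TRUE)[[1]]
  if (length(parts) > 2L) stop("model spec may contain at most one '|'")
  cl <- if (length(parts) == 2L) trimws(parts[2]) else NULL
  list(formula = stats::as.formula(trimws(parts[1]), env = parent.frame()),
       cluster = cl)
}

#' Cluster-robust logistic regression
#'
#' Maximum-likelihood logistic fit (via [stats::glm()]) with a cluster-robust
#' sandwich covariance computed in-package: per-cluster score sums
#' `s_g = sum_i w_i x_i (y_i - p_i)`, meat `sum_g s_g s_g'`, bread
#' `(X' W X)^{-1}`, and a CR1 small-sample factor `G / (G - 1)`. Odds ratios
#' are `exp(coef)` with 95% intervals from normal quantiles on the log-odds
#' scale by default (`df = "t"` switches to a t reference with `G - 1`
#' degrees of freedom).
#'
#' @param records Data frame of individual records.
#' @param spec Formula or `"outcome ~ terms | cluster"` string. Rows with
#'   missing values in any model variable are dropped.
#' @param cluster Cluster id column (overridden by a `| cluster` suffix).
#' @param weights Optional column name of individual weights (e.g. IPW).
#' @param df `"normal"` or `"t"` reference for the OR intervals.
#' @param conf Confidence level.
#' @return Object of class `cluster_logit`: list with `coefficients`,
#'   `vcov` (cluster-robust), `or_table` (tibble of terms, log-odds, robust
#'   SEs, odds ratios and CIs), `n`, `n_clusters`, `log_likelihood`,
#'   `formula`, `cluster`, `glm` (the underlying fit) and `diagnostics`.
#' @export
fit_logistic_clustered <- function(records, spec, cluster = "village_id",
                                   weights = NULL, df = c("normal", "t"),
                                   conf = 0.95) {
  df <- match.arg(df)
  ps <- parse_model_spec(spec)
  if (!is.null(ps$cluster)) cluster <- ps$cluster
  assert_cols(records, cluster)
  vars <- all.vars(ps$formula)
  assert_cols(records, vars)
  keep <- stats::complete.cases(records[, vars, drop = FALSE])
  if (!is.null(weights)) keep <- keep & !is.na(records[[weights]])
  d <- as.data.frame(records[keep, , drop = FALSE])

  w <- if (is.null(weights)) rep(1, nrow(d)) else d[[weights]]
  if (any(!is.finite(w) | w < 0)) stop("weights must be finite and non-negative")
  fam <- if (is.null(weights)) stats::binomial() else stats::quasibinomial()
  d$.w <- w
  fit <- stats::glm(ps$formula, family = fam, data = d, weights = .w)

  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  X <- stats::model.matrix(fit)
  y <- fit$y
  p <- fit$fitted.values
  cl <- d[[cluster]]
  G <- length(unique(cl))
  if (G < 2L) stop("at least 2 clusters are required for a clustered covariance")

  sep_flag <- any(p < 1e-8 | p > 1 - 1e-8) && max(abs(beta)) > 12
  if (sep_flag) {
    warning("possible separation: fitted probabilities at the boundary with large coefficients")
  }

  scores <- X * (w * (y - p))                 # n x k score contributions
  S <- rowsum(scores, group = cl)             # per-cluster score sums
  meat <- crossprod(as.matrix(S))
  # bread from the converged probabilities (not the IRLS working weights,
  # which lag one iteration behind): (X' W X)^{-1} with W = w p (1-p)
  bread <- chol2inv(chol(crossprod(X * sqrt(w * p * (1 - p)))))
  V <- (G / (G - 1)) * bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(beta), names(beta))

  se <- sqrt(diag(V))
  crit <- if (df == "normal") stats::qnorm(1 - (1 - conf) / 2) else
    stats::qt(1 - (1 - conf) / 2, G - 1)
  z <- beta / se
  pval <- if (df == "normal") 2 * stats::pnorm(-abs(z)) else
    2 * stats::pt(-abs(z), G - 1)
  ll <- sum(w * (y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))))

  structure(list(
    coefficients = beta,
    vcov = V,
    or_table = tibble::tibble(
      term = names(beta), estimate = unname(beta), se = unname(se),
      statistic = unname(z), p_value = unname(pval),
      or = exp(unname(beta)),
      or_low = exp(unname(beta - crit * se)),
      or_high = exp(unname(beta + crit * se))
    ),
    n = nrow(d), n_clusters = G,
    log_likelihood = ll,
    formula = ps$formula, cluster = cluster, df = df,
    glm = fit,
    diagnostics = list(separation = sep_flag)
  ), class = "cluster_logit")
}

#' @export
print.cluster_logit <- function(x, ...) {
  cat("Cluster-robust logistic regression\n")
  cat("  ", deparse(x$formula), "  [cluster: ", x$cluster, "]\n", sep = "")
  cat(sprintf("  n = %d, clusters = %d, logLik = %.1f\n",
              x$n, x$n_clusters, x$log_likelihood))
  print(as.data.frame(x$or_table), digits = 3)
  invisible(x)
}

#' @export
coef.cluster_logit <- function(object, ...) object$coefficients

#' @export
vcov.cluster_logit <- function(object, ...) object$vcov

#' Add design dummy columns used by the published model forms
#'
#' Creates the treatment indicators of the trial's regression models from
#' `video`, `arm` and `untreated_spillover`: `health`, `low_cash`,
#' `high_cash`, `cash` (video actually seen, zero for untreated residents);
#' `health_placebo`, `low_cash_placebo`, `high_cash_placebo`, `cash_placebo`
#' (embedded placebos by village arm); `vcash_health`, `vcash_low_cash`,
#' `vcash_high_cash` and `untreated_treated` (untreated residents by village
#' arm); plus `male` and the reporting scalings `age10` (age/10) and
#' `food50` (weekly food spend/50).
#'
#' @param records Individual table with `video`, `arm`,
#'   `untreated_spillover`.
#' @return `records` with the dummy columns appended.
#' @export
add_design_dummies <- function(records) {
  assert_cols(records, c("video", "arm"))
  if (!"untreated_spillover" %in% names(records)) records$untreated_spillover <- FALSE
  tr <- !records$untreated_spillover
  v <- records$video
  a <- records$arm
  records$health <- as.integer(tr & v == "health")
  records$low_cash <- as.integer(tr & v == "low_cash")
  records$high_cash <- as.integer(tr & v == "high_cash")
  records$cash <- as.integer(tr & v %in% c("low_cash", "high_cash"))
  emb <- tr & v == "placebo" & a != "placebo"
  records$health_placebo <- as.integer(emb & a == "health")
  records$low_cash_placebo <- as.integer(emb & a == "low_cash")
  records$high_cash_placebo <- as.integer(emb & a == "high_cash")
  records$cash_placebo <- as.integer(emb & a %in% c("low_cash", "high_cash"))
  records$vcash_health <- as.integer(!tr & a == "health")
  records$vcash_low_cash <- as.integer(!tr & a == "low_cash")
  records$vcash_high_cash <- as.integer(!tr & a == "high_cash")
  records$untreated_treated <- as.integer(!tr & a != "placebo")
  if ("female" %in% names(records)) records$male <- 1L - records$female
  if ("age" %in% names(records)) records$age10 <- records$age / 10
  if ("weekly_food_spend" %in% names(records)) {
    records$food50 <- records$weekly_food_spend / 50
  }
  records
}
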