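# Arm rates, pooled rates, cluster-robust difference-in-means contrasts and
# the one-way ANOVA intracluster correlation.

#' Arm-level outcome rate with its counts
#'
#' @param records Individual table.
#' @param outcome Name of a binary outcome column; missing values (attrition)
#'   are excluded from the denominator.
#' @param arm Level of `group` to summarize.
#' @param group Grouping column; defaults to `"video"` (participants are
#'   classified by the video they actually saw, which is how the published
#'   arm tallies count embedded placebos in the placebo arm).
#' @return Tibble: `group`, `outcome`, `successes`, `n`, `rate` (percent).
#' @export
arm_rate <- function(records, outcome, arm, group = "video") {
  assert_cols(records, c(outcome, group))
  y <- records[[outcome]][records[[group]] == arm]
  y <- y[!is.na(y)]
  if (!length(y)) stop(sprintf("no observed '%s' outcomes in %s = '%s'", outcome, group, arm))
  tibble::tibble(group = arm, outcome = outcome,
                 successes = sum(y), n = length(y),
                 rate = 100 * mean(y))
}

#' Sample-size-weighted pooled rate
#'
#' @param rate Numeric vector of rates (percent).
#' @param n Matching vector of sample sizes.
#' @return The pooled rate (percent).
#' @export
pooled_rate <- function(rate, n) {
  if (length(rate) != length(n)) stop("rate and n must have equal length")
  if (any(n <= 0)) stop("all sample sizes must be positive")
  sum(rate * n) / sum(n)
}

# Core of the cluster-level t contrast, shared with the power module.
# w: cluster weights (sizes), m: cluster means, g: group index (1/2).
diff_from_cluster_stats <- function(w, m, g, conf = 0.95) {
  W <- tapply(w, g, sum)
  ybar <- tapply(w * m, g, sum) / W
  G <- tabulate(g, 2L)
  diff <- 100 * (ybar[[1]] - ybar[[2]])
  df <- G[1] + G[2] - 2L
  resid2 <- w * (m - ybar[g])^2
  s2 <- sum(resid2) / df
  se <- 100 * sqrt(s2 * (1 / W[[1]] + 1 / W[[2]]))
  if (se == 0) {
    p <- if (abs(diff) < 1e-12) 1 else 0
    tstat <- if (abs(diff) < 1e-12) 0 else Inf * sign(diff)
  } else {
    tstat <- diff / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  list(diff = diff, se = se, t = tstat, p = p, df = df,
       ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
       rate_a = 100 * ybar[[1]], rate_b = 100 * ybar[[2]], g = G)
}

#' Cluster-robust difference in means between two arms
#'
#' The contrast of size-weighted arm proportions, in percentage points, with
#' a standard error from the between-cluster variance of cluster-level means
#' (clusters weighted by size — algebraically identical to a weighted OLS of
#' cluster means on an arm dummy), a t reference with
#' `df = g_a + g_b - 2`, and a t-based confidence interval. Optional
#' individual weights (e.g. inverse-probability weights) replace counts in
#' both the cluster means and the cluster weights.
#'
#' @param records Individual table.
#' @param outcome Binary outcome column name (missing values dropped).
#' @param arm_a,arm_b The two levels to contrast (`arm_a` minus `arm_b`).
#' @param group Column holding the levels (default `"video"`).
#' @param cluster Cluster id column (default `"village_id"`).
#' @param weights Optional column name of individual weights.
#' @param conf Confidence level.
#' @return One-row tibble: `diff`, `se`, `ci_low`, `ci_high`, `statistic`,
#'   `p_value`, `df`, `rate_a`, `rate_b`, `n_a`, `n_b`, `g_a`, `g_b`.
#' @export
diff_in_means_clustered <- function(records, outcome, arm_a, arm_b,
                                    group = "video", cluster = "village_id",
                                    weights = NULL, conf = 0.95) {
  assert_cols(records, c(outcome, group, cluster))
  keep <- records[[group]] %in% c(arm_a, arm_b) & !is.na(records[[outcome]])
  d <- records[keep, , drop = FALSE]
  if (!nrow(d)) stop("no observations in the requested arms")
  g <- ifelse(d[[group]] == arm_a, 1L, 2L)
  w_i <- if (is.null(weights)) rep(1, nrow(d)) else d[[weights]]
  if (any(!is.finite(w_i) | w_i < 0)) stop("weights must be finite and non-negative")
  key <- paste(g, d[[cluster]], sep = "\r")
  w_c <- tapply(w_i, key, sum)
  m_c <- tapply(w_i * d[[outcome]], key, sum) / w_c
  g_c <- as.integer(substr(names(w_c), 1, 1))
  if (any(tabulate(g_c, 2L) < 2L)) {
    stop("each arm needs at least 2 clusters for a between-cluster variance")
  }
  st <- diff_from_cluster_stats(as.numeric(w_c), as.numeric(m_c), g_c, conf)
  tibble::tibble(
    outcome = outcome, arm_a = arm_a, arm_b = arm_b,
    diff = st$diff, se = st$se, ci_low = st$ci_low, ci_high = st$ci_high,
    statistic = st$t, p_value = st$p, df = st$df,
    rate_a = st$rate_a, rate_b = st$rate_b,
    n_a = sum(g == 1L), n_b = sum(g == 2L),
    g_a = st$g[1], g_b = st$g[2]
  )
}

#' One-way ANOVA intracluster correlation with confidence interval
#'
#' The ANOVA estimator
#' `rho = (MSB - MSW) / (MSB + (m0 - 1) * MSW)` with
#' `m0 = (N - sum(n_c^2)/N) / (G - 1)` the ANOVA mean cluster size. The
#' default interval uses the Smith/Swiger large-sample variance
#' `2 (N-1) (1-rho)^2 (1 + (m0-1) rho)^2 / (m0^2 (N-G)(G-1))`;
#' `ci = "bootstrap"` resamples clusters with replacement instead
#' (percentile interval).
#'
#' @param records Individual table.
#' @param outcome Binary (or numeric) outcome column; missing values dropped.
#' @param cluster Cluster id column.
#' @param ci `"smith"` or `"bootstrap"`.
#' @param conf Confidence level.
#' @param boot Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n_clusters`,
#'   `mean_cluster_size`, `m0`, `method`. An all-constant outcome yields
#'   `NA` ICC with a warning (undefined).
#' @export
icc_anova <- function(records, outcome, cluster = "village_id",
                      ci = c("smith", "bootstrap"), conf = 0.95,
                      boot = 500, seed = NULL) {
  ci <- match.arg(ci)
  assert_cols(records, c(outcome, cluster))
  keep <- !is.na(records[[outcome]])
  y <- records[[outcome]][keep]
  cl <- records[[cluster]][keep]
  est <- icc_point(y, cl)
  if (is.na(est$icc)) {
    warning("outcome is constant; ICC is undefined")
    return(tibble::tibble(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          n_clusters = est$G, mean_cluster_size = est$N / est$G,
                          m0 = est$m0, method = ci))
  }
  if (ci == "smith") {
    v <- 2 * (est$N - 1) * (1 - est$icc)^2 * (1 + (est$m0 - 1) * est$icc)^2 /
      (est$m0^2 * (est$N - est$G) * (est$G - 1))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- est$icc - z * sqrt(v)
    hi <- est$icc + z * sqrt(v)
  } else {
    ids <- unique(cl)
    idx <- split(seq_along(y), match(cl, ids))
    stat <- with_seed(seed, replicate(boot, {
      take <- sample.int(length(ids), replace = TRUE)
      rows <- unlist(idx[take], use.names = FALSE)
      cls <- rep(seq_along(take), lengths(idx[take]))
      icc_point(y[rows], cls)$icc
    }))
    qs <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    lo <- qs[[1]]; hi <- qs[[2]]
  }
  tibble::tibble(icc = est$icc, ci_low = lo, ci_high = hi,
                 n_clusters = est$G, mean_cluster_size = est$N / est$G,
                 m0 = est$m0, method = ci)
}

icc_point <- function(y, cl) {
  f <- factor(cl)
  n_c <- tabulate(f)
  m_c <- as.numeric(tapply(y, f, mean))
  N <- length(y)
  G <- length(n_c)
  if (G < 2L) stop("at least 2 clusters are required")
  m0 <- (N - sum(n_c^2) / N) / (G - 1)
  gm <- mean(y)
  ssb <- sum(n_c * (m_c - gm)^2)
  ssw <- sum((y - m_c[as.integer(f)])^2)
  msb <- ssb / (G - 1)
  msw <- ssw / (N - G)
  icc <- if (msb + (m0 - 1) * msw == 0) NA_real_ else
    (msb - msw) / (msb + (m0 - 1) * msw)
  list(icc = icc, N = N, G = G, m0 = m0)
}
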