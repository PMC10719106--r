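# Randomization inference: design-based p-values by re-drawing the
# assignment under the sharp null with outcomes held fixed.

#' Randomization-inference p-value
#'
#' Re-draws the entire arm-and-video assignment `B` times with
#' [redraw_assignment()] — the same quadruplets, a fresh uniform arm
#' permutation per quadruplet and fresh embedded-placebo positions, i.e.
#' exactly the assignment law of the design — recomputes the test statistic
#' on the fixed outcomes, and returns the two-sided Monte-Carlo p-value with
#' the +1 finite-sample correction:
#' `p = (1 + #\{|T_b| >= |T_obs|\}) / (B + 1)`.
#'
#' @param records Individual table including outcomes, `individual_id`,
#'   `village_id` and current `arm`/`video` columns.
#' @param plan The `trial_plan` that produced the observed assignment.
#' @param stat_fn Function `records -> numeric(1)`; must be deterministic
#'   given data and assignment. A failing draw is dropped and counted.
#' @param B Number of re-randomizations.
#' @param seed Integer seed.
#' @return Object of class `ri_result`: list with `observed`, `null_draws`,
#'   `p_value`, `B`, `n_failed`, `seed`.
#' @export
ri_pvalue <- function(records, plan, stat_fn, B = 2000, seed = 1L) {
  stopifnot(inherits(plan, "trial_plan"), is.function(stat_fn), B >= 1)
  assert_cols(records, c("individual_id", "village_id"))
  t_obs <- stat_fn(records)
  if (!is.finite(t_obs)) stop("observed statistic is not finite")
  seeds <- spawn_seeds(seed, B)
  draws <- rep(NA_real_, B)
  treated <- if ("untreated_spillover" %in% names(records)) {
    !records$untreated_spillover
  } else rep(TRUE, nrow(records))
  inds <- records[treated, c("individual_id", "village_id")]
  idx <- village_index(inds)
  rb <- records
  for (b in seq_len(B)) {
    re <- redraw_core(plan, inds, idx, seed = seeds[b])
    rb$arm <- re$arm[match(rb$village_id, re$village_id)]
    rb$video[treated] <- re$video
    draws[b] <- tryCatch(stat_fn(rb), error = function(e) NA_real_)
  }
  ok <- !is.na(draws)
  n_ok <- sum(ok)
  if (!n_ok) stop("all randomization draws failed")
  p <- (1 + sum(abs(draws[ok]) >= abs(t_obs) - 1e-12)) / (n_ok + 1)
  structure(list(observed = t_obs, null_draws = draws[ok], p_value = p,
                 B = B, n_failed = B - n_ok, seed = seed),
            class = "ri_result")
}

#' @export
print.ri_result <- function(x, ...) {
  cat("Randomization inference\n")
  cat(sprintf("  observed statistic: %.4f\n", x$observed))
  cat(sprintf("  p-value: %.4g  (B = %d, failed draws = %d)\n",
              x$p_value, x$B, x$n_failed))
  invisible(x)
}

#' Difference-in-means statistic factory for randomization inference
#'
#' Builds a fast `stat_fn` for [ri_pvalue()]: the cluster-level
#' size-weighted difference in mean outcome (percentage points) between two
#' video groups, with `"cash"` understood as low plus high cash pooled.
#'
#' @param outcome Outcome column.
#' @param arm_a,arm_b Video labels (or `"cash"`).
#' @return A function of `records`.
#' @export
ri_stat_diff <- function(outcome, arm_a = "cash", arm_b = "placebo") {
  expand <- function(a) if (identical(a, "cash")) c("low_cash", "high_cash") else a
  va <- expand(arm_a)
  vb <- expand(arm_b)
  function(records) {
    y <- records[[outcome]]
    v <- records$video
    ina <- v %in% va
    keep <- !is.na(y) & (ina | v %in% vb)
    y <- y[keep]
    g <- ifelse(ina[keep], 1L, 2L)
    vil <- records$village_id[keep]
    key <- g * 1000000L + match(vil, unique(vil))
    cnt <- rowsum(rep(1L, length(key)), key)
    sm <- rowsum(y, key)
    gc <- ifelse(as.integer(rownames(cnt)) >= 2000000L, 2L, 1L)
    st <- diff_from_cluster_stats(as.numeric(cnt), as.numeric(sm / cnt), gc)
    st$diff
  }
}
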