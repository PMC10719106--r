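# Covariate balance: standardized mean differences across arm pairs.

#' Standardized mean differences across arm pairs
#'
#' For continuous covariates, `SMD = (mean_a - mean_b) / pooled SD` with the
#' pooled SD `sqrt((s_a^2 + s_b^2) / 2)`; for binary covariates the raw
#' difference in proportions is reported instead (the published convention).
#' Pairs with `|SMD|` above the tolerance (default 0.1) are flagged. A zero
#' pooled SD makes the SMD undefined; such rows carry `NA` and a flag.
#'
#' @param records Individual table.
#' @param covariates Character vector of covariate columns (numeric or
#'   binary; factors are expanded to indicator proportions per level).
#' @param arm_pairs List of 2-vectors of arm labels, or NULL for all pairs of
#'   levels found in `group`.
#' @param group Grouping column (default `"arm"`).
#' @param tol Flag threshold on `|SMD|`.
#' @return Tibble: `covariate`, `arm_a`, `arm_b`, `mean_a`, `mean_b`, `smd`,
#'   `binary`, `flag`.
#' @export
smd_balance <- function(records, covariates, arm_pairs = NULL, group = "arm",
                        tol = 0.1) {
  assert_cols(records, c(covariates, group))
  levs <- unique(stats::na.omit(records[[group]]))
  if (is.null(arm_pairs)) {
    arm_pairs <- utils::combn(as.character(levs), 2, simplify = FALSE)
  }
  expand <- list()
  for (cv in covariates) {
    x <- records[[cv]]
    if (is.numeric(x)) {
      expand[[cv]] <- x
    } else {
      for (lv in unique(stats::na.omit(x))) {
        expand[[paste(cv, lv, sep = ":")]] <- as.numeric(x == lv)
      }
    }
  }
  rows <- list()
  for (pr in arm_pairs) {
    ga <- records[[group]] == pr[1]
    gb <- records[[group]] == pr[2]
    for (nm in names(expand)) {
      x <- expand[[nm]]
      xa <- x[ga & !is.na(x)]
      xb <- x[gb & !is.na(x)]
      binary <- all(x %in% c(0, 1, NA))
      ma <- mean(xa); mb <- mean(xb)
      if (binary) {
        smd <- ma - mb
      } else {
        sp <- sqrt((stats::var(xa) + stats::var(xb)) / 2)
        smd <- if (sp == 0) NA_real_ else (ma - mb) / sp
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = nm, arm_a = pr[1], arm_b = pr[2],
        mean_a = ma, mean_b = mb, smd = smd, binary = binary,
        flag = is.na(smd) | abs(smd) >= tol - 1e-12
      )
    }
  }
  dplyr::bind_rows(rows)
}
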