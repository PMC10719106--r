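# Leave-one-district-out sensitivity of a multi-variable model.

#' Leave-one-district-out refits
#'
#' Refits a cluster-robust logistic model dropping each district in turn; a
#' failure in one fold is recorded and the remaining folds proceed.
#'
#' @param records Individual table with `district_id`.
#' @param spec Model spec for [fit_logistic_clustered()].
#' @param cluster Cluster id column.
#' @param district Column holding the district id.
#' @return List with `or_table` (tibble of every fold's odds-ratio rows,
#'   keyed by `district_dropped`), `fits` (named list of `cluster_logit` or
#'   `NULL`) and `errors` (named character of fold failures).
#' @export
district_sensitivity <- function(records, spec, cluster = "village_id",
                                 district = "district_id") {
  assert_cols(records, district)
  ds <- unique(records[[district]])
  if (length(ds) < 2L) stop("at least 2 districts are required")
  fits <- list()
  errors <- character(0)
  tabs <- list()
  for (d in as.character(ds)) {
    sub <- records[records[[district]] != d, , drop = FALSE]
    res <- tryCatch(fit_logistic_clustered(sub, spec, cluster = cluster),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[d] <- conditionMessage(res)
      fits[d] <- list(NULL)
    } else {
      fits[[d]] <- res
      tab <- res$or_table
      tab$district_dropped <- d
      tabs[[d]] <- tab
    }
  }
  list(or_table = dplyr::bind_rows(tabs), fits = fits, errors = errors)
}
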