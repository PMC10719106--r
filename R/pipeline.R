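# End-to-end pipeline and the printed-count reproduction table.

#' Recompute the published headline arithmetic from its printed counts
#'
#' The package ships a small fixture of printed numerators, denominators,
#' rates and contrasts from the trial's summary tables. This function
#' recomputes every rate (`100 * numerator / denominator`), every pooled
#' rate (sample-size-weighted, via [pooled_rate()]) and every arm difference
#' from its referenced rows, and reports a check table of computed versus
#' printed values. Rows whose printed value disagrees with its own printed
#' counts at the printed precision — a handful of headline figures do — are
#' flagged rather than treated as errors.
#'
#' @param fixture Path to a fixture CSV; default the packaged one. Columns:
#'   `label`, `kind` (`rate`/`pooled`/`diff`), `outcome`, `group`,
#'   `numerator`, `denominator`, `printed` (character, preserving printed
#'   precision), `ref_a`, `ref_b` (row labels; for pooled rows `ref_a` is a
#'   `;`-separated component list).
#' @return Tibble: `label`, `kind`, `computed`, `printed`, `gap`, `flag`.
#' @export
reproduce_summary <- function(fixture = NULL) {
  fixture <- fixture %||% system.file("extdata", "printed_counts.csv",
                                      package = "quadtrial")
  fx <- utils::read.csv(fixture, colClasses = "character")
  need <- c("label", "kind", "numerator", "denominator", "printed", "ref_a", "ref_b")
  assert_cols(fx, need, "printed-counts fixture")
  if (anyDuplicated(fx$label)) stop("fixture labels must be unique")
  num <- suppressWarnings(as.numeric(fx$numerator))
  den <- suppressWarnings(as.numeric(fx$denominator))
  printed <- suppressWarnings(as.numeric(fx$printed))
  if (anyNA(printed)) stop("malformed fixture: non-numeric printed value")
  digits <- ifelse(grepl("\\.", fx$printed),
                   nchar(sub("^[^.]*\\.", "", fx$printed)), 0L)
  computed <- rep(NA_real_, nrow(fx))
  for (i in seq_len(nrow(fx))) {
    computed[i] <- switch(
      fx$kind[i],
      rate = if (!is.na(num[i]) && !is.na(den[i])) {
        arm_rate(tibble::tibble(v = "x",
                                y = rep(c(1, 0), c(num[i], den[i] - num[i]))),
                 "y", "x", group = "v")$rate
      } else printed[i],
      pooled = {
        parts <- match(strsplit(fx$ref_a[i], ";")[[1]], fx$label)
        if (anyNA(parts) || any(parts >= i)) {
          stop("malformed fixture: pooled refs must point to earlier rows")
        }
        pooled_rate(computed[parts], den[parts])
      },
      diff = {
        ia <- match(fx$ref_a[i], fx$label)
        ib <- match(fx$ref_b[i], fx$label)
        if (is.na(ia) || is.na(ib)) stop("malformed fixture: unknown diff reference")
        computed[ia] - computed[ib]
      },
      stop("malformed fixture: unknown kind '", fx$kind[i], "'")
    )
  }
  gap <- abs(computed - printed)
  tibble::tibble(
    label = fx$label, kind = fx$kind,
    computed = computed, printed = printed, gap = gap,
    flag = gap > 0.5 * 10^(-digits) + 1e-9
  )
}

#' Run the full design-simulate-estimate pipeline
#'
#' One seed-locked pass through every stage: generate villages and clinics,
#' run the two-stage randomization, generate participants (plus the
#' untreated spillover sample), assign videos with embedded placebos,
#' simulate the three clustered outcomes and attrition, then estimate arm
#' rates, cluster-robust contrasts, ICCs, the multi-variable logistic
#' models, spillover contrasts, covariate balance, the attrition logit and
#' (optionally) a randomization-inference p-value for the cash contrast.
#'
#' @param config A [trial_config()].
#' @param seed Master integer seed; every stage draws from substreams
#'   spawned from it.
#' @param out_dir Optional directory: result tables are written as CSV, all
#'   fits as JSON, plus a run manifest.
#' @param ri_reps Re-randomizations for the RI stage (0 skips it).
#' @return Invisibly, a list with `plan`, `records` and `results` (named
#'   list of tibbles/fits), and `manifest`.
#' @export
run_full_pipeline <- function(config = trial_config(), seed = 1L,
                              out_dir = NULL, ri_reps = 200L) {
  seeds <- spawn_seeds(seed, 8L)
  villages <- generate_villages(config, seed = seeds[1])
  clinics <- generate_clinics(villages, config, seed = seeds[2])
  plan <- randomize_trial(villages, config$quads_per_district, seed = seeds[3])
  sel <- plan$villages[plan$villages$selected, , drop = FALSE]
  records <- generate_individuals(sel, config, clinics = clinics,
                                  include_untreated = TRUE, seed = seeds[4])
  treated <- !records$untreated_spillover
  vids <- assign_videos(plan, records[treated, ], seed = seeds[5])
  records$video <- "none"
  records$video[treated] <- vids$video
  records <- simulate_outcomes(records, plan, config$outcomes, seed = seeds[6])
  records <- simulate_attrition(records, config$attrition, seed = seeds[7])
  records <- add_design_dummies(records)

  tr <- records[treated, , drop = FALSE]
  outcomes <- c(intention = "intention", reported = "reported_vax",
                verified = "verified_vax")
  rates <- dplyr::bind_rows(lapply(names(outcomes), function(o) {
    dplyr::bind_rows(lapply(ARM_LEVELS, function(a) {
      r <- arm_rate(tr, outcomes[[o]], a)
      r$outcome <- o
      r
    }))
  }))
  contrasts <- dplyr::bind_rows(lapply(names(outcomes), function(o) {
    rows <- lapply(TREATED_ARMS, function(a) {
      diff_in_means_clustered(tr, outcomes[[o]], a, "placebo")
    })
    rows[[length(rows) + 1L]] <-
      diff_in_means_clustered(tr, outcomes[[o]], "low_cash", "high_cash")
    out <- dplyr::bind_rows(rows)
    out$outcome <- o
    out
  }))
  iccs <- dplyr::bind_rows(lapply(names(outcomes), function(o) {
    x <- icc_anova(tr, outcomes[[o]])
    x$outcome <- o
    x
  }))
  fits <- lapply(outcomes, function(oc) {
    fit_logistic_clustered(
      tr, sprintf("%s ~ health + low_cash + high_cash + age10 + male + factor(district_id)", oc))
  })
  spill <- spillover_contrasts(records, "verified_vax")
  balance <- smd_balance(tr, c("female", "age", "household_size",
                               "weekly_food_spend", "education"), group = "video")
  attr_fit <- attrition_logit(records, "recontact")
  ri <- NULL
  if (ri_reps > 0) {
    ri <- ri_pvalue(records, plan, ri_stat_diff("verified_vax", "cash", "placebo"),
                    B = ri_reps, seed = seeds[8])
  }

  results <- list(rates = rates, contrasts = contrasts, iccs = iccs,
                  fits = fits, spillover = spill, balance = balance,
                  attrition = attr_fit, ri = ri)
  manifest <- list(
    command = "run_full_pipeline", seed = seed,
    config_hash = config_hash(config),
    quads_per_district = config$quads_per_district,
    per_village = config$per_village,
    n_villages = nrow(villages), n_selected = nrow(sel),
    n_records = nrow(records), n_treated = sum(treated),
    ri_reps = ri_reps,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    write_pipeline_results(results, manifest, out_dir)
  }
  invisible(list(plan = plan, records = records, results = results,
                 manifest = manifest))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

fit_to_list <- function(f) {
  list(terms = f$or_table$term, estimate = f$or_table$estimate,
       se = f$or_table$se, or = f$or_table$or,
       or_low = f$or_table$or_low, or_high = f$or_table$or_high,
       p_value = f$or_table$p_value,
       n = f$n, n_clusters = f$n_clusters, log_likelihood = f$log_likelihood)
}

write_pipeline_results <- function(results, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$rates, file.path(out_dir, "arm_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(results$contrasts, file.path(out_dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(results$iccs, file.path(out_dir, "iccs.csv"),
                   row.names = FALSE)
  utils::write.csv(results$spillover$contrasts,
                   file.path(out_dir, "spillover_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(results$balance, file.path(out_dir, "balance.csv"),
                   row.names = FALSE)
  js <- list(
    manifest = manifest[names(manifest) != "timestamp"],
    rates = results$rates, contrasts = results$contrasts, iccs = results$iccs,
    fits = lapply(results$fits, fit_to_list),
    spillover_fits = lapply(results$spillover$fits, fit_to_list),
    attrition = fit_to_list(results$attrition),
    ri = if (!is.null(results$ri)) {
      list(observed = results$ri$observed, p_value = results$ri$p_value,
           B = results$ri$B)
    }
  )
  jsonlite::write_json(js, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
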