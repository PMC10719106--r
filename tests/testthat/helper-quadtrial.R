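# Shared fixture builders: all synthetic, generated at test time.

# Deterministic village table: `n` villages per district, strictly
# decreasing populations (no ties unless asked for).
toy_villages <- function(n = 52, districts = paste0("D", 1:6), ties = FALSE) {
  pops <- if (ties) rep(1000, n) else seq(5000, by = -17, length.out = n)
  tibble::tibble(
    village_id = sprintf("%s_v%03d", rep(districts, each = n),
                         rep(seq_len(n), length(districts))),
    district_id = rep(districts, each = n),
    population = rep(pops, length(districts))
  )
}

# Minimal participant table for a plan's selected villages (no covariates).
sim_records <- function(plan, per_village = 21, seed = 1) {
  sel <- plan$villages[plan$villages$selected, ]
  ind <- tibble::tibble(
    individual_id = sprintf("%s_i%03d", rep(sel$village_id, each = per_village),
                            rep(seq_len(per_village), nrow(sel))),
    village_id = rep(sel$village_id, each = per_village),
    district_id = rep(sel$district_id, each = per_village)
  )
  vid <- assign_videos(plan, ind, seed = seed)
  ind$video <- vid$video
  ind$arm <- sel$arm[match(ind$village_id, sel$village_id)]
  ind$untreated_spillover <- FALSE
  ind
}

# Full mini-trial: plan + records with outcomes under given outcome params.
sim_trial <- function(params, quads_per_district = 13,
                      districts = paste0("D", 1:6), per_village = 21,
                      seed = 1) {
  v <- toy_villages(n = 4 * quads_per_district, districts = districts)
  plan <- randomize_trial(v, quads_per_district, seed = seed)
  rec <- sim_records(plan, per_village, seed = seed + 1)
  rec <- simulate_outcomes(rec, plan, params, seed = seed + 2)
  list(plan = plan, records = rec)
}

# Outcome params with a single outcome model replicated across the three
# outcome slots (tests mostly inspect one).
uniform_params <- function(rates, icc, ...) {
  p <- outcome_params(rates = rates, icc = icc, ...)
  list(intention = p, reported = p, verified = p, misreport = NULL)
}

flat_rates <- function(p) {
  c(placebo = p, health = p, low_cash = p, high_cash = p)
}
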