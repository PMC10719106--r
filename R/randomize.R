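# Two-stage randomization: population-ranked quadruplets, weighted quadruplet
# sampling, within-quadruplet arm assignment, embedded-placebo video draws.

#' Arm labels of the four-arm design
#' @return Character vector `c("placebo", "health", "low_cash", "high_cash")`.
#' @export
arm_levels <- function() ARM_LEVELS

#' Form population-ranked quadruplets within a district
#'
#' Villages are ranked by descending population (ties broken by `village_id`
#' for determinism) and each consecutive block of four becomes a quadruplet.
#' Leftover villages (when the district size is not a multiple of four) are
#' excluded and reported. Each quadruplet carries its population share of the
#' district's quadruplet-eligible villages, used as its sampling weight.
#'
#' @param villages Data frame with columns `village_id`, `district_id`,
#'   `population`.
#' @param district Optional district id; default processes every district.
#' @return A list with `quadruplets` (tibble: `quad_id`, `district_id`,
#'   `members` list-column of 4 village ids, `population`, `pop_share`) and
#'   `excluded` (tibble of leftover villages).
#' @export
form_quadruplets <- function(villages, district = NULL) {
  assert_cols(villages, c("village_id", "district_id", "population"), "villages")
  if (any(villages$population < 1)) stop("village populations must be >= 1")
  if (!is.null(district)) {
    villages <- villages[villages$district_id %in% district, , drop = FALSE]
  }
  quads <- list()
  excl <- list()
  for (d in unique(villages$district_id)) {
    v <- villages[villages$district_id == d, , drop = FALSE]
    if (nrow(v) < 4) {
      stop(sprintf("district %s has %d villages; at least 4 are required to form a quadruplet",
                   as.character(d), nrow(v)))
    }
    v <- v[order(-v$population, as.character(v$village_id)), , drop = FALSE]
    n_q <- nrow(v) %/% 4L
    used <- v[seq_len(4L * n_q), , drop = FALSE]
    left <- v[-seq_len(4L * n_q), , drop = FALSE]
    qpop <- tapply(used$population, rep(seq_len(n_q), each = 4L), sum)
    quads[[length(quads) + 1L]] <- tibble::tibble(
      quad_id = sprintf("%s_q%02d", as.character(d), seq_len(n_q)),
      district_id = d,
      members = split(used$village_id, rep(seq_len(n_q), each = 4L)),
      population = as.numeric(qpop),
      pop_share = as.numeric(qpop) / sum(used$population)
    )
    if (nrow(left)) excl[[length(excl) + 1L]] <- tibble::as_tibble(left)
  }
  list(
    quadruplets = dplyr::bind_rows(quads),
    excluded = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::as_tibble(villages[0, , drop = FALSE])
  )
}

#' Sample quadruplets with population-share weights
#'
#' Draws `k` distinct quadruplets without replacement by sequential weighted
#' draws with renormalization after each draw (the law implemented by
#' [base::sample()] with a `prob` argument). Randomization-inference re-draws
#' use this same routine.
#'
#' @param quads Quadruplet tibble from [form_quadruplets()].
#' @param k Number of quadruplets to select.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return The selected rows of `quads`, in draw order.
#' @export
sample_quadruplets <- function(quads, k, seed = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  if (k > nrow(quads)) {
    stop(sprintf("k = %d exceeds the %d available quadruplets", k, nrow(quads)))
  }
  if (any(!is.finite(quads$pop_share)) || any(quads$pop_share < 0)) {
    stop("quadruplet pop_share weights must be finite and non-negative")
  }
  idx <- with_seed(seed, sample.int(nrow(quads), size = k, replace = FALSE,
                                    prob = quads$pop_share))
  quads[idx, , drop = FALSE]
}

#' Assign the four arms within one quadruplet
#'
#' A uniformly random permutation of the four arms over the quadruplet's four
#' member villages.
#'
#' @param members Character/atomic vector of exactly 4 village ids.
#' @param seed Optional integer seed.
#' @return Tibble with columns `village_id`, `arm`.
#' @export
assign_arms <- function(members, seed = NULL) {
  tibble::tibble(village_id = members,
                 arm = with_seed(seed, arm_permutation(members)))
}

# The assignment law itself (current RNG stream); shared by assign_arms(),
# randomize_trial() and the randomization-inference re-draws.
arm_permutation <- function(members) {
  if (length(members) != 4L || anyDuplicated(members)) {
    stop("a quadruplet must have exactly 4 distinct member villages")
  }
  sample(ARM_LEVELS)
}

#' Assign individual videos within a village (25% embedded placebos)
#'
#' In a placebo village every participant sees the placebo video. In a
#' treated village exactly `round(0.25 * n)` participants (positions drawn
#' uniformly without replacement) see the placebo video — the embedded
#' placebos — and the rest see the village-arm video. `round()` follows R's
#' half-to-even convention; at the design's n = 21 this gives
#' `round(5.25) = 5` embedded placebos.
#'
#' @param village_arm One of [arm_levels()].
#' @param n Number of participants in the village.
#' @param seed Optional integer seed.
#' @return Character vector of length `n` of video labels.
#' @export
assign_individual_videos <- function(village_arm, n, seed = NULL) {
  stopifnot(village_arm %in% ARM_LEVELS, is.numeric(n), n >= 0)
  with_seed(seed, video_draw(village_arm, as.integer(n)))
}

# The video law itself (current RNG stream); shared with the re-draw path.
video_draw <- function(village_arm, n) {
  if (n == 0L) return(character(0))
  if (village_arm == "placebo") return(rep("placebo", n))
  n_pl <- as.integer(round(0.25 * n))
  videos <- rep(village_arm, n)
  if (n_pl > 0L) videos[sample.int(n, n_pl)] <- "placebo"
  videos
}

#' Run the full two-stage randomization
#'
#' For each district: form quadruplets ([form_quadruplets()]), sample
#' `quads_per_district` of them with population-share weights
#' ([sample_quadruplets()]), and assign the four arms within each selected
#' quadruplet ([assign_arms()]). Per-district RNG substreams are spawned
#' deterministically from the single master seed, so the whole plan is a pure
#' function of (village table, k, seed).
#'
#' @param villages Village table (`village_id`, `district_id`, `population`,
#'   optionally `lat`, `lon`).
#' @param quads_per_district Number of quadruplets to select per district.
#' @param seed Master integer seed.
#' @return An object of class `trial_plan`: list with `villages` (input plus
#'   `quad_id`, `selected`, `arm`), `quadruplets`, `selected_quads`,
#'   `excluded`, `quads_per_district`, `seed`.
#' @export
randomize_trial <- function(villages, quads_per_district = 13, seed = 1L) {
  fq <- form_quadruplets(villages)
  quads <- fq$quadruplets
  districts <- unique(villages$district_id)
  seeds <- spawn_seeds(seed, 2L * length(districts))
  sel_list <- list()
  arm_list <- list()
  for (i in seq_along(districts)) {
    d <- districts[[i]]
    qd <- quads[quads$district_id == d, , drop = FALSE]
    sel <- sample_quadruplets(qd, quads_per_district, seed = seeds[2L * i - 1L])
    arm_seeds <- spawn_seeds(seeds[2L * i], nrow(sel))
    arms <- dplyr::bind_rows(lapply(seq_len(nrow(sel)), function(j) {
      a <- assign_arms(sel$members[[j]], seed = arm_seeds[j])
      a$quad_id <- sel$quad_id[j]
      a
    }))
    sel_list[[i]] <- sel
    arm_list[[i]] <- arms
  }
  selected <- dplyr::bind_rows(sel_list)
  arm_map <- dplyr::bind_rows(arm_list)

  v <- tibble::as_tibble(villages)
  quad_of <- rep(quads$quad_id, lengths(quads$members))
  names(quad_of) <- unlist(quads$members)
  v$quad_id <- unname(quad_of[as.character(v$village_id)])
  v$arm <- arm_map$arm[match(v$village_id, arm_map$village_id)]
  v$selected <- !is.na(v$arm)

  structure(list(
    villages = v,
    quadruplets = quads,
    selected_quads = selected,
    arm_assignment = arm_map,
    excluded = fq$excluded,
    quads_per_district = quads_per_district,
    seed = seed
  ), class = "trial_plan")
}

#' Re-draw the arm and video assignment of an existing plan
#'
#' Holds the village structure fixed — the same selected quadruplets and the
#' same individuals per village — and re-randomizes (a) the arm permutation
#' within each quadruplet and (b) the embedded-placebo positions within each
#' treated village, using exactly the assignment law of [assign_arms()] and
#' [assign_individual_videos()]. This is the re-randomization step of
#' randomization inference.
#'
#' @param plan A `trial_plan`.
#' @param individuals Tibble with `individual_id`, `village_id` (rows in
#'   village order define the video positions).
#' @param seed Integer seed for this re-draw.
#' @return List with `arm_assignment` (village_id, arm) and `videos` (tibble
#'   `individual_id`, `village_id`, `video`).
#' @export
redraw_assignment <- function(plan, individuals, seed) {
  assert_cols(individuals, c("individual_id", "village_id"), "individuals")
  core <- redraw_core(plan, individuals, village_index(individuals), seed)
  list(
    arm_assignment = tibble::tibble(village_id = core$village_id,
                                    arm = core$arm),
    videos = tibble::tibble(individual_id = individuals$individual_id,
                            village_id = individuals$village_id,
                            video = core$video)
  )
}

# Hot path shared with ri_pvalue(): `idx` is a precomputed village index.
# Returns bare vectors (village_id/arm aligned; video aligned to rows).
redraw_core <- function(plan, individuals, idx, seed) {
  stopifnot(inherits(plan, "trial_plan"))
  sel <- plan$selected_quads
  with_seed(seed, {
    vid <- unlist(sel$members, use.names = FALSE)
    arm <- unlist(lapply(sel$members, arm_permutation), use.names = FALSE)
    video <- draw_videos(arm[match(names(idx), vid)], individuals, idx)
    list(village_id = vid, arm = arm, video = video)
  })
}

village_index <- function(individuals) {
  split(seq_len(nrow(individuals)),
        factor(individuals$village_id, levels = unique(individuals$village_id)))
}

# Shared video-assignment path (uses the current RNG stream): one
# video_draw() per village, positions per `idx`; `arm_of` aligned to `idx`.
draw_videos <- function(arm_of, individuals, idx) {
  if (anyNA(arm_of)) stop("some individuals belong to villages without an assigned arm")
  out <- rep(NA_character_, nrow(individuals))
  for (i in seq_along(idx)) {
    out[idx[[i]]] <- video_draw(arm_of[i], length(idx[[i]]))
  }
  out
}

#' Assign videos to individuals under a trial plan
#'
#' @param plan A `trial_plan` from [randomize_trial()].
#' @param individuals Tibble with `individual_id`, `village_id` for every
#'   participant in selected villages.
#' @param seed Integer seed.
#' @return Tibble `individual_id`, `village_id`, `video`.
#' @export
assign_videos <- function(plan, individuals, seed = 1L) {
  stopifnot(inherits(plan, "trial_plan"))
  assert_cols(individuals, c("individual_id", "village_id"), "individuals")
  idx <- village_index(individuals)
  arm_of <- plan$arm_assignment$arm[match(names(idx),
                                          plan$arm_assignment$village_id)]
  video <- with_seed(seed, draw_videos(arm_of, individuals, idx))
  tibble::tibble(individual_id = individuals$individual_id,
                 village_id = individuals$village_id,
                 video = video)
}

#' @export
print.trial_plan <- function(x, ...) {
  cat("Two-stage cluster randomization plan\n")
  cat(sprintf("  districts: %d, quadruplets formed: %d, selected per district: %d\n",
              length(unique(x$villages$district_id)), nrow(x$quadruplets),
              x$quads_per_district))
  cat(sprintf("  villages: %d total, %d selected, %d excluded as leftovers\n",
              nrow(x$villages), sum(x$villages$selected), nrow(x$excluded)))
  cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

#' Write a trial plan to delimited text plus a JSON manifest
#'
#' @param plan A `trial_plan`.
#' @param dir Output directory (created if needed).
#' @param videos Optional video assignment tibble from [assign_videos()].
#' @return Invisibly, the paths written.
#' @export
write_plan <- function(plan, dir, videos = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p1 <- file.path(dir, "village_arms.csv")
  utils::write.csv(plan$villages[plan$villages$selected,
                                 c("village_id", "district_id", "quad_id", "arm")],
                   p1, row.names = FALSE)
  paths <- c(paths, p1)
  if (!is.null(videos)) {
    p2 <- file.path(dir, "individual_videos.csv")
    utils::write.csv(videos, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  manifest <- list(
    seed = plan$seed,
    quads_per_district = plan$quads_per_district,
    n_villages_selected = 4L * nrow(plan$selected_quads),
    excluded_villages = as.character(plan$excluded$village_id)
  )
  pm <- file.path(dir, "plan_manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pm))
}
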