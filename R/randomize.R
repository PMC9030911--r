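#' Split a roster into the two baseline-adherence strata
#'
#' Partitions participants by `baseline_consistent`: those reporting
#' helmet use on every trip at baseline versus the rest. The two strata
#' are randomized separately so that each arm receives exactly the same
#' number of baseline-consistent participants.
#'
#' @param records Roster tibble with complete `baseline_consistent`.
#' @return A named list of two tibbles, `consistent` and `inconsistent`,
#'   preserving input order; sizes sum to `nrow(records)`.
#' @export
stratify <- function(records) {
  if (anyNA(records$baseline_consistent)) {
    abort("baseline_consistent must be complete for stratification.")
  }
  list(
    consistent = records[records$baseline_consistent == 1L, ],
    inconsistent = records[records$baseline_consistent == 0L, ]
  )
}

#' Form matched propensity triplets within strata
#'
#' Within each baseline-adherence stratum, participants are sorted by
#' ascending propensity score (ties broken by stable input order) and
#' grouped into consecutive runs of three: the three lowest scores form
#' the first triplet, the next three the second, and so on. The 1 or 2
#' highest-score participants that do not fill a triplet form a leftover
#' unit, later assigned by the first position(s) of its own permutation
#' draw. Input row order of the returned roster is preserved.
#'
#' @param records Roster tibble carrying a score column (default
#'   `.propensity`, see [add_propensity()]).
#' @param score_col Name of the score column.
#' @return `records` with columns `triplet_id` (unique across strata),
#'   `triplet_rank` (1-3, ascending score within the unit) and
#'   `leftover` (`TRUE` for units of fewer than three members).
#' @export
make_triplets <- function(records, score_col = ".propensity") {
  if (!score_col %in% names(records)) {
    abort(sprintf(
      "Score column '%s' not found; run add_propensity() first.", score_col
    ))
  }
  if (anyNA(records$baseline_consistent)) {
    abort("baseline_consistent must be complete for triplet formation.")
  }
  n <- nrow(records)
  triplet_id <- integer(n)
  triplet_rank <- integer(n)
  leftover <- logical(n)
  next_id <- 0L
  for (s in c(1L, 0L)) { # consistent stratum first, then inconsistent
    rows <- which(records$baseline_consistent == s)
    if (length(rows) == 0) next
    ord <- rows[order(records[[score_col]][rows])] # stable sort
    k <- length(ord)
    unit <- (seq_len(k) - 1L) %/% 3L + 1L
    n_complete <- k %/% 3L
    if (k %% 3L > 0 && n_complete > 0) {
      # the 1-2 highest scores form their own leftover unit
      is_left <- seq_len(k) > 3L * n_complete
    } else if (n_complete == 0) {
      is_left <- rep(TRUE, k)
    } else {
      is_left <- rep(FALSE, k)
    }
    triplet_id[ord] <- next_id + unit
    triplet_rank[ord] <- (seq_len(k) - 1L) %% 3L + 1L
    leftover[ord] <- is_left
    next_id <- next_id + max(unit)
  }
  dplyr::mutate(
    records,
    triplet_id = triplet_id, triplet_rank = triplet_rank, leftover = leftover
  )
}

# Draw one of the 6 arm permutations per unit and map members to arms.
# Shared by the design-time assignment and the rerandomization engine.
draw_arms <- function(triplet_id, triplet_rank, n_units, unit_index) {
  perm <- sample.int(6L, n_units, replace = TRUE)
  arm_code <- ARM_PERMUTATIONS[cbind(perm[unit_index], triplet_rank)]
  list(perm = perm, arm_code = arm_code)
}

unit_index_of <- function(triplet_id) {
  match(triplet_id, sort(unique(triplet_id)))
}

check_triplets <- function(records) {
  if (!all(c("triplet_id", "triplet_rank") %in% names(records))) {
    abort(paste(
      "Roster lacks triplet structure (columns triplet_id, triplet_rank);",
      "run randomize_trial() or make_triplets() first."
    ))
  }
}

check_seed <- function(seed) {
  if (is.null(seed) || is.na(seed) || !is.numeric(seed)) {
    abort("A numeric seed is required: assignments must be reproducible.")
  }
  as.integer(seed)
}

#' Randomly assign triplet members to the three arms
#'
#' For each complete triplet an integer from 1 to 6 is drawn uniformly
#' with replacement, selecting one of the six permutations ABC, ACB,
#' BAC, BCA, CAB, CBA by which the three score-ordered members are
#' assigned one-per-arm (A = control, B = fear appeal, C = social
#' norming). A leftover unit draws a permutation in the same way and its
#' member(s) take the first position(s) — the leftover participant is
#' treated as the lowest score of their own triplet.
#'
#' @param records Roster tibble with triplet columns ([make_triplets()]).
#' @param seed Integer seed; required (assignment must be reproducible).
#' @return `records` with columns `arm` (factor control/fear/social) and
#'   `permutation_index` (the unit's draw, 1-6) filled in.
#' @export
assign_arms <- function(records, seed) {
  check_triplets(records)
  seed <- check_seed(seed)
  uidx <- unit_index_of(records$triplet_id)
  n_units <- max(uidx)
  drawn <- withr::with_seed(
    seed, draw_arms(records$triplet_id, records$triplet_rank, n_units, uidx)
  )
  dplyr::mutate(
    records,
    arm = factor(ARM_LEVELS[drawn$arm_code], levels = ARM_LEVELS),
    permutation_index = drawn$perm[uidx]
  )
}

#' Rerandomize arms within the fixed triplet structure
#'
#' Redraws the per-triplet permutation (with replacement, uniformly over
#' the six arrangements) while holding triplet membership, covariates
#' and outcomes fixed — the relabelling step of the randomization
#' (permutation) test. Identical to [assign_arms()]; the separate name
#' marks intent.
#'
#' @inheritParams assign_arms
#' @return `records` with `arm` and `permutation_index` redrawn.
#' @export
rerandomize <- function(records, seed) {
  assign_arms(records, seed)
}

#' Run the full four-step matched-triplet randomization
#'
#' (1) fits the baseline helmet-use propensity model, (2) stratifies by
#' baseline adherence, (3) forms matched propensity triplets within each
#' stratum, (4) randomly assigns each triplet's members one-per-arm.
#' With strata of 207 and 184 this yields 69 + 61 complete triplets and
#' one leftover, hence arm sizes of 130/130/131 in some order, with the
#' baseline-consistent count identical across arms.
#'
#' @inheritParams fit_propensity
#' @param seed Integer seed for the permutation draws.
#' @return The roster with `.propensity`, `triplet_id`, `triplet_rank`,
#'   `leftover`, `arm` and `permutation_index` columns added; the fitted
#'   `propensity_model` is attached as attribute `"propensity_model"`.
#' @export
#' @examples
#' cfg <- trial_config(seed = 7)
#' roster <- simulate_trial(cfg)
#' assigned <- randomize_trial(roster, seed = 7)
#' table(assigned$arm)
randomize_trial <- function(records, covariates = default_covariates(),
                            seed) {
  model <- fit_propensity(records, covariates)
  out <- add_propensity(records, model)
  out <- make_triplets(out)
  out <- assign_arms(out, seed)
  attr(out, "propensity_model") <- model
  out
}

#' Summarize the triplet assignment log
#'
#' One row per triplet/leftover unit: stratum, ordered member ids,
#' drawn permutation and score range — the assignment log of the design.
#'
#' @param records An assigned roster ([randomize_trial()]).
#' @return A tibble with one row per unit.
#' @export
triplet_table <- function(records) {
  check_triplets(records)
  out <- dplyr::group_by(records, .data$triplet_id)
  out <- dplyr::summarise(
    out,
    stratum = STRATUM_LEVELS[2L - .data$baseline_consistent[1]],
    n_members = dplyr::n(),
    member_ids = paste(.data$id[order(.data$triplet_rank)], collapse = ","),
    permutation_index = if ("permutation_index" %in% names(records)) {
      .data$permutation_index[1]
    } else {
      NA_integer_
    },
    leftover = .data$leftover[1],
    score_min = if (".propensity" %in% names(records)) {
      min(.data$.propensity)
    } else {
      NA_real_
    },
    score_max = if (".propensity" %in% names(records)) {
      max(.data$.propensity)
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  dplyr::arrange(out, .data$triplet_id)
}
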