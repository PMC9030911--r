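#' Packaged aggregate count tables from the helmet-use trial
#'
#' The aggregate results of the three-arm SMS helmet-use trial among
#' 391 commercial motorcycle-taxi drivers are shipped
#' as plain-text count tables: the baseline balance counts per arm for
#' each covariate, the arm-level consistent-helmet-use counts at
#' baseline / week 3 / week 6, and the week-6 counts split by the
#' baseline-adherence stratum. Every table reproduces its printed
#' denominators exactly (e.g. week-6 analyzable n of 110 / 118 / 116).
#'
#' @param name Fixture key: `"table2"` (helmet use by wave and arm),
#'   `"table3"` (week-6 use by baseline stratum and arm), or
#'   `"table1_<variable>"` with variable one of `district`, `education`,
#'   `married`, `has_children`, `phone`, `driving_setting`, `night`,
#'   `baseline`, `speeding`, `weekend`.
#' @return A tibble of nonnegative integer counts. Balance tables have
#'   one row per level with per-arm columns `social`, `fear`, `control`;
#'   outcome tables have `events` and `n` per arm (and wave or stratum).
#' @export
#' @examples
#' trial_fixture("table2")
#' trial_fixture("table1_weekend")
trial_fixture <- function(name) {
  table1 <- readr::read_csv(
    system.file("extdata", "table1_counts.csv", package = "tripletrct",
                mustWork = TRUE),
    col_types = "cciii", progress = FALSE
  )
  valid <- c("table2", "table3", paste0("table1_", unique(table1$variable)))
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    abort(sprintf(
      "Unknown fixture %s. Valid keys: %s.",
      dQuote(as.character(name)[1], q = FALSE), paste(valid, collapse = ", ")
    ))
  }
  if (name == "table2") {
    return(readr::read_csv(
      system.file("extdata", "table2_helmet_use.csv", package = "tripletrct",
                  mustWork = TRUE),
      col_types = "ccii", progress = FALSE
    ))
  }
  if (name == "table3") {
    return(readr::read_csv(
      system.file("extdata", "table3_week6_by_stratum.csv",
                  package = "tripletrct", mustWork = TRUE),
      col_types = "ccii", progress = FALSE
    ))
  }
  var <- sub("^table1_", "", name)
  dplyr::select(dplyr::filter(table1, .data$variable == var), -"variable")
}

#' Reconstruct a participant-level roster from the packaged count tables
#'
#' Expands the aggregate outcome tables into a minimal participant-level
#' roster (arm, baseline stratum, week-3 and week-6 outcomes, and a
#' reconstructed triplet structure) sufficient to regenerate every
#' unadjusted estimate in the published tables. Week-6 outcomes are
#' allocated exactly per stratum-by-arm cell; week-3 outcomes are only
#' constrained at the arm level (their stratum split was not published),
#' and the triplet composition is a synthetic one-per-arm zip within each
#' stratum, so permutation p-values computed on this roster are
#' approximate: the true matched-triplet composition is unknown.
#'
#' @param shuffle_seed Optional integer; when supplied, outcomes are
#'   shuffled within each stratum-by-arm cell (counts unchanged) so the
#'   reconstructed triplets are not block-ordered.
#' @return A roster tibble with columns `id`, `baseline_consistent`,
#'   `arm`, `outcome_wk3`, `outcome_wk6`, `triplet_id`, `triplet_rank`,
#'   `leftover`.
#' @export
#' @examples
#' roster <- fixture_roster()
#' nrow(roster) # 391
fixture_roster <- function(shuffle_seed = NULL) {
  t2 <- trial_fixture("table2")
  t3 <- trial_fixture("table3")
  baseline <- dplyr::filter(t2, .data$wave == "baseline")

  cells <- purrr::map(ARM_LEVELS, function(a) {
    n_arm <- baseline$n[baseline$arm == a]
    n_cons <- baseline$events[baseline$arm == a]
    purrr::map(STRATUM_LEVELS, function(s) {
      n_cell <- if (s == "consistent") n_cons else n_arm - n_cons
      row3 <- dplyr::filter(t3, .data$stratum == s, .data$arm == a)
      wk6 <- c(rep(1L, row3$events), rep(0L, row3$n - row3$events),
               rep(NA_integer_, n_cell - row3$n))
      if (!is.null(shuffle_seed)) {
        wk6 <- withr::with_seed(shuffle_seed + match(a, ARM_LEVELS), sample(wk6))
      }
      tibble::tibble(
        baseline_consistent = as.integer(s == "consistent"),
        arm = a, outcome_wk6 = wk6
      )
    })
  })
  roster <- dplyr::bind_rows(purrr::flatten(cells))

  # week-3 outcomes: allocate per arm (the published split is arm-level only)
  wk3 <- dplyr::filter(t2, .data$wave == "wk3")
  roster <- dplyr::group_by(roster, .data$arm)
  roster <- dplyr::mutate(roster, outcome_wk3 = {
    g <- dplyr::cur_group()$arm
    row <- wk3[wk3$arm == g, ]
    c(rep(1L, row$events), rep(0L, row$n - row$events),
      rep(NA_integer_, dplyr::n() - row$n))
  })
  roster <- dplyr::ungroup(roster)

  # synthetic triplets: zip one member per arm within each stratum
  roster <- dplyr::group_by(roster, .data$baseline_consistent, .data$arm)
  roster <- dplyr::mutate(roster, .zip = dplyr::row_number())
  roster <- dplyr::ungroup(roster)
  roster <- dplyr::group_by(roster, .data$baseline_consistent, .data$.zip)
  roster <- dplyr::mutate(
    roster,
    .complete = dplyr::n() == 3L,
    triplet_rank = dplyr::row_number()
  )
  roster <- dplyr::ungroup(roster)
  roster <- dplyr::mutate(
    roster,
    triplet_id = dplyr::dense_rank(
      interaction(.data$baseline_consistent, .data$.zip, drop = TRUE)
    ),
    leftover = !.data$.complete
  )
  roster <- dplyr::arrange(roster, .data$triplet_id, .data$triplet_rank)
  roster <- dplyr::mutate(
    roster,
    id = sprintf("P%03d", dplyr::row_number()),
    arm = factor(.data$arm, levels = ARM_LEVELS)
  )
  dplyr::select(
    roster, "id", "baseline_consistent", "arm", "outcome_wk3", "outcome_wk6",
    "triplet_id", "triplet_rank", "leftover"
  )
}
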