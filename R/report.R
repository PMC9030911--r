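#' Run the full trial analysis on an assigned roster
#'
#' End-to-end orchestration reproducing the published table set from any
#' roster with assigned arms and outcomes: the baseline balance table
#' (when covariates are present), adherence proportions by wave and arm
#' with differences from control and the week-6 difference in
#' differences, the 3-contrast by 3-subgroup grid of unadjusted (and
#' optionally covariate-adjusted) odds ratios with triplet-permutation
#' p-values, the effect-modification row of ratios of odds ratios, and
#' the Holm-Bonferroni decisions for the primary family (the three
#' all-observations comparisons). Intervention-vs-control contrasts are
#' tested one-sided, the head-to-head contrast two-sided. Deterministic
#' given `seed`; every dropped-row count is carried in the tables.
#'
#' @param records Assigned roster with triplet structure and outcomes.
#' @param B Permutations per count-based test.
#' @param B_adjusted Permutations per covariate-adjusted test.
#' @param seed Integer seed.
#' @param alpha Family-wise level for the Holm correction.
#' @param adjusted Also compute the covariate-adjusted grid? Requires
#'   the adjustment covariates in the roster.
#' @param controls Adjustment covariate set.
#' @return An object of class `trial_report`: a list with elements
#'   `balance`, `proportions`, `comparisons`, `effect_modification`,
#'   `holm`, and `meta`.
#' @export
run_full_analysis <- function(records, B = 10000, B_adjusted = 5000, seed,
                              alpha = 0.05, adjusted = FALSE,
                              controls = default_adjustment()) {
  if (!"arm" %in% names(records) || anyNA(records$arm)) {
    abort("Roster has no assigned arms; run randomize_trial() first.")
  }
  check_triplets(records)
  seed <- check_seed(seed)

  contrasts <- tibble::tribble(
    ~exposed, ~reference, ~sided,
    "fear",   "control",  "one",
    "social", "control",  "one",
    "social", "fear",     "two"
  )
  subgroups <- SUBGROUP_LEVELS

  balance <- tryCatch(balance_table(records), error = function(e) NULL)

  proportions <- tidyr::expand_grid(wave = WAVE_LEVELS, arm = ARM_LEVELS)
  proportions <- dplyr::mutate(proportions, purrr::map2_dfr(
    .data$wave, .data$arm, function(w, a) {
      y <- wave_outcome(records, w)[as.character(records$arm) == a]
      tibble::tibble(events = sum(y == 1L, na.rm = TRUE), n = sum(!is.na(y)))
    }
  ))
  proportions <- dplyr::mutate(
    proportions,
    percent = 100 * .data$events / .data$n
  )
  proportions <- dplyr::group_by(proportions, .data$wave)
  proportions <- dplyr::mutate(
    proportions,
    diff_from_control = .data$percent -
      .data$percent[.data$arm == "control"]
  )
  proportions <- dplyr::ungroup(proportions)
  wk6 <- dplyr::filter(proportions, .data$wave == "wk6")
  base <- dplyr::filter(proportions, .data$wave == "baseline")
  did <- tibble::tibble(
    arm = wk6$arm,
    week6_did = difference_in_differences(wk6$diff_from_control,
                                          base$diff_from_control)
  )

  grid <- tidyr::expand_grid(contrasts, subgroup = subgroups)
  test_seed <- seed
  run_grid <- function(adj) {
    purrr::pmap_dfr(grid, function(exposed, reference, sided, subgroup) {
      est <- arm_comparison(records, exposed, reference, wave = "wk6",
                            subgroup = subgroup, adjusted = adj,
                            controls = controls)
      test_seed <<- test_seed + 1L
      pt <- permutation_test(
        records, exposed, reference, wave = "wk6", subgroup = subgroup,
        statistic = if (adj) "adjusted_log_or" else "log_or",
        sided = sided, B = if (adj) B_adjusted else B, seed = test_seed,
        controls = controls, keep_null = FALSE
      )
      dplyr::mutate(est, sided = sided, p_value = pt$p_value, B = pt$B,
                    seed = pt$seed)
    })
  }
  comparisons <- run_grid(FALSE)
  if (adjusted) {
    comparisons <- dplyr::bind_rows(comparisons, run_grid(TRUE))
  }

  effect_mod <- purrr::pmap_dfr(contrasts, function(exposed, reference, sided) {
    cons <- dplyr::filter(comparisons, !.data$adjusted,
                          .data$exposed == !!exposed,
                          .data$reference == !!reference,
                          .data$subgroup == "baseline_consistent")
    inc <- dplyr::filter(comparisons, !.data$adjusted,
                         .data$exposed == !!exposed,
                         .data$reference == !!reference,
                         .data$subgroup == "baseline_inconsistent")
    test_seed <<- test_seed + 1L
    pt <- effect_modification_test(records, exposed, reference, B = B,
                                   seed = test_seed, keep_null = FALSE)
    tibble::tibble(
      exposed = exposed, reference = reference,
      ratio_of_odds_ratios = ratio_of_odds_ratios(cons$odds_ratio,
                                                  inc$odds_ratio),
      sided = "two", p_value = pt$p_value, B = pt$B, seed = pt$seed
    )
  })

  primary <- dplyr::filter(comparisons, !.data$adjusted,
                           .data$subgroup == "all")
  holm <- holm_bonferroni(
    setNames(primary$p_value,
             paste(primary$exposed, primary$reference, sep = "_vs_")),
    alpha = alpha
  )

  structure(
    list(
      balance = balance, proportions = proportions,
      week6_did = did, comparisons = comparisons,
      effect_modification = effect_mod, holm = holm,
      meta = list(
        seed = seed, B = B, B_adjusted = if (adjusted) B_adjusted else NA,
        alpha = alpha, n = nrow(records),
        package_version = as.character(utils::packageVersion("tripletrct"))
      )
    ),
    class = "trial_report"
  )
}

#' Write a trial report as JSON
#'
#' Serializes every table of a [run_full_analysis()] report; identical
#' seeds give byte-identical files.
#'
#' @param report A `trial_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "trial_report"))
  jsonlite::write_json(
    unclass(report), path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> n = %d, seed = %d, B = %d\n",
              x$meta$n, x$meta$seed, x$meta$B))
  cat("\nUnadjusted week-6 odds ratios (permutation p):\n")
  grid <- dplyr::filter(x$comparisons, !.data$adjusted)
  out <- dplyr::mutate(
    grid,
    cell = sprintf("%.2f (p=%.2g)", .data$odds_ratio, .data$p_value),
    contrast = paste(.data$exposed, .data$reference, sep = ":")
  )
  print.data.frame(
    tidyr::pivot_wider(out[c("subgroup", "contrast", "cell")],
                       names_from = "contrast", values_from = "cell"),
    row.names = FALSE
  )
  cat("\nEffect modification (ratio of odds ratios, two-sided p):\n")
  print.data.frame(as.data.frame(x$effect_modification[
    c("exposed", "reference", "ratio_of_odds_ratios", "p_value")
  ]), row.names = FALSE, digits = 3)
  cat(sprintf(
    "\nHolm-Bonferroni (primary family, alpha = %.2f): %d of %d rejected\n",
    x$meta$alpha, sum(x$holm$reject), nrow(x$holm)
  ))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null-distribution plot for a permutation test
#'
#' Histogram of the permuted statistics with the observed statistic
#' marked; the shaded fraction at or beyond the line is the p-value.
#'
#' @param object A [permutation_test()] result with `keep_null = TRUE`.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, bins = 50, ...) {
  if (is.null(object$null_draws)) {
    abort("No null draws stored; rerun with keep_null = TRUE.")
  }
  draws <- object$null_draws[is.finite(object$null_draws)]
  ggplot2::ggplot(tibble::tibble(statistic = draws),
                  ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      title = sprintf("Permutation null: %s, %s vs %s", object$statistic,
                      object$exposed, object$reference),
      subtitle = sprintf("%s-sided p = %.4g (B = %d)", object$sided,
                         object$p_value, object$B),
      x = "permuted statistic", y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Odds-ratio grid plot for a trial report
#'
#' Dot plot of the unadjusted week-6 odds ratios by contrast and
#' subgroup, on a log scale with the null at 1.
#'
#' @param object A `trial_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trial_report <- function(object, ...) {
  grid <- dplyr::filter(object$comparisons, !.data$adjusted)
  grid <- dplyr::mutate(
    grid, contrast = paste(.data$exposed, .data$reference, sep = " vs ")
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$odds_ratio,
                                     y = .data$contrast,
                                     colour = .data$subgroup)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "week-6 odds ratio (log scale)", y = NULL,
                  colour = "subgroup") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.trial_report <- function(x, ...) {
  x$comparisons
}

#' @exportS3Method generics::glance
glance.trial_report <- function(x, ...) {
  tibble::tibble(
    n = x$meta$n, seed = x$meta$seed, B = x$meta$B,
    alpha = x$meta$alpha, holm_rejections = sum(x$holm$reject)
  )
}
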