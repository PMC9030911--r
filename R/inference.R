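#' Triplet-level permutation (rerandomization) test
#'
#' Randomization inference for one arm contrast: the test statistic is
#' computed on the observed assignment, then each triplet (and leftover
#' unit) is independently rerandomized with replacement to one of the 6
#' arm permutations — exactly the original assignment mechanism — and
#' the statistic recomputed, `B` times. Outcomes, covariates and outcome
#' missingness travel with the participant; the statistic is evaluated
#' on the observed-outcome subset of each permuted dataset, so attrition
#' is handled by design. Significance is the fraction of permuted
#' statistics at least as large as the observed one.
#'
#' The one-sided p-value (allowed only for intervention-vs-control
#' contrasts, where a benefit is hypothesized a priori) counts permuted
#' statistics `>=` the signed observed statistic, oriented so that
#' positive means the exposed arm did better; the two-sided p-value
#' counts `|permuted| >= |observed|`. The default is the plain fraction
#' over `B`; `p_method = "plus_one"` gives the finite-sample-valid
#' `(count + 1)/(B + 1)` variant.
#'
#' @inheritParams arm_comparison
#' @param statistic `"log_or"` (log odds ratio of the contrast, the
#'   default), `"adjusted_log_or"` (arm coefficient of the
#'   covariate-adjusted logistic fit) or `"log_ror"` (log ratio of
#'   odds ratios between the baseline strata, for effect modification;
#'   ignores `subgroup`).
#' @param sided `"one"` or `"two"`.
#' @param B Number of rerandomizations (defaults: 10,000 for count-based
#'   statistics, 5,000 for the covariate-adjusted statistic).
#' @param seed Integer seed; required.
#' @param p_method `"plain"` or `"plus_one"`.
#' @param keep_null Keep the permuted statistics in the result (needed
#'   for `autoplot`)?
#' @return An object of class `perm_test` with the observed statistic,
#'   p-value, `B`, seed, exceedance count, null-distribution summary and
#'   (optionally) the permuted draws. Permuted datasets on which the
#'   statistic is undefined (all-zero cross-products) are counted as
#'   exceedances, and the test aborts if they exceed 10% of `B`.
#' @export
#' @examples
#' roster <- fixture_roster()
#' permutation_test(roster, "social", "control", B = 200, seed = 1)
permutation_test <- function(records, exposed, reference, wave = "wk6",
                             subgroup = "all",
                             statistic = c("log_or", "adjusted_log_or",
                                           "log_ror"),
                             sided = c("one", "two"), B = NULL, seed,
                             controls = default_adjustment(),
                             p_method = c("plain", "plus_one"),
                             keep_null = TRUE) {
  check_triplets(records)
  seed <- check_seed(seed)
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  p_method <- match.arg(p_method)
  exposed <- match.arg(exposed, ARM_LEVELS)
  reference <- match.arg(reference, ARM_LEVELS)
  if (exposed == reference) abort("exposed and reference must differ.")
  if (sided == "one" && reference != "control") {
    abort(paste(
      "One-sided tests are reserved for intervention-vs-control contrasts;",
      "use sided = \"two\"."
    ))
  }
  if (is.null(B)) B <- if (statistic == "adjusted_log_or") 5000L else 10000L
  if (B < 1) abort("B must be at least 1.")

  y <- wave_outcome(records, wave)
  e <- match(exposed, ARM_LEVELS)
  r <- match(reference, ARM_LEVELS)
  stat_fun <- switch(statistic,
    log_or = log_or_stat(y, subgroup_mask(records, subgroup), e, r),
    log_ror = log_ror_stat(y, records$baseline_consistent, e, r),
    adjusted_log_or = adjusted_stat(records, y,
                                    subgroup_mask(records, subgroup),
                                    e, r, controls)
  )

  obs_code <- match(as.character(records$arm), ARM_LEVELS)
  if (anyNA(obs_code)) abort("All analyzed records need an assigned arm.")
  observed <- stat_fun(obs_code)
  if (is.nan(observed)) {
    # a constant analyzed outcome makes the statistic invariant under any
    # relabeling: no assignment can look more extreme, so p = 1
    mask <- if (statistic == "log_ror") {
      rep(TRUE, nrow(records))
    } else {
      subgroup_mask(records, subgroup)
    }
    y_obs <- y[mask & !is.na(y)]
    if (length(unique(y_obs)) < 2) {
      return(structure(
        list(
          statistic = statistic, exposed = exposed, reference = reference,
          wave = wave, subgroup = if (statistic == "log_ror") NA else subgroup,
          sided = sided, observed = NaN, p_value = 1, B = B, seed = seed,
          p_method = p_method, exceedances = B, n_undefined = B,
          n_units = max(unit_index_of(records$triplet_id)),
          null_mean = NaN, null_sd = NaN, null_draws = NULL
        ),
        class = "perm_test"
      ))
    }
    abort("Test statistic is undefined on the observed data (empty cells).")
  }

  uidx <- unit_index_of(records$triplet_id)
  n_units <- max(uidx)
  pos <- records$triplet_rank
  null_draws <- withr::with_seed(seed, {
    perms <- matrix(sample.int(6L, n_units * B, replace = TRUE), nrow = n_units)
    vapply(seq_len(B), function(b) {
      stat_fun(ARM_PERMUTATIONS[cbind(perms[uidx, b], pos)])
    }, numeric(1))
  })

  undefined <- is.nan(null_draws)
  if (sum(undefined) > 0.1 * B) {
    abort(sprintf(
      "Statistic undefined on %d of %d permuted datasets (>10%%); the contrast is too sparse for this statistic.",
      sum(undefined), B
    ))
  }
  exceed <- if (sided == "one") {
    sum(null_draws >= observed | undefined)
  } else {
    sum(abs(null_draws) >= abs(observed) | undefined)
  }
  p <- switch(p_method,
    plain = exceed / B,
    plus_one = (exceed + 1) / (B + 1)
  )
  finite <- null_draws[is.finite(null_draws)]
  structure(
    list(
      statistic = statistic, exposed = exposed, reference = reference,
      wave = wave, subgroup = if (statistic == "log_ror") NA else subgroup,
      sided = sided, observed = observed, p_value = p, B = B, seed = seed,
      p_method = p_method, exceedances = exceed,
      n_undefined = sum(undefined), n_units = n_units,
      null_mean = mean(finite), null_sd = stats::sd(finite),
      null_draws = if (keep_null) null_draws else NULL
    ),
    class = "perm_test"
  )
}

log_or_stat <- function(y, mask, e, r) {
  y1 <- which(mask & !is.na(y) & y == 1L)
  y0 <- which(mask & !is.na(y) & y == 0L)
  function(code) {
    c1 <- code[y1]
    c0 <- code[y0]
    log(sum(c1 == e)) + log(sum(c0 == r)) -
      log(sum(c0 == e)) - log(sum(c1 == r))
  }
}

log_ror_stat <- function(y, baseline_consistent, e, r) {
  cons <- log_or_stat(y, baseline_consistent == 1L, e, r)
  inc <- log_or_stat(y, baseline_consistent == 0L, e, r)
  function(code) cons(code) - inc(code)
}

adjusted_stat <- function(records, y, mask, e, r, controls) {
  controls <- intersect(controls, names(records))
  if (length(controls) == 0) abort("No adjustment covariates present.")
  cc <- mask & !is.na(y) & stats::complete.cases(records[controls])
  idx <- which(cc)
  dat <- records[idx, controls, drop = FALSE]
  keep <- controls[purrr::map_lgl(controls, function(v) {
    length(unique(dat[[v]])) > 1
  })]
  mm <- stats::model.matrix(
    stats::reformulate(c("1", keep)), data = dat,
    contrasts.arg = treatment_contrasts(dat, keep)
  )
  ycc <- y[idx]
  function(code) {
    ccode <- code[idx]
    rows <- ccode == e | ccode == r
    x <- cbind(mm[rows, , drop = FALSE], .exposed = as.numeric(ccode[rows] == e))
    fit <- suppressWarnings(
      stats::glm.fit(x, ycc[rows], family = binomial(),
                     control = list(epsilon = 1e-8, maxit = 50))
    )
    beta <- coef(fit)[".exposed"]
    if (is.na(beta)) NaN else as.numeric(beta)
  }
}

#' Permutation test for effect modification by baseline adherence
#'
#' Tests whether an arm contrast's effect differs between the baseline
#' always-wearer and inconsistent-wearer strata. The observed statistic
#' is the log ratio of odds ratios (always-wearer stratum in the
#' numerator); the null distribution comes from triplet rerandomization
#' and the p-value is two-sided. Separation in a permuted stratum
#' contributes a sign-preserving infinite statistic.
#'
#' @inheritParams permutation_test
#' @return A `perm_test` object.
#' @export
effect_modification_test <- function(records, exposed, reference,
                                     B = 10000, seed,
                                     p_method = c("plain", "plus_one"),
                                     keep_null = TRUE) {
  if (!all(c(0L, 1L) %in% records$baseline_consistent)) {
    abort("Both baseline strata must be nonempty for effect modification.")
  }
  permutation_test(
    records, exposed, reference, wave = "wk6", statistic = "log_ror",
    sided = "two", B = B, seed = seed, p_method = match.arg(p_method),
    keep_null = keep_null
  )
}

#' Holm-Bonferroni step-down multiple-testing correction
#'
#' Standard step-down control of the family-wise error rate: p-values
#' are sorted ascending and the i-th smallest is compared to
#' `alpha/(m - i + 1)`, stopping at the first failure — so the most
#' significant of 3 p-values must be at most `alpha/3` (0.0167 at
#' alpha = 0.05) for any rejection. Adjusted p-values are the usual
#' monotone step-down values capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`, optionally
#'   named by comparison.
#' @param alpha Family-wise error level.
#' @return A tibble in input order: `comparison`, `p_value`, `rank`,
#'   `threshold`, `reject`, `p_adjusted`. Empty input gives an empty
#'   tibble.
#' @export
#' @examples
#' holm_bonferroni(c(fear = .47, social = .04, head_to_head = .12))
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(
      comparison = character(), p_value = numeric(), rank = integer(),
      threshold = numeric(), reject = logical(), p_adjusted = numeric()
    ))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    abort("p_values must lie in [0, 1] with no missing values.")
  }
  m <- length(p_values)
  ord <- order(p_values)
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  threshold <- alpha / (m - rank + 1)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) {
      reject_sorted[i] <- TRUE
    } else {
      break # step-down stops at the first failure
    }
  }
  reject <- logical(m)
  reject[ord] <- reject_sorted
  tibble::tibble(
    comparison = names(p_values) %||% paste0("H", seq_len(m)),
    p_value = as.numeric(p_values),
    rank = rank,
    threshold = threshold,
    reject = reject,
    p_adjusted = p.adjust(p_values, method = "holm")
  )
}

#' @export
print.perm_test <- function(x, ...) {
  lab <- if (x$statistic == "log_ror") {
    sprintf("log ratio of odds ratios, %s vs %s", x$exposed, x$reference)
  } else {
    sprintf("%s, %s vs %s (%s, %s)", x$statistic, x$exposed, x$reference,
            x$wave, x$subgroup)
  }
  cat(sprintf(
    "<perm_test> %s\n  observed = %.4f, %s-sided p = %.4g (B = %d, seed = %d)\n",
    lab, x$observed, x$sided, x$p_value, x$B, x$seed
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, exposed = x$exposed, reference = x$reference,
    wave = x$wave, subgroup = x$subgroup, sided = x$sided,
    estimate = exp(x$observed), log_estimate = x$observed,
    p_value = x$p_value
  )
}

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    B = x$B, seed = x$seed, exceedances = x$exceedances,
    n_undefined = x$n_undefined, n_units = x$n_units,
    null_mean = x$null_mean, null_sd = x$null_sd, p_method = x$p_method
  )
}
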