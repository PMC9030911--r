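#' Odds ratio from a two-by-two table
#'
#' Cross-product odds ratio `(a d)/(b c)` of an exposed-vs-reference
#' table, equal to the exponentiated arm coefficient of a logistic
#' regression with a single arm indicator. A zero cell yields an
#' infinite or zero odds ratio, flagged rather than raised as an error.
#'
#' @param t A one-row [two_by_two()] tibble.
#' @return A one-row effect-estimate tibble: `odds_ratio`, `log_or`,
#'   `risk_difference` (percentage points), `n_exposed`, `n_reference`,
#'   and `finite` (FALSE when a zero cell degenerates the estimate).
#' @export
#' @examples
#' odds_ratio_2x2(two_by_two(74, 42, 58, 52)) # week-6 social vs control
odds_ratio_2x2 <- function(t) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(t)), nrow(t) == 1)
  log_or <- log(t$a) + log(t$d) - log(t$b) - log(t$c)
  tibble::tibble(
    odds_ratio = exp(log_or),
    log_or = log_or,
    risk_difference = risk_difference(t$a, t$a + t$b, t$c, t$c + t$d),
    n_exposed = t$a + t$b,
    n_reference = t$c + t$d,
    finite = is.finite(log_or)
  )
}

#' Risk difference in percentage points
#'
#' `100 * (k_exposed/n_exposed - k_reference/n_reference)`, computed
#' from unrounded proportions (reporting rounds to 1 decimal).
#'
#' @param k_exposed,n_exposed Events and total in the exposed arm.
#' @param k_reference,n_reference Events and total in the reference arm.
#' @return Difference in percentage points (vectorized).
#' @export
#' @examples
#' risk_difference(74, 116, 58, 110) # 11.1 after rounding
risk_difference <- function(k_exposed, n_exposed, k_reference, n_reference) {
  if (any(n_exposed <= 0) || any(n_reference <= 0)) {
    abort("Denominators must be positive.")
  }
  100 * (k_exposed / n_exposed - k_reference / n_reference)
}

#' Difference in differences of arm-vs-control percentages
#'
#' The change in an arm's lead over control between baseline and week 6:
#' `week6_diff - baseline_diff`, both in percentage points against the
#' same reference arm and computed from unrounded proportions.
#'
#' @param week6_diff,baseline_diff Percentage-point differences.
#' @return Percentage points (vectorized).
#' @export
#' @examples
#' difference_in_differences(0.7, -0.4) # fear arm, 1.1
difference_in_differences <- function(week6_diff, baseline_diff) {
  week6_diff - baseline_diff
}

#' Ratio of odds ratios between baseline-adherence subgroups
#'
#' Effect-modification measure: the odds ratio of an arm contrast among
#' baseline consistent wearers divided by the same contrast's odds ratio
#' among baseline inconsistent wearers (numerator convention: the
#' always-wearer stratum). Zero or infinite inputs pass through flagged
#' by the resulting zero/infinite value.
#'
#' @param or_consistent Odds ratio in the baseline-consistent stratum.
#' @param or_inconsistent Odds ratio in the baseline-inconsistent stratum.
#' @return The ratio (vectorized).
#' @export
#' @examples
#' ratio_of_odds_ratios(2.2959, 1.1097) # 2.07 after rounding
ratio_of_odds_ratios <- function(or_consistent, or_inconsistent) {
  if (any(or_consistent < 0, na.rm = TRUE) ||
      any(or_inconsistent < 0, na.rm = TRUE)) {
    abort("Odds ratios must be nonnegative.")
  }
  or_consistent / or_inconsistent
}

#' Fit a logistic regression by maximum likelihood
#'
#' IRLS fit of a binary outcome on a model formula, with treatment
#' (dummy) coding for every factor including ordered frequency scales.
#' Rows with a missing outcome or missing model covariates are dropped
#' (complete-case, intent-to-treat among observed); the dropped count is
#' reported. Exactly collinear columns raise an error naming the aliased
#' terms; separation and flat-likelihood (constant outcome) fits are
#' flagged via attributes rather than errors.
#'
#' @param data A data frame.
#' @param formula Model formula; the intercept is always included.
#' @return A tibble with `term`, `estimate` (log-odds), `std_error`,
#'   `statistic`, `p_value`; attributes `converged`, `separation`,
#'   `flat_likelihood`, `n`, `n_dropped`, and `fit` (the glm object).
#' @export
fit_logistic <- function(data, formula) {
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[intersect(vars, names(data))])
  dat <- data[cc, , drop = FALSE]
  fit <- withCallingHandlers(
    glm(formula, data = dat, family = binomial(),
        contrasts = treatment_contrasts(dat, all.vars(formula[[3]])),
        control = list(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) > 0) {
    abort(sprintf(
      "Collinear model columns (aliased coefficients): %s.",
      paste(aliased, collapse = ", ")
    ))
  }
  s <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s), estimate = unname(s[, 1]),
    std_error = unname(s[, 2]), statistic = unname(s[, 3]),
    p_value = unname(s[, 4])
  )
  y <- fit$y
  attr(out, "converged") <- fit$converged
  attr(out, "separation") <-
    any(fit$fitted.values < 1e-7 | fit$fitted.values > 1 - 1e-7) &&
    length(unique(y)) > 1
  attr(out, "flat_likelihood") <- length(unique(y)) < 2
  attr(out, "n") <- nrow(dat)
  attr(out, "n_dropped") <- sum(!cc)
  attr(out, "fit") <- fit
  out
}

#' Default adjustment covariate set
#'
#' The baseline controls used in the covariate-adjusted specifications:
#' marital status, driving setting, night-driving frequency and weekend
#' driving frequency. (Age and having children are excluded because of
#' strong multicollinearity with marital status.)
#'
#' @return Character vector of column names.
#' @export
default_adjustment <- function() {
  c("married", "driving_setting", "night_freq", "weekend_freq")
}

#' Estimate a pairwise arm contrast
#'
#' Point estimate of one arm-vs-arm comparison at one wave, optionally
#' restricted to a baseline-adherence subgroup and optionally adjusted
#' for baseline controls. Unadjusted estimates use the two-by-two
#' cross-product odds ratio (identical to the single-regressor logistic
#' fit); adjusted estimates exponentiate the arm coefficient of a
#' logistic fit with dummy-coded controls, dropping incomplete rows with
#' a reported count.
#'
#' @param records Assigned roster with outcomes.
#' @param exposed,reference Arm labels (`"control"`, `"fear"`, `"social"`).
#' @param wave `"baseline"`, `"wk3"` or `"wk6"`.
#' @param subgroup `"all"`, `"baseline_consistent"` or
#'   `"baseline_inconsistent"`.
#' @param adjusted Adjust for `controls`?
#' @param controls Adjustment covariates (dummy-coded in the fit).
#' @return A one-row tibble: the comparison labels plus `odds_ratio`,
#'   `log_or`, `risk_difference`, `n_exposed`, `n_reference`,
#'   `n_dropped`.
#' @export
arm_comparison <- function(records, exposed, reference, wave = "wk6",
                           subgroup = "all", adjusted = FALSE,
                           controls = default_adjustment()) {
  exposed <- match.arg(exposed, ARM_LEVELS)
  reference <- match.arg(reference, ARM_LEVELS)
  if (exposed == reference) abort("exposed and reference must differ.")
  wave <- match.arg(wave, WAVE_LEVELS)
  subgroup <- match.arg(subgroup, SUBGROUP_LEVELS)
  t <- count_two_by_two(records, exposed, reference, wave, subgroup)
  est <- odds_ratio_2x2(t)
  n_dropped <- 0L
  if (adjusted) {
    controls <- intersect(controls, names(records))
    if (length(controls) == 0) abort("No adjustment covariates present.")
    y <- wave_outcome(records, wave)
    keep <- !is.na(y) & subgroup_mask(records, subgroup) &
      as.character(records$arm) %in% c(exposed, reference)
    dat <- records[keep, , drop = FALSE]
    dat$.y <- y[keep]
    dat$.exposed <- as.integer(as.character(dat$arm) == exposed)
    # drop controls constant on this subset: they carry no information
    # and would alias the intercept
    controls <- controls[purrr::map_lgl(controls, function(v) {
      x <- dat[[v]][!is.na(dat[[v]])]
      length(unique(x)) > 1
    })]
    form <- stats::reformulate(c(".exposed", controls), response = ".y")
    coefs <- fit_logistic(dat, form)
    est$log_or <- coefs$estimate[coefs$term == ".exposed"]
    est$odds_ratio <- exp(est$log_or)
    n_dropped <- attr(coefs, "n_dropped")
  }
  tibble::tibble(
    exposed = exposed, reference = reference, wave = wave,
    subgroup = subgroup, adjusted = adjusted,
    odds_ratio = est$odds_ratio, log_or = est$log_or,
    risk_difference = est$risk_difference,
    n_exposed = est$n_exposed, n_reference = est$n_reference,
    n_dropped = n_dropped
  )
}
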