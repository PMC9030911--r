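#' Pooled baseline covariate marginals
#'
#' Default category probabilities (and age / household-size moments)
#' used by the synthetic generator: the pooled across-arm margins of the
#' study population of 391 boda drivers (e.g. district 141/178/72,
#' about 53% baseline consistent wearers, mean age 28, SD 6.3).
#'
#' @return A named list: per-variable probability vectors for
#'   categorical variables and `c(mean, sd)` for numeric ones.
#' @export
default_marginals <- function() {
  list(
    district = c(D1 = 141, D2 = 178, D3 = 72) / 391,
    education = c(elementary_or_none = 261, junior_high_or_above = 114) / 375,
    married = 252 / 381,
    has_children = 242 / 378,
    phone_self_owned = 378 / 380,
    household_size = c(mean = 5.13, sd = 2.6),
    driving_setting = c(urban = 84, suburban = 79, both = 217) / 380,
    night_freq = c(never = 112, sometimes = 129, usually = 91,
                   always = 57) / 389,
    speeding_freq = c(never = 53, sometimes = 119, usually = 199,
                      always = 19) / 390,
    weekend_freq = c(never = 19, sometimes = 90, usually = 95,
                     always = 187) / 391,
    age = c(mean = 28, sd = 6.3)
  )
}

# Per-covariate item-missingness rates matching the study's
# variable-specific denominators (e.g. age observed for 384 of 391).
default_covariate_missingness <- function() {
  c(
    district = 0, age = 7, education = 16, married = 10, has_children = 13,
    phone_self_owned = 11, household_size = 5, driving_setting = 11,
    night_freq = 2, speeding_freq = 1, weekend_freq = 0
  ) / 391
}

#' Synthetic trial configuration
#'
#' Parameters of the synthetic three-arm helmet-use trial. Defaults
#' emulate the study conditions: 391 participants, a 53% baseline
#' consistent-wearing rate, pooled covariate marginals, control-arm
#' week-6 transition probabilities of 0.36 (inconsistent becoming
#' consistent) and 2/3 (consistent staying consistent), and wave-wise
#' missingness of 0.10 (week 3) and 0.12 (week 6), reproducing the
#' 391 -> ~352 -> ~344 analyzable denominators.
#'
#' @param n_participants Roster size.
#' @param baseline_consistent_rate Probability of baseline consistent
#'   wearing.
#' @param covariate_marginals See [default_marginals()].
#' @param effects Named list of per-arm log-odds shifts applied to the
#'   week-6 adherence probability; each entry is either a scalar (both
#'   strata) or `c(consistent = , inconsistent = )`. The control arm is
#'   always 0. Example: `list(social = log(1.58))`.
#' @param control_transition `c(inconsistent = , consistent = )`:
#'   probability of being a consistent wearer at week 6 in the control
#'   arm, by baseline stratum.
#' @param attrition `c(wk3 = , wk6 = )` per-wave missingness
#'   probabilities, independent of outcome; each may instead be a
#'   length-3 vector named by arm for differential attrition.
#' @param week3_effect_fraction Fraction of the week-6 log-odds effect
#'   already present at week 3 (effects build over the 6 weeks).
#' @param covariate_link Log-odds slope linking (centered) night and
#'   speeding frequency ranks to baseline adherence; 0 (default) makes
#'   covariates independent of the outcome so the propensity score is
#'   flat, a positive value gives the propensity model real signal.
#' @param covariate_missingness Named per-covariate item-missingness
#'   probabilities.
#' @param seed Default seed used by [simulate_trial()]/[apply_effects()].
#' @return A validated list of class `trial_config`.
#' @export
trial_config <- function(n_participants = 391,
                         baseline_consistent_rate = 0.53,
                         covariate_marginals = default_marginals(),
                         effects = list(),
                         control_transition = c(inconsistent = 0.36,
                                                consistent = 2 / 3),
                         attrition = c(wk3 = 0.10, wk6 = 0.12),
                         week3_effect_fraction = 0.5,
                         covariate_link = 0,
                         covariate_missingness = default_covariate_missingness(),
                         seed = NULL) {
  check_prob <- function(x, what) {
    if (any(x < 0 | x > 1, na.rm = TRUE) || anyNA(x)) {
      abort(sprintf("Invalid probability in '%s'.", what))
    }
  }
  check_prob(baseline_consistent_rate, "baseline_consistent_rate")
  check_prob(control_transition, "control_transition")
  check_prob(unlist(attrition), "attrition")
  check_prob(covariate_missingness, "covariate_missingness")
  check_prob(week3_effect_fraction, "week3_effect_fraction")
  effects <- purrr::map(effects, function(e) {
    if (length(e) == 1 && is.null(names(e))) {
      e <- c(consistent = unname(e), inconsistent = unname(e))
    }
    if (!all(c("consistent", "inconsistent") %in% names(e)) ||
        any(!is.finite(e))) {
      abort("Each effect must be a finite scalar or a named 2-vector (consistent, inconsistent).")
    }
    e[c("consistent", "inconsistent")]
  })
  bad_arm <- setdiff(names(effects), c("fear", "social"))
  if (length(bad_arm) > 0) {
    abort(sprintf("Effects may be given for fear/social only, not: %s.",
                  paste(bad_arm, collapse = ", ")))
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      baseline_consistent_rate = baseline_consistent_rate,
      covariate_marginals = covariate_marginals,
      effects = effects,
      control_transition = control_transition,
      attrition = attrition,
      week3_effect_fraction = week3_effect_fraction,
      covariate_link = covariate_link,
      covariate_missingness = covariate_missingness,
      seed = seed
    ),
    class = "trial_config"
  )
}

freq_rank <- function(x) as.integer(x) # ordered factors: never=1 .. always=4

#' Simulate a synthetic trial roster (arms unassigned)
#'
#' Draws covariates independently from the configured marginals,
#' baseline adherence from the configured rate (optionally linked to
#' night/speeding frequency via `covariate_link`), per-covariate item
#' missingness, and per-wave attrition indicators that are independent
#' of outcomes by default. Outcomes stay `NA` until arms are assigned
#' and [apply_effects()] realizes them.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A roster tibble per [trial_schema()], plus hidden attrition
#'   columns `.u_wk3` / `.u_wk6` (uniform draws thresholded by
#'   [apply_effects()], allowing arm-dependent attrition).
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  seed <- check_seed(seed)
  n <- config$n_participants
  m <- config$covariate_marginals
  schema <- trial_schema()
  lv <- function(col) schema$levels[[match(col, schema$column)]]
  withr::with_seed(seed, {
    draw_cat <- function(col, probs, ordered = FALSE) {
      factor(sample(names(probs), n, replace = TRUE, prob = probs),
             levels = lv(col), ordered = ordered)
    }
    rec <- tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      district = draw_cat("district", m$district),
      age = pmax(18, round(rnorm(n, m$age["mean"], m$age["sd"]))),
      education = draw_cat("education", m$education),
      married = rbinom(n, 1L, m$married),
      has_children = rbinom(n, 1L, m$has_children),
      phone_self_owned = rbinom(n, 1L, m$phone_self_owned),
      household_size = pmax(1, round(rnorm(n, m$household_size["mean"],
                                           m$household_size["sd"]))),
      driving_setting = draw_cat("driving_setting", m$driving_setting),
      night_freq = draw_cat("night_freq", m$night_freq, ordered = TRUE),
      speeding_freq = draw_cat("speeding_freq", m$speeding_freq,
                               ordered = TRUE),
      weekend_freq = draw_cat("weekend_freq", m$weekend_freq, ordered = TRUE)
    )
    lp <- qlogis(config$baseline_consistent_rate)
    if (config$covariate_link != 0) {
      z <- (freq_rank(rec$night_freq) - 2.5) + (freq_rank(rec$speeding_freq) - 2.5)
      lp <- lp + config$covariate_link * z
    }
    rec$baseline_consistent <- rbinom(n, 1L, plogis(lp))
    # item missingness, applied after adherence so the link uses true values
    for (v in names(config$covariate_missingness)) {
      p_miss <- config$covariate_missingness[[v]]
      if (p_miss > 0) rec[[v]][runif(n) < p_miss] <- NA
    }
    rec$arm <- factor(NA_character_, levels = ARM_LEVELS)
    rec$outcome_wk3 <- NA_integer_
    rec$outcome_wk6 <- NA_integer_
    rec$.u_wk3 <- runif(n)
    rec$.u_wk6 <- runif(n)
    rec
  })
}

#' Realize outcomes on an assigned synthetic roster
#'
#' Week-6 adherence probability is
#' `plogis(qlogis(control_transition[stratum]) + effect[arm][stratum])`;
#' week 3 uses the configured fraction of the log-odds effect (effects
#' build over the study). Outcomes are drawn independently per wave and
#' blanked where the roster's attrition draw falls below the configured
#' per-wave (optionally per-arm) missingness probability.
#'
#' @param records Assigned roster from [simulate_trial()] +
#'   [randomize_trial()].
#' @param config The same [trial_config()].
#' @param seed Integer seed; defaults to `config$seed + 1`.
#' @return `records` with `outcome_wk3` / `outcome_wk6` realized.
#' @export
apply_effects <- function(records, config, seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (!"arm" %in% names(records) || anyNA(records$arm)) {
    abort("Arms must be assigned before applying effects.")
  }
  seed <- check_seed(seed %||% (check_seed(config$seed %||% NULL) + 1L))
  stratum <- ifelse(records$baseline_consistent == 1L,
                    "consistent", "inconsistent")
  base_lp <- qlogis(config$control_transition[stratum])
  eff <- vapply(seq_len(nrow(records)), function(i) {
    a <- as.character(records$arm[i])
    e <- config$effects[[a]]
    if (is.null(e)) 0 else unname(e[stratum[i]])
  }, numeric(1))
  miss_prob <- function(wave) {
    p <- config$attrition[[wave]]
    if (length(p) == 3) p[as.character(records$arm)] else rep(p, nrow(records))
  }
  withr::with_seed(seed, {
    p6 <- plogis(base_lp + eff)
    p3 <- plogis(base_lp + config$week3_effect_fraction * eff)
    records$outcome_wk3 <- rbinom(nrow(records), 1L, p3)
    records$outcome_wk6 <- rbinom(nrow(records), 1L, p6)
  })
  u3 <- records$.u_wk3 %||% runif(nrow(records))
  u6 <- records$.u_wk6 %||% runif(nrow(records))
  records$outcome_wk3[u3 < miss_prob("wk3")] <- NA_integer_
  records$outcome_wk6[u6 < miss_prob("wk6")] <- NA_integer_
  records
}

#' Simulate, randomize and realize one complete synthetic trial
#'
#' Convenience wrapper: [simulate_trial()], [randomize_trial()] (with an
#' intercept-only propensity model by default, since the default
#' generator draws covariates independently of adherence), then
#' [apply_effects()].
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @param covariates Propensity covariates passed to [randomize_trial()];
#'   default none (flat scores, triplets in roster order).
#' @return An assigned roster with realized outcomes.
#' @export
simulate_assigned_trial <- function(config, seed,
                                    covariates = character(0)) {
  seed <- check_seed(seed)
  roster <- simulate_trial(config, seed = seed)
  assigned <- randomize_trial(roster, covariates = covariates, seed = seed + 1L)
  apply_effects(assigned, config, seed = seed + 2L)
}
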