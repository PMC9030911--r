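#' Pearson chi-square balance test for a level-by-arm count table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column margins, no continuity correction (the convention that
#' reproduces the published balance statistics), and
#' `(rows - 1) * (cols - 1)` degrees of freedom.
#'
#' @param counts A matrix of nonnegative counts (levels x arms), or a
#'   tibble whose numeric columns are the arms (as returned by
#'   [trial_fixture()] for balance tables).
#' @param variable Optional variable label for the output row.
#' @return A one-row balance tibble: `variable`, `test = "chisq"`,
#'   `statistic`, `df`, `df2 = NA`, `p_value`, `n`.
#' @export
#' @examples
#' chisq_balance(trial_fixture("table1_weekend"), "weekend_freq")
chisq_balance <- function(counts, variable = NA_character_) {
  m <- as_count_matrix(counts)
  zero_row <- which(rowSums(m) == 0)
  zero_col <- which(colSums(m) == 0)
  if (length(zero_row) > 0 || length(zero_col) > 0) {
    abort(sprintf(
      "Degenerate margin: %s%s.",
      if (length(zero_row) > 0) {
        paste0("row(s) ", paste(rownames(m)[zero_row] %||% zero_row,
                                collapse = ", "), " sum to zero")
      } else "",
      if (length(zero_col) > 0) {
        paste0("column(s) ", paste(colnames(m)[zero_col] %||% zero_col,
                                   collapse = ", "), " sum to zero")
      } else ""
    ))
  }
  t <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(
    variable = variable, test = "chisq",
    statistic = as.numeric(t$statistic), df = as.numeric(t$parameter),
    df2 = NA_real_, p_value = as.numeric(t$p.value), n = sum(m)
  )
}

as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (is.data.frame(counts)) {
    num <- counts[purrr::map_lgl(counts, is.numeric)]
    lab <- counts[purrr::map_lgl(counts, is.character)]
    m <- as.matrix(num)
    if (ncol(lab) > 0) rownames(m) <- lab[[1]]
    return(m)
  }
  abort("counts must be a matrix or a data frame of counts.")
}

#' One-way analysis of variance across arms
#'
#' Classic one-way ANOVA for a continuous baseline variable: F is the
#' between-group mean square over the within-group mean square, with a
#' p-value from the F distribution. Used for age and household size,
#' where a count table would discard information.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (arm labels) of the same length;
#'   missing values in either are dropped pairwise.
#' @param variable Optional variable label.
#' @return A one-row balance tibble: `variable`, `test = "anova"`,
#'   `statistic` (F), `df` (between), `df2` (within), `p_value`, `n`.
#'   Zero within-group variance yields an infinite F, flagged by the
#'   value itself rather than an error.
#' @export
anova_oneway <- function(values, groups, variable = NA_character_) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) abort("At least two groups are required.")
  if (any(table(groups) < 2)) abort("Each group needs at least 2 observations.")
  a <- withCallingHandlers(
    anova(lm(values ~ groups)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  f <- a$`F value`[1]
  p <- a$`Pr(>F)`[1]
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0) && any(tapply(values, groups, mean) !=
                                  mean(values))) {
    f <- Inf # zero within-group variance with distinct means
    p <- 0
  }
  tibble::tibble(
    variable = variable, test = "anova",
    statistic = f, df = a$Df[1], df2 = a$Df[2],
    p_value = p, n = length(values)
  )
}

#' Baseline balance table across arms
#'
#' One diagnostic row per baseline variable present in the roster:
#' chi-square tests for categorical and binary variables, one-way ANOVA
#' for age and household size. Each row uses that variable's complete
#' cases (the per-variable `n` is reported), so denominators vary across
#' rows exactly as item missingness dictates.
#'
#' @param records Assigned roster (at least two arms present).
#' @return A tibble of balance rows (`variable`, `test`, `statistic`,
#'   `df`, `df2`, `p_value`, `n`).
#' @export
balance_table <- function(records) {
  if (!"arm" %in% names(records) || all(is.na(records$arm))) {
    abort("Arms must be assigned before checking balance.")
  }
  arms <- droplevels(factor(records$arm))
  if (nlevels(arms) < 2) {
    abort("At least two arms are required for a balance contrast.")
  }
  numeric_vars <- c("age", "household_size")
  cat_vars <- setdiff(
    intersect(c(default_covariates(), "phone_self_owned",
                "baseline_consistent"), names(records)),
    numeric_vars
  )
  rows <- purrr::map(cat_vars, function(v) {
    x <- records[[v]]
    keep <- !is.na(x) & !is.na(arms)
    m <- table(factor(x[keep]), arms[keep])
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) < 2) return(NULL) # constant variable: no contrast
    chisq_balance(unclass(m), variable = v)
  })
  num_rows <- purrr::map(intersect(numeric_vars, names(records)), function(v) {
    anova_oneway(records[[v]], arms, variable = v)
  })
  dplyr::bind_rows(purrr::compact(c(rows, num_rows)))
}
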