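#' Trial roster schema
#'
#' Column names, types and categorical levels for a participant roster:
#' one row per driver, with baseline covariates, the baseline helmet-use
#' stratum, the assigned arm (once randomized) and the week-3 / week-6
#' binary outcomes. Missing values are encoded as empty CSV cells; any
#' sentinel string is rejected as a malformed level.
#'
#' @return A tibble with one row per schema column: `column`, `type`
#'   (`"id"`, `"category"`, `"ordered"`, `"binary"`, `"count"`) and
#'   `levels` (list-column of allowed labels, `NULL` for non-categorical).
#' @export
#' @examples
#' trial_schema()
trial_schema <- function() {
  tibble::tribble(
    ~column,               ~type,      ~levels,
    "id",                  "id",       NULL,
    "district",            "category", c("D1", "D2", "D3"),
    "age",                 "count",    NULL,
    "education",           "category", c("elementary_or_none", "junior_high_or_above"),
    "married",             "binary",   NULL,
    "has_children",        "binary",   NULL,
    "phone_self_owned",    "binary",   NULL,
    "household_size",      "count",    NULL,
    "driving_setting",     "category", c("urban", "suburban", "both"),
    "night_freq",          "ordered",  c("never", "sometimes", "usually", "always"),
    "speeding_freq",       "ordered",  c("never", "sometimes", "usually", "always"),
    "weekend_freq",        "ordered",  c("never", "sometimes", "usually", "always"),
    "baseline_consistent", "binary",   NULL,
    "arm",                 "category", ARM_LEVELS,
    "outcome_wk3",         "binary",   NULL,
    "outcome_wk6",         "binary",   NULL
  )
}

# Default propensity covariate set: every baseline variable except the
# outcome-defining adherence indicator.
default_covariates <- function() {
  c(
    "district", "age", "education", "married", "has_children",
    "household_size", "driving_setting", "night_freq", "speeding_freq",
    "weekend_freq"
  )
}

# Coerce one raw character column to its schema type, with row/column
# labelled errors on malformed categorical labels or non-numeric cells.
coerce_column <- function(x, column, type, levels) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad_row <- function(bad) {
    abort(sprintf(
      "Malformed value %s in column '%s' (row %d); allowed: %s.",
      dQuote(x[bad][1], q = FALSE), column, bad[1],
      paste(levels %||% "numeric", collapse = ", ")
    ))
  }
  switch(type,
    id = x,
    category = {
      bad <- which(!is.na(x) & !x %in% levels)
      if (length(bad) > 0) bad_row(bad)
      factor(x, levels = levels)
    },
    ordered = {
      bad <- which(!is.na(x) & !x %in% levels)
      if (length(bad) > 0) bad_row(bad)
      factor(x, levels = levels, ordered = TRUE)
    },
    binary = {
      bad <- which(!is.na(x) & !x %in% c("0", "1"))
      if (length(bad) > 0) {
        levels <- c("0", "1")
        bad_row(bad)
      }
      as.integer(x)
    },
    count = {
      suppress <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(suppress))
      if (length(bad) > 0) {
        levels <- NULL
        bad_row(bad)
      }
      suppress
    }
  )
}

#' Read a participant roster from CSV
#'
#' Reads a comma-delimited, UTF-8 roster matching [trial_schema()]:
#' one row per participant, empty cells for missing values. Unknown
#' columns are dropped with a warning; `baseline_consistent` must be
#' present and complete because it defines the randomization strata.
#' Input row order is preserved exactly (triplet formation depends on it).
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble of participant records, one per input row, with
#'   schema-typed columns (factors for categories, integer 0/1 for
#'   binary fields, `NA` for missing cells).
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  schema <- trial_schema()
  unknown <- setdiff(names(raw), schema$column)
  if (length(unknown) > 0) {
    warn(sprintf(
      "Ignoring unknown column(s): %s.", paste(unknown, collapse = ", ")
    ))
    raw <- raw[setdiff(names(raw), unknown)]
  }
  if (!"baseline_consistent" %in% names(raw)) {
    abort("Column 'baseline_consistent' is required: it defines the strata.")
  }
  out <- purrr::pmap(schema, function(column, type, levels) {
    if (!column %in% names(raw)) return(NULL)
    coerce_column(raw[[column]], column, type, levels)
  })
  names(out) <- schema$column
  out <- tibble::as_tibble(out[!purrr::map_lgl(out, is.null)])
  if (anyNA(out$baseline_consistent)) {
    abort(sprintf(
      "baseline_consistent is missing in row(s) %s; it must be complete.",
      paste(head(which(is.na(out$baseline_consistent)), 5), collapse = ", ")
    ))
  }
  out
}

#' Write a participant roster to CSV
#'
#' Inverse of [read_trial_csv()]: writes schema columns as labels with
#' empty cells for missing values, so that write-then-read is the
#' identity on every field including missingness.
#'
#' @param records A roster tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(records, path) {
  keep <- intersect(trial_schema()$column, names(records))
  out <- dplyr::mutate(
    records[keep],
    dplyr::across(dplyr::where(is.factor), as.character)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Two-by-two table odds-ratio input
#'
#' Bundles the four cells of an exposed-vs-reference two-by-two table:
#' `a` exposed events, `b` exposed non-events, `c` reference events,
#' `d` reference non-events. The odds ratio `(a d)/(b c)` is finite iff
#' `b * c > 0`.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' two_by_two(74, 42, 58, 52)
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || anyNA(cells)) {
    abort("All two-by-two cells must be nonnegative and non-missing.")
  }
  tibble::tibble(a = a, b = b, c = c, d = d)
}

# Count a 2x2 (events/non-events by exposed/reference arm) from a roster
# for one wave and subgroup, among participants with an observed outcome.
count_two_by_two <- function(records, exposed, reference,
                             wave = "wk6", subgroup = "all") {
  y <- wave_outcome(records, wave)
  keep <- !is.na(y) & subgroup_mask(records, subgroup)
  arm <- as.character(records$arm)
  two_by_two(
    a = sum(keep & arm == exposed & y == 1L),
    b = sum(keep & arm == exposed & y == 0L),
    c = sum(keep & arm == reference & y == 1L),
    d = sum(keep & arm == reference & y == 0L)
  )
}

wave_outcome <- function(records, wave) {
  wave <- match.arg(wave, WAVE_LEVELS)
  switch(wave,
    baseline = records$baseline_consistent,
    wk3 = records$outcome_wk3,
    wk6 = records$outcome_wk6
  )
}

subgroup_mask <- function(records, subgroup) {
  subgroup <- match.arg(subgroup, SUBGROUP_LEVELS)
  switch(subgroup,
    all = rep(TRUE, nrow(records)),
    baseline_consistent = records$baseline_consistent == 1L,
    baseline_inconsistent = records$baseline_consistent == 0L
  )
}
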