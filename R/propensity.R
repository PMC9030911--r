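#' Fit the baseline helmet-use propensity model
#'
#' Logistic regression of baseline consistent helmet use on demographic
#' and driving-habit covariates, fitted by iteratively reweighted least
#' squares (tolerance 1e-8, at most 50 iterations). The fitted
#' probability is the propensity score used to order participants before
#' triplet matching. Covariates missing at fit time are imputed with the
#' full-sample mode (categorical) or median (numeric); the imputation
#' values are stored so that scoring never fails on incomplete records.
#'
#' @param records Roster tibble (see [trial_schema()]).
#' @param covariates Character vector of covariate columns; defaults to
#'   every baseline variable except the adherence indicator itself. An
#'   empty vector fits an intercept-only model (every score equals the
#'   sample adherence rate).
#' @return An object of class `propensity_model`: the glm fit plus the
#'   covariate list, imputation values, a convergence flag and a
#'   complete-separation flag (scores pinned toward 0/1).
#' @seealso [add_propensity()], [randomize_trial()]
#' @export
fit_propensity <- function(records, covariates = default_covariates()) {
  covariates <- intersect(covariates, names(records))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0) {
    abort(sprintf("Covariates not in roster: %s.",
                  paste(missing_cov, collapse = ", ")))
  }
  if (anyNA(records$baseline_consistent)) {
    abort("baseline_consistent must be complete to fit the propensity model.")
  }
  impute_values <- purrr::map(
    setNames(covariates, covariates),
    function(v) impute_value(records[[v]])
  )
  dat <- impute_columns(records, impute_values)
  form <- if (length(covariates) == 0) {
    baseline_consistent ~ 1
  } else {
    stats::reformulate(covariates, response = "baseline_consistent")
  }
  fit <- withCallingHandlers(
    glm(form, data = dat, family = binomial(),
        contrasts = treatment_contrasts(dat, covariates),
        control = list(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  separation <- any(fit$fitted.values < 1e-7 | fit$fitted.values > 1 - 1e-7)
  if (!fit$converged) {
    warn("Propensity model did not converge within 50 IRLS iterations.")
  }
  if (separation) inform("Propensity model shows (quasi-)complete separation.")
  structure(
    list(
      fit = fit, covariates = covariates, impute_values = impute_values,
      converged = fit$converged, separation = separation
    ),
    class = "propensity_model"
  )
}

impute_value <- function(x) {
  if (is.factor(x)) {
    tab <- table(x)
    names(tab)[which.max(tab)] # mode; ties broken by level order
  } else {
    median(x, na.rm = TRUE)
  }
}

impute_columns <- function(records, impute_values) {
  for (v in names(impute_values)) {
    x <- records[[v]]
    if (anyNA(x)) {
      if (is.factor(x)) {
        x[is.na(x)] <- impute_values[[v]]
      } else {
        x[is.na(x)] <- as.numeric(impute_values[[v]])
      }
      records[[v]] <- x
    }
  }
  records
}

# Treatment (dummy) contrasts for every factor among `vars`, including
# ordered factors (whose R default would be polynomial contrasts).
treatment_contrasts <- function(data, vars) {
  fac <- vars[purrr::map_lgl(vars, function(v) is.factor(data[[v]]))]
  if (length(fac) == 0) return(NULL)
  setNames(replicate(length(fac), "contr.treatment", simplify = FALSE), fac)
}

#' @export
predict.propensity_model <- function(object, newdata, ...) {
  dat <- impute_columns(newdata, object$impute_values)
  as.numeric(predict(object$fit, newdata = dat, type = "response"))
}

#' Attach propensity scores to a roster
#'
#' Scores every record with a fitted [fit_propensity()] model (imputing
#' missing covariates with the stored full-sample values) and adds the
#' result as a `.propensity` column. Row order is preserved.
#'
#' @param records Roster tibble.
#' @param model A `propensity_model`.
#' @return `records` with a `.propensity` column in `(0, 1)`.
#' @export
add_propensity <- function(records, model) {
  stopifnot(inherits(model, "propensity_model"))
  dplyr::mutate(records, .propensity = predict(model, records))
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf(
    "<propensity_model> %d covariate(s), %sconverged%s\n",
    length(x$covariates), if (x$converged) "" else "NOT ",
    if (x$separation) ", separation flagged" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.propensity_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @exportS3Method generics::glance
glance.propensity_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$fit$y), n_covariates = length(x$covariates),
    deviance = x$fit$deviance, aic = x$fit$aic,
    converged = x$converged, separation = x$separation
  )
}
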