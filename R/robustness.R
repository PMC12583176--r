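#' Robustness / mechanism scenario
#'
#' A named re-estimation recipe: drop donor units (directly or through a
#' unit-to-group lookup, e.g. province membership), truncate the sample at
#' an end year, and/or swap the outcome for a mediator variable with an
#' expected effect direction (mechanism analysis).
#'
#' @param name scenario label.
#' @param drop_units character vector of donor units to exclude.
#' @param drop_groups character vector of group names to exclude via
#'   `lookup`.
#' @param lookup optional data.frame `unit, group` (or a path to such a
#'   CSV) mapping units to groups.
#' @param end_year sample truncation year or `NULL`.
#' @param outcome_variable outcome for this scenario (`NULL` keeps the
#'   panel's outcome; a mediator name runs a mechanism analysis).
#' @param expected_sign `"negative"`, `"positive"` or `"none"`; used by
#'   [direction_check()].
#' @return a list of class `scm_scenario`.
#' @export
scenario <- function(name, drop_units = character(0),
                     drop_groups = character(0), lookup = NULL,
                     end_year = NULL, outcome_variable = NULL,
                     expected_sign = c("none", "negative", "positive")) {
  expected_sign <- match.arg(expected_sign)
  if (length(drop_groups)) {
    if (is.character(lookup))
      lookup <- utils::read.csv(lookup, stringsAsFactors = FALSE)
    if (is.null(lookup) || !all(c("unit", "group") %in% names(lookup)))
      stopf("drop_groups needs a lookup with 'unit' and 'group' columns")
    drop_units <- union(drop_units,
                        lookup$unit[lookup$group %in% drop_groups])
  }
  structure(list(name = name, drop_units = as.character(drop_units),
                 end_year = end_year, outcome_variable = outcome_variable,
                 expected_sign = expected_sign), class = "scm_scenario")
}

#' Run one robustness or mechanism scenario
#'
#' Subsets the panel per the scenario, swaps the outcome if a mediator
#' scenario, imputes the (possibly gappy) mediator by [impute_linear()]
#' first, refits the synthetic control and tags the fit with the scenario.
#'
#' @param panel an `scm_panel`.
#' @param spec a [predictor_spec()]; lag-year predictors refer to the
#'   scenario's outcome.
#' @param scn an [scenario()].
#' @param v_method,control forwarded to [synth_control()].
#' @return a `synth_control` fit with a `scenario` component.
#' @export
run_scenario <- function(panel, spec = NULL, scn,
                         v_method = "nested", control = scm_control()) {
  stopifnot(inherits(scn, "scm_scenario"))
  pp <- subset_panel(panel, drop_units = scn$drop_units,
                     end_year = scn$end_year)
  if (length(setdiff(pp$units, pp$treated_unit)) < 2L)
    stopf("scenario '%s' leaves fewer than 2 donors", scn$name)
  if (!is.null(scn$outcome_variable) &&
      !identical(scn$outcome_variable, pp$outcome)) {
    if (!scn$outcome_variable %in% names(pp$values))
      stopf("scenario outcome '%s' not in panel", scn$outcome_variable)
    if (anyNA(pp$values[[scn$outcome_variable]]))
      pp <- impute_linear(pp, scn$outcome_variable)
    pp <- set_outcome(pp, scn$outcome_variable)
  }
  fit <- synth_control(pp, spec, v_method = v_method, control = control)
  fit$scenario <- scn
  fit
}

#' Compare scenario fits against a baseline
#'
#' @param fits list of `synth_control` fits (the first is the baseline
#'   unless `baseline` is given separately).
#' @param baseline optional baseline fit.
#' @return data.frame `scenario, mean_post_effect, pre_rmspe, n_donors,
#'   delta_vs_baseline`.
#' @export
compare_scenarios <- function(fits, baseline = NULL) {
  if (inherits(fits, "synth_control")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  if (is.null(baseline)) baseline <- fits[[1]]
  rows <- lapply(fits, function(f) {
    data.frame(
      scenario = if (!is.null(f$scenario)) f$scenario$name else "baseline",
      mean_post_effect = f$mean_post_effect,
      pre_rmspe = f$pre_rmspe,
      n_donors = length(f$donors),
      delta_vs_baseline = f$mean_post_effect - baseline$mean_post_effect,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check the direction of a mechanism effect
#'
#' Passes when the sign of the mean post-treatment gap matches the expected
#' direction; also reports the share of post years whose gap has the
#' expected sign.
#'
#' @param fit a `synth_control` fit.
#' @param expected_sign `"negative"` or `"positive"`.
#' @return list `pass`, `mean_post_effect`, `fraction_matching`.
#' @export
direction_check <- function(fit, expected_sign = c("negative", "positive")) {
  expected_sign <- match.arg(expected_sign)
  stopifnot(inherits(fit, "synth_control"))
  sgn <- if (expected_sign == "positive") 1 else -1
  post <- fit$years >= fit$treatment_year
  gaps <- fit$gap_path[post]
  list(pass = sign(fit$mean_post_effect) == sgn,
       mean_post_effect = fit$mean_post_effect,
       fraction_matching = mean(sign(gaps) == sgn))
}
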