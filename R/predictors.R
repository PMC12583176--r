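#' Predictor specification for synthetic control fitting
#'
#' Predictors are (a) covariates aggregated by their pre-treatment mean and
#' (b) individual lag years of the outcome. The canonical specification in
#' the Sanming evaluation uses five covariates (secondary and tertiary
#' industry shares, GDP, GDP growth rate, registered population) plus the
#' outcome at 2007, 2008, 2009 and 2010 as four separate lag predictors,
#' nine rows in total.
#'
#' @param covariates character vector of covariate names (possibly empty).
#' @param lag_years integer years of the outcome to use as individual
#'   predictors; `NULL` means all pre-treatment years. Must lie inside the
#'   pre-treatment period.
#' @return an object of class `predictor_spec`.
#' @export
predictor_spec <- function(covariates = character(0), lag_years = NULL) {
  structure(list(covariates = as.character(covariates),
                 lag_years = if (!is.null(lag_years))
                   sort(as.integer(lag_years))),
            class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat("Predictor specification\n")
  cat("  covariates:", if (length(x$covariates))
    paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  outcome lags:", if (is.null(x$lag_years)) "all pre-treatment years"
      else paste(x$lag_years, collapse = ", "), "\n")
  invisible(x)
}

# resolve the lag years for a concrete panel / fake treatment year
resolve_spec <- function(spec, panel, treatment_year = panel$treatment_year,
                         quiet = FALSE) {
  pre <- panel$years[panel$years < treatment_year]
  lags <- spec$lag_years %||% pre
  dropped <- lags[!lags %in% pre]
  if (length(dropped)) {
    if (!quiet)
      message("dropping lag predictor(s) at/after the treatment year: ",
              paste(dropped, collapse = ", "))
    lags <- lags[lags %in% pre]
  }
  if (length(spec$covariates) + length(lags) == 0L)
    stopf("predictor specification resolves to zero predictors")
  missing_cov <- setdiff(spec$covariates, names(panel$values))
  if (length(missing_cov))
    stopf("covariate(s) not in panel: %s", paste(missing_cov, collapse = ", "))
  list(covariates = spec$covariates, lag_years = lags, pre_years = pre)
}

#' Build treated and donor predictor matrices
#'
#' Assembles the k-vector `X1` (treated) and k x J matrix `X0` (donors):
#' covariate pre-treatment means first, then the outcome at each lag year.
#' Each predictor row is standardized to mean 0, variance 1 across the
#' treated unit and all donors, so the importance weights V are not
#' unit-dependent; the centering and scaling are recorded and the raw values
#' kept so balance tables report original units.
#'
#' @param panel an `scm_panel` with a designated outcome.
#' @param spec a [predictor_spec()].
#' @param treatment_year treatment year to build against (defaults to the
#'   panel's; in-time placebos pass an earlier one).
#' @return list with `X1`, `X0` (standardized), `X1_raw`, `X0_raw`, predictor
#'   `names`, `center`, `scale`, `donors`, and the resolved `lag_years` /
#'   `pre_years`.
#' @export
build_predictors <- function(panel, spec,
                             treatment_year = panel$treatment_year) {
  if (is.na(panel$outcome))
    stopf("panel has no outcome variable; assign one first")
  rs <- resolve_spec(spec, panel, treatment_year)
  donors <- setdiff(panel$units, panel$treated_unit)
  if (length(donors) < 2L)
    stopf("need at least 2 donor units, got %d", length(donors))
  pre_chr <- as.character(rs$pre_years)

  rows <- list()
  for (v in rs$covariates) {
    m <- panel_matrix(panel, v)
    if (anyNA(m[, pre_chr]))
      stopf("covariate '%s' has missing pre-treatment values; impute first", v)
    rows[[v]] <- rowMeans(m[, pre_chr, drop = FALSE])
  }
  ym <- panel_matrix(panel, panel$outcome)
  for (yr in rs$lag_years) {
    nm <- sprintf("%s(%d)", panel$outcome, yr)
    if (anyNA(ym[, as.character(yr)]))
      stopf("outcome has missing values in lag year %d", yr)
    rows[[nm]] <- ym[, as.character(yr)]
  }

  Xall <- do.call(rbind, rows)           # k x (all units)
  Xall <- Xall[, c(panel$treated_unit, donors), drop = FALSE]
  ctr <- rowMeans(Xall)
  scl <- apply(Xall, 1, stats::sd)
  zero <- which(scl == 0)
  if (length(zero))
    stopf("predictor(s) with zero variance across units: %s",
          paste(rownames(Xall)[zero], collapse = ", "))
  Xstd <- (Xall - ctr) / scl

  list(X1 = Xstd[, 1], X0 = Xstd[, -1, drop = FALSE],
       X1_raw = Xall[, 1], X0_raw = Xall[, -1, drop = FALSE],
       names = rownames(Xall), center = ctr, scale = scl,
       donors = donors, lag_years = rs$lag_years, pre_years = rs$pre_years)
}
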