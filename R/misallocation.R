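#' Medical-resource misallocation index
#'
#' The dependent variable of the evaluation: for each city and year, the
#' absolute relative deviation of the city's total (normalized) medical
#' resources from the yearly national average,
#' \deqn{M_{it} = | R_{it} - \bar R_t | / \bar R_t,}
#' where \eqn{R_{it}} is the sum of the city's three normalized resource
#' components (hospitals and health centers, hospital beds, physicians) and
#' \eqn{\bar R_t} is the unweighted mean of \eqn{R_{it}} over all cities in
#' year \eqn{t}. The index is 0 exactly when a city sits at the national
#' average and grows with deviation in either direction.
#'
#' Components are rescaled within each year across cities before summing.
#' Two schemes are provided: `"minmax"` maps each component to \[0, 1\]
#' (default), `"mean_ratio"` divides by the component's yearly mean. Both are
#' invariant to uniform positive rescaling of any single component, so the
#' index does not depend on measurement units.
#'
#' @name misallocation
NULL

.resource_components <- c("hospitals_health_centers", "beds", "physicians")

#' Read a raw resource table
#'
#' Long-format CSV with columns `unit, year, hospitals_health_centers, beds,
#' physicians[, population]`; balanced over units x years, all counts >= 0.
#'
#' @param path CSV file.
#' @return a data.frame with validated columns.
#' @export
read_resources <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_resources(raw)
}

validate_resources <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("unit", "year", .resource_components)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("resource table missing column(s): %s", paste(miss, collapse = ", "))
  df$unit <- as.character(df$unit)
  df$year <- .check_integerish(df$year, "year")
  for (v in intersect(c(.resource_components, "population"), names(df))) {
    df[[v]] <- .check_numeric(df[[v]], v)
    if (any(df[[v]] < 0, na.rm = TRUE))
      stopf("negative values in resource column '%s'", v)
  }
  key <- paste(df$unit, df$year)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stopf("duplicate resource row for unit '%s', year %d", d$unit, d$year)
  }
  tab <- table(df$unit)
  if (length(unique(tab)) != 1L ||
      length(unique(df$year)) * length(unique(df$unit)) != nrow(df))
    stopf("resource table is not balanced over units x years")
  df
}

#' Normalize resource components within years
#'
#' @param resources data.frame as from [read_resources()].
#' @param method `"minmax"` (rescale to \[0,1\] across cities within a year)
#'   or `"mean_ratio"` (divide by the yearly cross-city mean).
#' @return the data.frame with the three component columns replaced by their
#'   normalized values.
#' @export
normalize_components <- function(resources,
                                 method = c("minmax", "mean_ratio")) {
  method <- match.arg(method)
  resources <- validate_resources(resources)
  years <- unique(resources$year)
  for (y in years) {
    idx <- resources$year == y
    if (sum(idx) < 2L)
      stopf("need >= 2 units per year; year %d has %d", y, sum(idx))
    for (v in .resource_components) {
      x <- resources[[v]][idx]
      if (method == "minmax") {
        rng <- range(x)
        if (rng[1] == rng[2])
          stopf("component '%s' constant across units in year %d; %s", v, y,
                "min-max normalization undefined")
        resources[[v]][idx] <- (x - rng[1]) / (rng[2] - rng[1])
      } else {
        mu <- mean(x)
        if (mu == 0)
          stopf("component '%s' has zero mean in year %d; %s", v, y,
                "mean-ratio normalization undefined")
        resources[[v]][idx] <- x / mu
      }
    }
  }
  resources
}

#' Compute the misallocation index from raw counts
#'
#' Applies the three-step construction: normalize components within years,
#' sum them into a city's total resources (optionally per capita), take the
#' yearly unweighted national mean of the totals, and report each city's
#' absolute relative deviation from it.
#'
#' @inheritParams normalize_components
#' @param per_capita divide each component by `population` before
#'   normalizing; requires a positive `population` column. Off by default
#'   (the index is defined on counts).
#' @return a data.frame `unit, year, total_resources, national_mean,
#'   misallocation`.
#' @export
compute_misallocation <- function(resources,
                                  method = c("minmax", "mean_ratio"),
                                  per_capita = FALSE) {
  method <- match.arg(method)
  resources <- validate_resources(resources)
  if (per_capita) {
    if (is.null(resources$population))
      stopf("per_capita = TRUE requires a 'population' column")
    if (any(resources$population <= 0))
      stopf("per_capita = TRUE requires population > 0")
    for (v in .resource_components)
      resources[[v]] <- resources[[v]] / resources$population
  }
  norm <- normalize_components(resources, method)
  total <- rowSums(as.matrix(norm[.resource_components]))
  out <- data.frame(unit = norm$unit, year = norm$year,
                    total_resources = total, stringsAsFactors = FALSE)
  nm <- tapply(out$total_resources, out$year, mean)
  out$national_mean <- as.numeric(nm[as.character(out$year)])
  if (any(out$national_mean == 0))
    stopf("national mean of totals is 0 in year(s): %s",
          paste(unique(out$year[out$national_mean == 0]), collapse = ", "))
  out$misallocation <- abs(out$total_resources - out$national_mean) /
    out$national_mean
  out[order(out$unit, out$year), , drop = FALSE]
}

#' Inject a misallocation series into a panel as its outcome
#'
#' @param panel an `scm_panel`.
#' @param series data.frame from [compute_misallocation()].
#' @param name variable name for the outcome column.
#' @return a new `scm_panel` with the outcome variable set.
#' @export
add_misallocation_outcome <- function(panel, series, name = "misallocation") {
  m <- matrix(NA_real_, length(panel$units), length(panel$years),
              dimnames = list(panel$units, as.character(panel$years)))
  idx <- series$unit %in% panel$units & series$year %in% panel$years
  sub <- series[idx, , drop = FALSE]
  m[cbind(match(sub$unit, panel$units), match(sub$year, panel$years))] <-
    sub$misallocation
  if (anyNA(m))
    stopf("misallocation series does not cover the full panel grid")
  set_variable(panel, name, m, role = "outcome")
}
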