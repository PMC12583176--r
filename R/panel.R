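#' Balanced city-year panel container
#'
#' `panel_data()` builds the validated balanced-panel object used throughout
#' the package. Data may be supplied wide (one column per variable) or long
#' (`unit, year, variable, value`); internally each variable is held as a
#' units-by-years matrix. Every (unit, year) pair must be present for every
#' variable: absent rows are a structural error, while `NA` values in present
#' rows are recorded as missing cells (to be imputed with
#' [impute_linear()]).
#'
#' @param data a data.frame, wide (`unit`, `year`, variable columns) or long
#'   (`unit`, `year`, `variable`, `value`).
#' @param treated_unit identifier of the treated unit; must appear in `unit`.
#' @param treatment_year first year of the intervention `T0`; must satisfy
#'   `min(years) < T0 <= max(years)`.
#' @param roles named character vector mapping each variable to one of
#'   `"outcome"`, `"component"`, `"covariate"`, `"mediator"`. Exactly one
#'   variable may carry the `"outcome"` role.
#' @return an object of class `scm_panel` with fields `units`, `years`,
#'   `values` (named list of unit x year matrices), `roles`, `treated_unit`,
#'   `treatment_year`, `outcome`.
#' @seealso [read_panel()], [impute_linear()], [subset_panel()]
#' @export
panel_data <- function(data, treated_unit, treatment_year, roles) {
  stopifnot(is.data.frame(data))
  names(data) <- tolower(names(data))
  if (!all(c("unit", "year") %in% names(data)))
    stopf("panel data must have 'unit' and 'year' columns")
  data$unit <- as.character(data$unit)
  data$year <- .check_integerish(data$year, "year")

  long <- if (all(c("variable", "value") %in% names(data))) {
    data.frame(unit = data$unit, year = data$year,
               variable = as.character(data$variable),
               value = .check_numeric(data$value, "value"),
               stringsAsFactors = FALSE)
  } else {
    .wide_to_long(data)
  }

  vars <- unique(long$variable)
  if (length(vars) == 0L) stopf("panel contains no value columns")
  if (missing(roles) || is.null(roles)) stopf("'roles' is required")
  roles <- unlist(roles)
  bad <- setdiff(vars, names(roles))
  if (length(bad))
    stopf("no role assigned for variable(s): %s", paste(bad, collapse = ", "))
  roles <- roles[vars]
  ok_roles <- c("outcome", "component", "covariate", "mediator")
  if (!all(roles %in% ok_roles))
    stopf("roles must be one of: %s", paste(ok_roles, collapse = ", "))
  if (sum(roles == "outcome") > 1L)
    stopf("more than one variable tagged as outcome")

  units <- unique(long$unit)
  years <- sort(unique(long$year))
  if (any(diff(years) != 1L))
    stopf("years must be contiguous with step 1; got gaps at %s",
          paste(years[which(diff(years) != 1L)], collapse = ", "))

  # duplicates: same (unit, year, variable) more than once
  key <- paste(long$unit, long$year, long$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicate row for unit '%s', year %d (variable '%s')",
          d$unit, d$year, d$variable)
  }

  # balance: every unit x year present for every variable
  values <- list()
  for (v in vars) {
    sub <- long[long$variable == v, , drop = FALSE]
    m <- matrix(NA_real_, length(units), length(years),
                dimnames = list(units, as.character(years)))
    m[cbind(match(sub$unit, units), match(sub$year, years))] <- sub$value
    present <- matrix(FALSE, length(units), length(years))
    present[cbind(match(sub$unit, units), match(sub$year, years))] <- TRUE
    if (!all(present)) {
      miss <- which(!present, arr.ind = TRUE)
      pairs <- paste0("(", units[miss[, 1]], ", ", years[miss[, 2]], ")")
      stopf("unbalanced panel: variable '%s' missing rows for %s", v,
            paste(utils::head(pairs, 10L), collapse = ", "))
    }
    values[[v]] <- m
  }

  treated_unit <- as.character(treated_unit)
  if (!treated_unit %in% units)
    stopf("treated unit '%s' not found in panel", treated_unit)
  treatment_year <- .check_integerish(treatment_year, "treatment_year")
  if (!(min(years) < treatment_year && treatment_year <= max(years)))
    stopf("treatment_year %d must satisfy min(years) < T0 <= max(years)",
          treatment_year)

  structure(list(units = units, years = years, values = values,
                 roles = roles, treated_unit = treated_unit,
                 treatment_year = treatment_year,
                 outcome = names(roles)[roles == "outcome"][1] %||% NA_character_),
            class = "scm_panel")
}

.wide_to_long <- function(data) {
  vcols <- setdiff(names(data), c("unit", "year"))
  out <- lapply(vcols, function(v)
    data.frame(unit = data$unit, year = data$year, variable = v,
               value = .check_numeric(data[[v]], v), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.check_numeric <- function(x, what) {
  if (is.numeric(x)) return(as.numeric(x))
  xc <- trimws(as.character(x))
  xc[xc %in% c("", "NA")] <- NA
  conv <- suppressWarnings(as.numeric(xc))
  bad <- which(!is.na(xc) & is.na(conv))
  if (length(bad))
    stopf("non-numeric value in column '%s' at row %d: '%s'",
          what, bad[1], xc[bad[1]])
  conv
}

.check_integerish <- function(x, what) {
  x <- .check_numeric(x, what)
  if (any(!is.na(x) & x != round(x)))
    stopf("column '%s' must be integer-valued", what)
  as.integer(x)
}

#' Read a balanced panel from delimited text
#'
#' Reads a CSV (wide or long layout) plus a schema that assigns each value
#' column a role and names the treated unit and treatment year. The schema
#' may be a list or a path to a YAML/JSON file with fields `roles`
#' (mapping variable -> role), `treated_unit` and `treatment_year`.
#'
#' @param path CSV file; UTF-8, "." decimal, header required.
#' @param schema list or path to a YAML/JSON schema file.
#' @return an [panel_data()] object.
#' @export
read_panel <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE))
      jsonlite::read_json(schema, simplifyVector = TRUE)
    else yaml::read_yaml(schema)
  }
  stopifnot(is.list(schema))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  panel_data(raw,
             treated_unit = schema$treated_unit,
             treatment_year = schema$treatment_year,
             roles = schema$roles)
}

#' Write a panel as long-format CSV
#'
#' All writers in the package emit this dialect: columns
#' `unit, year, variable, value`, "." decimal, UTF-8.
#'
#' @param panel an `scm_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @export
as.data.frame.scm_panel <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$values), function(v) {
    m <- x$values[[v]]
    data.frame(unit = rep(rownames(m), times = ncol(m)),
               year = rep(x$years, each = nrow(m)),
               variable = v, value = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$variable, names(x$values)), out$unit, out$year),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.scm_panel <- function(x, ...) {
  cat(sprintf("Balanced panel: %d units x %d years (%d-%d)\n",
              length(x$units), length(x$years), min(x$years), max(x$years)))
  cat(sprintf("Treated unit: %s, treatment year: %d\n",
              x$treated_unit, x$treatment_year))
  for (r in unique(x$roles))
    cat(sprintf("  %-9s %s\n", paste0(r, ":"),
                paste(names(x$roles)[x$roles == r], collapse = ", ")))
  n_na <- sum(vapply(x$values, function(m) sum(is.na(m)), numeric(1)))
  if (n_na > 0) cat(sprintf("Missing cells: %d\n", n_na))
  invisible(x)
}

# unit x year matrix for one variable
panel_matrix <- function(panel, variable) {
  if (!variable %in% names(panel$values))
    stopf("variable '%s' not in panel", variable)
  panel$values[[variable]]
}

#' Linear imputation of a panel variable
#'
#' Fills missing cells of one variable unit by unit. Interior gaps are linear
#' interpolation between the nearest observed neighbours. Leading gaps (the
#' typical case: a mediator recorded only from some year onwards) are filled
#' by extending the straight line through the first two observed points
#' backwards; trailing gaps extend the line through the last two observed
#' points. Extrapolated values below zero are clipped to 0 (with a warning)
#' for count-like variables, i.e. roles `component` and `mediator`, unless
#' `clip_zero` overrides this.
#'
#' @param panel an `scm_panel`.
#' @param variable variable name to impute.
#' @param clip_zero logical; default depends on the variable's role.
#' @return a new `scm_panel`; the input is not modified. Idempotent.
#' @export
impute_linear <- function(panel, variable, clip_zero = NULL) {
  m <- panel_matrix(panel, variable)
  if (is.null(clip_zero))
    clip_zero <- panel$roles[[variable]] %in% c("component", "mediator")
  yrs <- panel$years
  clipped <- character(0)
  for (u in rownames(m)) {
    y <- m[u, ]
    obs <- which(!is.na(y))
    if (length(obs) == length(y)) next
    if (length(obs) < 2L)
      stopf("unit '%s' has fewer than 2 observations of '%s'", u, variable)
    # interior
    filled <- stats::approx(yrs[obs], y[obs], xout = yrs, method = "linear",
                            rule = 1)$y
    # leading: line through first two observed points
    lead <- seq_len(obs[1] - 1L)
    if (length(lead)) {
      i1 <- obs[1]; i2 <- obs[2]
      slope <- (y[i2] - y[i1]) / (yrs[i2] - yrs[i1])
      filled[lead] <- y[i1] + slope * (yrs[lead] - yrs[i1])
    }
    # trailing: line through last two observed points
    trail <- seq.int(obs[length(obs)] + 1L, length(y))
    if (obs[length(obs)] < length(y)) {
      i1 <- obs[length(obs) - 1L]; i2 <- obs[length(obs)]
      slope <- (y[i2] - y[i1]) / (yrs[i2] - yrs[i1])
      filled[trail] <- y[i2] + slope * (yrs[trail] - yrs[i2])
    }
    if (clip_zero && any(filled < 0)) {
      clipped <- c(clipped, u)
      filled[filled < 0] <- 0
    }
    m[u, ] <- filled
  }
  if (length(clipped))
    warnf("negative imputed values clipped to 0 for '%s' in unit(s): %s",
          variable, paste(unique(clipped), collapse = ", "))
  panel$values[[variable]] <- m
  panel
}

#' Restrict a panel to a donor subset and/or an end year
#'
#' Used by robustness scenarios: drop named donor units (never the treated
#' unit) and/or truncate the sample at `end_year`.
#'
#' @param panel an `scm_panel`.
#' @param drop_units character vector of units to remove; must not contain
#'   the treated unit.
#' @param end_year last year to keep, `NULL` for no truncation; must be
#'   `>= treatment_year`.
#' @return a new `scm_panel` (balance preserved by construction).
#' @export
subset_panel <- function(panel, drop_units = character(0), end_year = NULL) {
  drop_units <- as.character(drop_units)
  if (panel$treated_unit %in% drop_units)
    stopf("cannot drop the treated unit '%s'", panel$treated_unit)
  unknown <- setdiff(drop_units, panel$units)
  if (length(unknown))
    warnf("drop_units not in panel (ignored): %s",
          paste(unknown, collapse = ", "))
  keep_u <- setdiff(panel$units, drop_units)
  keep_y <- panel$years
  if (!is.null(end_year)) {
    end_year <- .check_integerish(end_year, "end_year")
    if (end_year < panel$treatment_year)
      stopf("end_year %d precedes the treatment year %d", end_year,
            panel$treatment_year)
    keep_y <- panel$years[panel$years <= end_year]
  }
  panel$values <- lapply(panel$values, function(m)
    m[keep_u, as.character(keep_y), drop = FALSE])
  panel$units <- keep_u
  panel$years <- keep_y
  panel
}

#' @export
subset.scm_panel <- function(x, drop_units = character(0), end_year = NULL,
                             ...) {
  subset_panel(x, drop_units = drop_units, end_year = end_year)
}

# replace / add a variable (units x years matrix) with a given role
set_variable <- function(panel, variable, m, role) {
  stopifnot(identical(rownames(m), panel$units),
            identical(colnames(m), as.character(panel$years)))
  panel$values[[variable]] <- m
  panel$roles[[variable]] <- role
  if (role == "outcome") {
    old <- names(panel$roles)[panel$roles == "outcome"]
    old <- setdiff(old, variable)
    if (length(old)) panel$roles[old] <- "covariate"  # demote previous outcome
    panel$outcome <- variable
  }
  panel
}

# switch which existing variable is the outcome (mechanism scenarios)
set_outcome <- function(panel, variable) {
  if (!variable %in% names(panel$values))
    stopf("variable '%s' not in panel", variable)
  prev <- panel$outcome
  if (!is.na(prev) && prev != variable) panel$roles[[prev]] <- "mediator"
  panel$roles[[variable]] <- "outcome"
  panel$outcome <- variable
  panel
}
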