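#' In-space (city) placebo inference
#'
#' Refits the synthetic control once per donor, treating that donor as the
#' pseudo-treated unit with the genuine treated unit removed from its donor
#' pool. Placebo fits whose pre-treatment RMSPE exceeds
#' `cutoff_multiplier` times the treated unit's are excluded (the standard
#' filter; the conventional multiplier is 5, and very lax values such as
#' 700 can be chosen to retain nearly all curves). The test statistic is the
#' post/pre RMSPE ratio; `pseudo_p` is the fraction of included placebo
#' units whose ratio is at least the treated unit's, and `pseudo_p_rank` is
#' the permutation form `(b + 1) / (m + 1)` with the treated unit's own
#' ratio appended. A pseudo-treated unit with zero pre-RMSPE gets an
#' infinite ratio and is included.
#'
#' @param panel an `scm_panel`.
#' @param spec a [predictor_spec()] (default as in [synth_control()]).
#' @param cutoff_multiplier positive pre-RMSPE cutoff multiplier; `Inf`
#'   disables the filter. Default 5.
#' @param v_method,control forwarded to [synth_control()].
#' @param treated_fit optionally a pre-computed genuine `synth_control` fit
#'   (avoids refitting).
#' @return an object of class `placebo_ensemble`: a data.frame `units`
#'   (unit, pre_rmspe, post_rmspe, rmspe_ratio, included, failed), the
#'   treated reference fit, gap paths matrix `gaps` (years x units),
#'   `cutoff_multiplier`, `pseudo_p`, `pseudo_p_rank`.
#' @export
placebo_space <- function(panel, spec = NULL, cutoff_multiplier = 5,
                          v_method = "nested", control = scm_control(),
                          treated_fit = NULL) {
  stopifnot(inherits(panel, "scm_panel"))
  if (!(cutoff_multiplier > 0))
    stopf("cutoff_multiplier must be positive (may be Inf)")
  if (is.null(treated_fit))
    treated_fit <- synth_control(panel, spec, v_method = v_method,
                                 control = control)
  donors <- setdiff(panel$units, panel$treated_unit)
  gaps <- matrix(NA_real_, length(panel$years), length(donors),
                 dimnames = list(panel$years, donors))
  rows <- vector("list", length(donors))
  base <- panel   # the genuine treated unit leaves the pool entirely
  base$values <- lapply(base$values, function(m) m[donors, , drop = FALSE])
  base$units <- donors
  for (i in seq_along(donors)) {
    u <- donors[i]
    pp <- base
    pp$treated_unit <- u
    f <- tryCatch(synth_control(pp, spec, v_method = v_method,
                                control = control),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(unit = u, pre_rmspe = NA_real_,
                              post_rmspe = NA_real_, rmspe_ratio = NA_real_,
                              included = FALSE, failed = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    gaps[, i] <- f$gap_path
    rows[[i]] <- data.frame(unit = u, pre_rmspe = f$pre_rmspe,
                            post_rmspe = f$post_rmspe,
                            rmspe_ratio = .rmspe_ratio(f$post_rmspe,
                                                       f$pre_rmspe),
                            included = NA, failed = FALSE,
                            stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, rows)
  if (mean(units$failed) > 0.5)
    stopf("more than half of the placebo fits failed (%d of %d)",
          sum(units$failed), nrow(units))
  cut_val <- cutoff_multiplier * treated_fit$pre_rmspe
  units$included <- !units$failed & units$pre_rmspe <= cut_val
  treated_ratio <- .rmspe_ratio(treated_fit$post_rmspe,
                                treated_fit$pre_rmspe)
  m <- sum(units$included)
  b <- sum(units$included & units$rmspe_ratio >= treated_ratio)
  structure(list(units = units, gaps = gaps,
                 treated_fit = treated_fit,
                 treated_ratio = treated_ratio,
                 cutoff_multiplier = cutoff_multiplier,
                 n_included = m,
                 pseudo_p = if (m > 0) b / m else NA_real_,
                 pseudo_p_rank = (b + 1) / (m + 1)),
            class = "placebo_ensemble")
}

.rmspe_ratio <- function(post, pre) if (pre == 0) Inf else post / pre

#' @export
print.placebo_ensemble <- function(x, ...) {
  cat(sprintf("In-space placebo ensemble: %d placebo fits (%d failed)\n",
              nrow(x$units), sum(x$units$failed)))
  cat(sprintf("Pre-RMSPE cutoff: %g x treated (%d included)\n",
              x$cutoff_multiplier, x$n_included))
  cat(sprintf("Treated post/pre RMSPE ratio: %.3f\n", x$treated_ratio))
  cat(sprintf("pseudo p (share of included placebos with ratio >= treated): %.4f\n",
              x$pseudo_p))
  cat(sprintf("pseudo p, rank form (treated appended): %.4f\n",
              x$pseudo_p_rank))
  cat("Note: the pseudo p-value is a permutation-style extension; the\n")
  cat("published analysis reports placebo curves only.\n")
  invisible(x)
}

#' Plot placebo gap curves
#'
#' Grey curves for included placebo units, black for the treated unit.
#'
#' @param x a `placebo_ensemble`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.placebo_ensemble <- function(x, ...) {
  yrs <- as.integer(rownames(x$gaps))
  inc <- x$units$unit[x$units$included]
  rng <- range(x$gaps[, inc, drop = FALSE], x$treated_fit$gap_path,
               na.rm = TRUE)
  graphics::plot(yrs, x$treated_fit$gap_path, type = "n", ylim = rng,
                 xlab = "year", ylab = "gap (treated - synthetic)", ...)
  for (u in inc) graphics::lines(yrs, x$gaps[, u], col = "grey75")
  graphics::lines(yrs, x$treated_fit$gap_path, lwd = 2)
  graphics::abline(v = x$treated_fit$treatment_year - 0.5, lty = 3,
                   col = "grey40")
  invisible(x)
}

#' In-time placebo: backdated treatment year
#'
#' Refits the synthetic control pretending the policy started in
#' `fake_treatment_year`, using only data up to the year before the true
#' treatment year so genuine post-reform observations cannot leak into the
#' placebo evaluation. Lag-year predictors falling at or after the fake
#' year are dropped (with a message). A genuine effect should not appear at
#' the fake year.
#'
#' @param panel an `scm_panel`.
#' @param spec a [predictor_spec()].
#' @param fake_treatment_year integer, before the true treatment year. At
#'   least two pre-years must remain unless `allow_short_pre = TRUE`.
#' @param allow_short_pre allow a single pre-year (forces
#'   `v_method = "uniform"` since the nested search needs 2+ pre-years).
#' @param v_method,control forwarded to [synth_control()].
#' @return a `synth_control` fit on the truncated panel with the backdated
#'   treatment year.
#' @export
placebo_time <- function(panel, spec = NULL, fake_treatment_year,
                         allow_short_pre = FALSE, v_method = "nested",
                         control = scm_control()) {
  stopifnot(inherits(panel, "scm_panel"))
  t0 <- panel$treatment_year
  fake <- .check_integerish(fake_treatment_year, "fake_treatment_year")
  if (fake >= t0)
    stopf("fake treatment year %d must precede the true one (%d)", fake, t0)
  n_pre <- sum(panel$years < fake)
  if (n_pre < 2L && !allow_short_pre)
    stopf("only %d pre-year(s) before %d; need >= 2 (or allow_short_pre)",
          n_pre, fake)
  if (n_pre < 1L)
    stopf("no pre-years before %d", fake)
  # truncate so true post-reform years cannot leak in
  keep <- panel$years <= t0 - 1L
  pp <- panel
  pp$values <- lapply(pp$values, function(m) m[, keep, drop = FALSE])
  pp$years <- panel$years[keep]
  pp$treatment_year <- fake
  if (n_pre < 2L) v_method <- "uniform"
  synth_control(pp, spec, v_method = v_method, treatment_year = fake,
                control = control)
}
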