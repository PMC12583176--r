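#' Fit a synthetic control
#'
#' The main estimator. A synthetic counterfactual for the treated unit is
#' built as a convex combination of donor units: donor weights W minimize
#' the V-weighted distance between treated and synthetic predictors
#' ([solve_w()]), and the predictor-importance weights V are chosen so the
#' implied synthetic control tracks the treated unit's pre-treatment outcome
#' as closely as possible ([solve_v()]). The estimated policy effect in each
#' post-treatment year is the gap between the actual and synthetic outcome
#' paths; its post-period mean (including the treatment year itself) is the
#' headline estimate.
#'
#' @param panel an `scm_panel` with a designated outcome variable.
#' @param spec a [predictor_spec()]; default: all covariate-role variables
#'   plus every pre-treatment year of the outcome as lag predictors.
#' @param v_method `"nested"` (default) optimizes V by multi-start search;
#'   `"uniform"` fixes V at equal weights (fast, used as a baseline);
#'   `"fixed"` uses the vector supplied in `V`.
#' @param V predictor weights for `v_method = "fixed"`.
#' @param treatment_year override of the panel's treatment year (used by
#'   in-time placebos).
#' @param control an [scm_control()].
#' @return an object of class `synth_control` with components
#'   `treated_path`, `synthetic_path`, `gap_path` (named by year),
#'   `pre_rmspe`, `post_rmspe`, `mean_post_effect`, `weights` (list `V`,
#'   `W`), `balance` (per-predictor treated/synthetic values and bias in
#'   percent, raw units), and metadata. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `plot`, `weights`.
#' @examples
#' sim <- simulate_panel(sim_config(n_units = 12, noise_sd = 0, seed = 3))
#' fit <- synth_control(sim$panel, v_method = "uniform")
#' round(fit$mean_post_effect, 3)
#' @export
synth_control <- function(panel, spec = NULL,
                          v_method = c("nested", "uniform", "fixed"),
                          V = NULL, treatment_year = panel$treatment_year,
                          control = scm_control()) {
  v_method <- match.arg(v_method)
  stopifnot(inherits(panel, "scm_panel"))
  if (is.null(spec))
    spec <- predictor_spec(
      covariates = names(panel$roles)[panel$roles == "covariate"])
  X <- build_predictors(panel, spec, treatment_year)
  k <- length(X$X1)

  yrs <- panel$years
  pre <- yrs < treatment_year
  post <- !pre
  Y <- panel_matrix(panel, panel$outcome)
  if (anyNA(Y))
    stopf("outcome has missing values; impute before fitting")
  Y1 <- Y[panel$treated_unit, ]
  Y0 <- Y[X$donors, , drop = FALSE]
  Z1 <- Y1[pre]
  Z0 <- t(Y0[, pre, drop = FALSE])       # pre-years x donors

  if (length(Z1) < 2L && v_method == "nested")
    stopf("nested V search needs >= 2 pre-treatment years (got %d); %s",
          length(Z1), "use v_method = 'uniform' or allow_short_pre contexts")

  sol <- switch(v_method,
    nested = solve_v(X, Z1, Z0, control),
    uniform = {
      Vu <- rep(1 / k, k)
      w <- solve_w(Vu, X$X1, X$X0, ridge = control$ridge)
      list(V = Vu, W = as.numeric(w),
           loss = mean((Z1 - as.numeric(Z0 %*% w))^2), n_converged = 1L)
    },
    fixed = {
      if (is.null(V) || length(V) != k)
        stopf("v_method = 'fixed' requires V of length %d", k)
      Vf <- V / sum(V)
      w <- solve_w(Vf, X$X1, X$X0, ridge = control$ridge)
      list(V = Vf, W = as.numeric(w),
           loss = mean((Z1 - as.numeric(Z0 %*% w))^2), n_converged = 1L)
    })

  W <- sol$W
  names(W) <- X$donors
  Vout <- sol$V
  names(Vout) <- X$names

  synthetic <- as.numeric(t(Y0) %*% W)
  names(synthetic) <- names(Y1)
  gap <- Y1 - synthetic

  syn_pred_raw <- as.numeric(X$X0_raw %*% W)
  balance <- data.frame(
    predictor = X$names,
    v_weight = as.numeric(Vout),
    treated = as.numeric(X$X1_raw),
    synthetic = syn_pred_raw,
    bias_pct = bias_pct(X$X1_raw, syn_pred_raw),
    stringsAsFactors = FALSE)

  structure(list(
    treated_path = Y1, synthetic_path = synthetic, gap_path = gap,
    pre_rmspe = sqrt(mean(gap[pre]^2)),
    post_rmspe = sqrt(mean(gap[post]^2)),
    mean_post_effect = mean(gap[post]),
    weights = list(V = Vout, W = W),
    balance = balance,
    loss_v = sol$loss, n_converged = sol$n_converged,
    outcome = panel$outcome, treated_unit = panel$treated_unit,
    treatment_year = treatment_year, years = yrs,
    donors = X$donors, spec = spec, v_method = v_method,
    control = control), class = "synth_control")
}

#' Percent bias of a synthetic value against the treated value
#'
#' The balance-table convention: `(synthetic - treated) / treated * 100`.
#' Rows with a treated value of exactly 0 are undefined and returned as
#' `NA`.
#'
#' @param treated,synthetic numeric vectors.
#' @return percent bias, same length.
#' @export
bias_pct <- function(treated, synthetic) {
  out <- (synthetic - treated) / treated * 100
  out[treated == 0] <- NA_real_
  as.numeric(out)
}

#' Gap arithmetic on actual and synthetic outcome paths
#'
#' Pure arithmetic shared by the fitter and by checks against published
#' per-year columns: the effect path is `actual - synthetic`, and the
#' summary row holds the column means (the mean effect over the period).
#'
#' @param actual,synthetic numeric vectors of equal length.
#' @param years optional year labels.
#' @return data.frame `year, actual, synthetic, effect` with attribute
#'   `means` = c(actual, synthetic, effect) column means.
#' @export
effect_table <- function(actual, synthetic, years = seq_along(actual)) {
  stopifnot(length(actual) == length(synthetic))
  out <- data.frame(year = years, actual = actual, synthetic = synthetic,
                    effect = actual - synthetic)
  attr(out, "means") <- c(actual = mean(actual), synthetic = mean(synthetic),
                          effect = mean(actual - synthetic))
  out
}

#' Covariate balance table of a fitted synthetic control
#'
#' One row per predictor: V weight, treated and synthetic values in raw
#' units, and percent bias `(synthetic - treated)/treated * 100` rounded to
#' two decimals. Predictors whose treated value is 0 have undefined bias and
#' are flagged with `NA`.
#'
#' @param fit a `synth_control` object.
#' @param digits decimals for the reported bias.
#' @return a data.frame.
#' @export
balance_table <- function(fit, digits = 2) {
  stopifnot(inherits(fit, "synth_control"))
  b <- fit$balance
  b$bias_pct <- round(b$bias_pct, digits)
  b
}

#' Per-year effects of a fitted synthetic control in the published layout
#'
#' @param fit a `synth_control` object.
#' @param post_only keep only treatment year onwards (default).
#' @return data.frame `year, actual, synthetic, effect` (+ `means`
#'   attribute), as in [effect_table()].
#' @export
effects_table <- function(fit, post_only = TRUE) {
  stopifnot(inherits(fit, "synth_control"))
  keep <- if (post_only) fit$years >= fit$treatment_year else
    rep(TRUE, length(fit$years))
  effect_table(fit$treated_path[keep], fit$synthetic_path[keep],
               fit$years[keep])
}

#' @export
print.synth_control <- function(x, digits = 4, ...) {
  cat(sprintf("Synthetic control fit (outcome: %s)\n", x$outcome))
  cat(sprintf("Treated unit: %s | treatment year: %d | donors: %d\n",
              x$treated_unit, x$treatment_year, length(x$donors)))
  cat(sprintf("Pre-period RMSPE:  %.*f\n", digits, x$pre_rmspe))
  cat(sprintf("Post-period RMSPE: %.*f\n", digits, x$post_rmspe))
  cat(sprintf("Mean post-treatment effect: %.*f\n", digits,
              x$mean_post_effect))
  invisible(x)
}

#' @export
summary.synth_control <- function(object, digits = 4, n_donors = 8, ...) {
  print(object, digits = digits)
  cat("\nPredictor balance:\n")
  b <- balance_table(object)
  b$v_weight <- round(b$v_weight, 4)
  b$treated <- signif(b$treated, 6)
  b$synthetic <- signif(b$synthetic, 6)
  print(b, row.names = FALSE)
  W <- sort(object$weights$W, decreasing = TRUE)
  W <- W[W > 1e-4]
  cat(sprintf("\nLargest donor weights (of %d donors, %d above 1e-4):\n",
              length(object$donors), length(W)))
  print(round(utils::head(W, n_donors), 4))
  invisible(object)
}

#' @export
coef.synth_control <- function(object, which = c("W", "V"), ...) {
  which <- match.arg(which)
  object$weights[[which]]
}

#' @export
weights.synth_control <- function(object, ...) object$weights$W

#' @export
fitted.synth_control <- function(object, ...) object$synthetic_path

#' @export
residuals.synth_control <- function(object, ...) object$gap_path

#' @export
predict.synth_control <- function(object, years = NULL, ...) {
  if (is.null(years)) return(object$synthetic_path)
  keep <- as.character(years)
  object$synthetic_path[keep]
}

#' Plot a fitted synthetic control
#'
#' Two base-graphics panels: actual vs synthetic outcome paths, and the gap
#' (effect) path, with a vertical line at the treatment year.
#'
#' @param x a `synth_control` object.
#' @param which `"paths"`, `"gap"` or `"both"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.synth_control <- function(x, which = c("both", "paths", "gap"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "paths")) {
    rng <- range(x$treated_path, x$synthetic_path)
    graphics::plot(x$years, x$treated_path, type = "l", lwd = 2,
                   ylim = rng, xlab = "year", ylab = x$outcome, ...)
    graphics::lines(x$years, x$synthetic_path, lty = 2)
    graphics::abline(v = x$treatment_year - 0.5, col = "grey50", lty = 3)
    graphics::legend("topright", legend = c("treated", "synthetic"),
                     lty = c(1, 2), lwd = c(2, 1), bty = "n")
  }
  if (which %in% c("both", "gap")) {
    graphics::plot(x$years, x$gap_path, type = "l", lwd = 2,
                   xlab = "year", ylab = "gap (treated - synthetic)", ...)
    graphics::abline(h = 0, col = "grey70")
    graphics::abline(v = x$treatment_year - 0.5, col = "grey50", lty = 3)
  }
  invisible(x)
}
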