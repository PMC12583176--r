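#' Configuration for the synthetic panel generator
#'
#' Defines a balanced city-year panel with known ground truth, emulating the
#' study conditions of the Sanming evaluation: 204 units observed 2007-2022,
#' one treated unit, treatment in 2012, an interactive-fixed-effects
#' (factor-model) outcome on the misallocation-index scale, five covariates
#' in the roles used by the evaluation (two industry shares in percent, a
#' GDP level, a GDP growth rate, a registered population), and, in mechanism
#' mode, two mediator series (government health expenditure, insured-person
#' counts with missing pre-2011 cells).
#'
#' The default effect path is a ramp from -0.02 to -0.23 with a mid-period
#' dip, a stylistic default chosen so that demonstration output is on the
#' magnitude scale of published Sanming estimates; it is not a data-derived
#' quantity.
#'
#' @param n_units number of units (>= 3); default 204.
#' @param start_year,end_year calendar years; default 2007-2022.
#' @param treatment_year first treated year T0; default 2012.
#' @param n_factors latent factors in the outcome; default 2.
#' @param effect_path additive treated effect per post year; `NULL` uses the
#'   default ramp (linearly rescaled if the post period is not 11 years).
#'   Forced to zero in `"null"` mode.
#' @param noise_sd idiosyncratic outcome noise sd; default 0.02.
#' @param rho correlation strength between covariates and factor loadings
#'   in \[0, 1\]; default 0.5.
#' @param mode `"outcome"` (emit the outcome directly), `"components"`
#'   (additionally emit hospital/bed/physician counts + population whose
#'   misallocation index reproduces the outcome exactly under the
#'   mean-ratio scheme), `"mechanism"` (additionally emit the two mediator
#'   series with injected post-period shifts: positive for expenditure,
#'   negative for enrollees), or `"null"` (no effect anywhere).
#' @param treated_draw `"hull"` (default): treated latents are an exact
#'   convex combination of 3-6 donors, so a perfect synthetic control
#'   exists; `"iid"`: treated drawn like any donor (exchangeable units, the
#'   right null for placebo-calibration studies); `"outside"`: treated
#'   placed outside the donor support to exercise poor-fit diagnostics.
#'   `TRUE`/`FALSE` map to `"hull"`/`"outside"`.
#' @param expenditure_shift,enrollee_shift post-period mediator shifts for
#'   the treated unit (end-of-ramp magnitudes, mediator units).
#' @param seed RNG seed; every draw is governed by it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_units = 204, start_year = 2007, end_year = 2022,
                       treatment_year = 2012, n_factors = 2,
                       effect_path = NULL, noise_sd = 0.02, rho = 0.5,
                       mode = c("outcome", "components", "mechanism", "null"),
                       treated_draw = "hull",
                       expenditure_shift = 8, enrollee_shift = -30,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.logical(treated_draw))
    treated_draw <- if (treated_draw) "hull" else "outside"
  treated_draw <- match.arg(treated_draw, c("hull", "iid", "outside"))
  stopifnot(n_units >= 3, noise_sd >= 0, rho >= 0, rho <= 1,
            start_year < treatment_year, treatment_year <= end_year,
            n_factors >= 1)
  years <- start_year:end_year
  n_post <- sum(years >= treatment_year)
  tau <- if (mode == "null") rep(0, n_post) else
    effect_path %||% .default_effect_path(n_post)
  if (length(tau) != n_post)
    stopf("effect_path must have one value per post year (%d)", n_post)
  structure(list(n_units = n_units, years = years,
                 treatment_year = treatment_year, n_factors = n_factors,
                 effect_path = tau, noise_sd = noise_sd, rho = rho,
                 mode = mode, treated_draw = treated_draw,
                 expenditure_shift = expenditure_shift,
                 enrollee_shift = enrollee_shift, seed = seed),
            class = "sim_config")
}

# ramp from -0.02 to -0.23 with a dip after the peak years, rescaled to the
# requested number of post years
.default_effect_path <- function(n_post) {
  template <- c(-0.02, -0.06, -0.08, -0.14, -0.16, -0.20,
                -0.155, -0.14, -0.17, -0.20, -0.23)
  if (n_post == length(template)) return(template)
  stats::approx(seq(0, 1, length.out = length(template)), template,
                xout = seq(0, 1, length.out = max(n_post, 2L)))$y[seq_len(n_post)]
}

.sim_covariate_map <- data.frame(
  name = c("sec_industry_share", "ter_industry_share", "gdp",
           "gdp_growth", "population"),
  intercept = c(45, 38, 5e6, 10, 300),
  slope = c(8, 7, 1.5e6, 3, 100),
  stringsAsFactors = FALSE)

#' Generate a synthetic balanced panel with known truth
#'
#' The outcome follows an interactive fixed-effects model
#' \deqn{Y_{it} = \delta_t + \theta_t^\top Z_i + \lambda_t^\top \mu_i +
#'   \varepsilon_{it},}
#' with bounded latent covariates \eqn{Z_i} (so emitted shares, GDP and
#' population stay in their natural ranges), factor loadings \eqn{\mu_i}
#' correlated with \eqn{Z_i} at strength `rho`, and the treated effect
#' `effect_path` added to the treated unit from the treatment year on.
#' Emitted covariates are affine transforms of \eqn{Z_i}, so convex-hull
#' membership of the treated unit carries over to the observed data.
#'
#' In components mode the outcome is additionally realized as an exact
#' misallocation index: per year, unit totals are sign-balanced around the
#' national mean by a greedy partition (one designated balancing donor
#' absorbs the rounding residual) and split into three proportional
#' component counts, so that [compute_misallocation()] with the mean-ratio
#' scheme returns the panel's outcome column to within numerical round-off.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (an `scm_panel`) and `truth` (effect path,
#'   latents, factor structure, hull membership, balancing unit).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_panel_impl(config))
}

.simulate_panel_impl <- function(cfg) {
  n <- cfg$n_units
  yrs <- cfg$years
  Tn <- length(yrs)
  Fk <- cfg$n_factors
  post <- yrs >= cfg$treatment_year
  units <- sprintf("u%03d", seq_len(n))
  treated <- units[1]

  s3 <- sqrt(3)

  # latents: mu (loadings) and Z (5 covariate latents), bounded (uniform on
  # [-sqrt(3), sqrt(3)], unit variance) so emitted shares/levels stay in
  # their natural ranges; Z correlated with the first loading at rho
  mu <- matrix(stats::runif(n * Fk, -s3, s3), n, Fk)
  Zr <- matrix(stats::runif(n * 5, -s3, s3), n, 5)
  Z <- cfg$rho * mu[, 1] + sqrt(1 - cfg$rho^2) * Zr  # recycled by column

  hull_donors <- integer(0)
  hull_w <- numeric(0)
  if (cfg$treated_draw == "hull") {
    if (n < 5) stopf("treated_draw = 'hull' needs n_units >= 5")
    m <- min(sample(3:6, 1), n - 2)
    # never the last unit (reserved as balancing donor in components mode)
    pool <- 2:(n - 1)
    hull_donors <- pool[sample.int(length(pool), m)]
    hull_w <- as.numeric(rdirichlet(1, rep(1, m)))
    mu[1, ] <- as.numeric(hull_w %*% mu[hull_donors, , drop = FALSE])
    Z[1, ] <- as.numeric(hull_w %*% Z[hull_donors, , drop = FALSE])
  } else if (cfg$treated_draw == "outside") {
    Z[1, ] <- Z[1, ] + 2.5 * s3      # beyond the bounded donor support
    mu[1, ] <- mu[1, ] + 2.5 * s3
  }

  delta <- 0.55 - 0.004 * (yrs - yrs[1])
  theta <- matrix(stats::rnorm(5 * Tn, 0, 0.03), 5, Tn)
  lambda <- matrix(stats::rnorm(Fk * Tn, 0, 0.06), Fk, Tn)
  eps <- matrix(stats::rnorm(n * Tn, 0, cfg$noise_sd), n, Tn)

  Y <- matrix(rep(delta, each = n), n, Tn) + Z %*% theta + mu %*% lambda + eps
  tau_full <- numeric(Tn)
  tau_full[post] <- cfg$effect_path
  Y[1, ] <- Y[1, ] + tau_full
  dimnames(Y) <- list(units, as.character(yrs))

  # emitted covariates: affine in the latent Z columns
  cov_mats <- list()
  for (j in seq_len(5)) {
    cm <- .sim_covariate_map[j, ]
    M <- matrix(rep(cm$intercept + cm$slope * Z[, j], Tn), n, Tn,
                dimnames = list(units, as.character(yrs)))
    cov_mats[[cm$name]] <- M
  }

  balancing_unit <- NA_character_
  comp_mats <- list()
  if (cfg$mode == "components") {
    Y <- pmin(pmax(Y, 1e-8), 0.999)
    balancing_unit <- units[n]
    sgn <- matrix(1, n, Tn)
    for (t in seq_len(Tn)) {
      y <- Y[, t]
      # greedy signed partition over all units except the balancing donor:
      # largest first, each taking the sign that shrinks the running sum
      idx <- setdiff(order(abs(y), decreasing = TRUE), n)
      run <- 0
      for (i in idx) {
        s <- if (run > 0) -1 else 1
        sgn[i, t] <- s
        run <- run + s * y[i]
      }
      Y[n, t] <- abs(run)
      sgn[n, t] <- -sign(run)
      if (run == 0) sgn[n, t] <- 1
    }
    Tot <- 3 * (1 + sgn * Y)     # totals with national mean exactly 3
    scales <- c(hospitals_health_centers = 60, beds = 2e4, physicians = 1.5e4)
    for (v in names(scales))
      comp_mats[[v]] <- scales[[v]] * Tot / 3
  }

  med_mats <- list()
  if (cfg$mode == "mechanism") {
    np <- sum(post)
    ramp <- seq_len(np) / np
    exp_base <- 20 + 2 * (yrs - yrs[1])
    ge <- matrix(rep(exp_base, each = n), n, Tn) +
      4 * mu[, 1] + 2 * mu[, min(2, Fk)] +
      matrix(stats::rnorm(n * Tn, 0, 20 * cfg$noise_sd), n, Tn)
    ge[1, post] <- ge[1, post] + cfg$expenditure_shift * ramp
    ins_base <- 250 + 1.5 * (yrs - yrs[1])
    ip <- matrix(rep(ins_base, each = n), n, Tn) +
      30 * mu[, 1] - 10 * mu[, min(2, Fk)] +
      matrix(stats::rnorm(n * Tn, 0, 250 * cfg$noise_sd), n, Tn)
    ip[1, post] <- ip[1, post] + cfg$enrollee_shift * ramp
    ip[, yrs < 2011] <- NA_real_          # enrollee data starts in 2011
    dimnames(ge) <- dimnames(ip) <- list(units, as.character(yrs))
    med_mats <- list(gov_health_expenditure = ge, insured_persons = ip)
  }

  values <- c(list(misallocation = Y), cov_mats, comp_mats, med_mats)
  roles <- c(misallocation = "outcome",
             stats::setNames(rep("covariate", 5), .sim_covariate_map$name),
             stats::setNames(rep("component", length(comp_mats)),
                             names(comp_mats)),
             stats::setNames(rep("mediator", length(med_mats)),
                             names(med_mats)))

  panel <- structure(list(units = units, years = yrs, values = values,
                          roles = roles, treated_unit = treated,
                          treatment_year = cfg$treatment_year,
                          outcome = "misallocation"), class = "scm_panel")

  truth <- list(effect_path = stats::setNames(cfg$effect_path,
                                              yrs[post]),
                mean_effect = mean(cfg$effect_path),
                delta = delta, theta = theta, lambda = lambda,
                mu = mu, Z = Z,
                treated_unit = treated,
                treatment_year = cfg$treatment_year,
                treated_draw = cfg$treated_draw,
                in_hull = cfg$treated_draw == "hull",
                hull_donors = units[hull_donors],
                hull_weights = hull_w,
                balancing_unit = balancing_unit,
                mode = cfg$mode, seed = cfg$seed)
  list(panel = panel, truth = truth)
}

#' Write a generated panel, schema and truth to disk
#'
#' Emits `panel.csv` (long format), `schema.yml` and `truth.json` into
#' `dir`; byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(config, dir) {
  sim <- simulate_panel(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_panel(sim$panel, file.path(dir, "panel.csv"))
  schema <- list(treated_unit = sim$panel$treated_unit,
                 treatment_year = sim$panel$treatment_year,
                 roles = as.list(sim$panel$roles))
  yaml::write_yaml(schema, file.path(dir, "schema.yml"))
  truth <- sim$truth
  truth$theta <- NULL; truth$lambda <- NULL  # keep the JSON compact
  truth$mu <- NULL; truth$Z <- NULL; truth$delta <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
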