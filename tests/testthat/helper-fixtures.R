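# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored binary data.

# canonical nine-predictor specification of the evaluation design:
# five covariates by pre-treatment mean + four outcome lags
study_spec <- function() {
  predictor_spec(
    covariates = c("sec_industry_share", "ter_industry_share", "gdp",
                   "gdp_growth", "population"),
    lag_years = 2007:2010)
}

# light-weight fitting options for Monte Carlo loops
fast_ctl <- function(n_starts = 1, nm_maxit = 60)
  scm_control(n_starts = n_starts, nm_maxit = nm_maxit)

# tiny wide panel: 2 units x 3 years x 1 variable
tiny_panel_df <- function() {
  data.frame(unit = rep(c("a", "b"), each = 3), year = rep(2010:2012, 2),
             y = c(1, 2, 3, 4, 5, 6))
}

tiny_panel <- function() {
  panel_data(tiny_panel_df(), treated_unit = "a", treatment_year = 2012,
             roles = c(y = "outcome"))
}

# hand-built panel: outcome from a 2-factor model, treated an exact convex
# combination of the first `m` donors; covariates either informative
# (equal to the loadings) or pure noise
factor_panel <- function(n = 10, years = 2007:2022, t0 = 2012, m = 3,
                         noise_sd = 0, cov_noise = FALSE, n_factors = 2,
                         seed = 99) {
  set.seed(seed)
  units <- sprintf("u%02d", 1:n)
  Tn <- length(years)
  mu <- matrix(rnorm(n * n_factors), n, n_factors)
  w <- as.numeric(rdirichlet_test(rep(1, m)))
  mu[1, ] <- as.numeric(w %*% mu[2:(m + 1), , drop = FALSE])
  lam <- matrix(rnorm(n_factors * Tn, 0, 0.3), n_factors, Tn)
  Y <- 0.5 + mu %*% lam + matrix(rnorm(n * Tn, 0, noise_sd), n, Tn)
  dimnames(Y) <- list(units, years)
  cov1 <- if (cov_noise) rnorm(n) else mu[, 1]
  cov2 <- if (cov_noise) rnorm(n) else mu[, 2]
  if (cov_noise) { cov1[1] <- rnorm(1); cov2[1] <- rnorm(1) }
  df <- data.frame(unit = rep(units, each = Tn), year = rep(years, n),
                   y = as.vector(t(Y)),
                   c1 = rep(cov1, each = Tn), c2 = rep(cov2, each = Tn))
  list(panel = panel_data(df, treated_unit = units[1], treatment_year = t0,
                          roles = c(y = "outcome", c1 = "covariate",
                                    c2 = "covariate")),
       w_true = w, mu = mu)
}

rdirichlet_test <- function(alpha) {
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}

# ---- independent oracles for the inner QP ----

qp_objective <- function(V, X1, X0, W) {
  r <- X1 - as.numeric(X0 %*% W)
  sum(V * r^2)
}

# exhaustive simplex grid search at resolution `res` (J = 2 or 3),
# vectorized over grid columns
grid_search_obj <- function(V, X1, X0, res = 1e-3) {
  J <- ncol(X0)
  stopifnot(J %in% 2:3)
  if (J == 2) {
    w1 <- seq(0, 1, by = res)
    W <- rbind(w1, 1 - w1)
    return(min(colSums(V * (X1 - X0 %*% W)^2)))
  }
  best <- Inf
  for (w1 in seq(0, 1, by = res)) {
    w2 <- seq(0, 1 - w1, by = res)
    W <- rbind(w1, w2, pmax(1 - w1 - w2, 0))
    best <- min(best, min(colSums(V * (X1 - X0 %*% W)^2)))
  }
  best
}

# exact oracle by enumeration of supports: for each nonempty donor subset,
# solve the sum-to-one-constrained least squares via a null-space
# parameterization and QR (no active-set machinery shared with solve_w),
# keep feasible candidates, return the best objective
support_enum_obj <- function(V, X1, X0) {
  J <- ncol(X0)
  A <- X0 * sqrt(V)
  b <- X1 * sqrt(V)
  best <- Inf
  for (size in 1:J) {
    for (S in utils::combn(J, size, simplify = FALSE)) {
      p <- length(S)
      w0 <- rep(1 / p, p)
      if (p == 1) {
        cand <- 1
      } else {
        N <- svd(diag(p) - matrix(1 / p, p, p))$u[, 1:(p - 1), drop = FALSE]
        As <- A[, S, drop = FALSE]
        t_hat <- qr.coef(qr(As %*% N), b - as.numeric(As %*% w0))
        t_hat[is.na(t_hat)] <- 0
        cand <- w0 + as.numeric(N %*% t_hat)
      }
      if (min(cand) < -1e-9) next
      W <- numeric(J); W[S] <- pmax(cand, 0); W <- W / sum(W)
      best <- min(best, qp_objective(V, X1, X0, W))
    }
  }
  best
}

# oracle dispatcher used by the solver-equivalence tests
oracle_obj <- function(V, X1, X0, res = 1e-3) {
  if (ncol(X0) <= 3) grid_search_obj(V, X1, X0, res) else
    support_enum_obj(V, X1, X0)
}
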