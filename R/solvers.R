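#' Donor weights for a given predictor weighting
#'
#' Solves the inner SCM problem
#' \deqn{W^* = \arg\min_{W \in \Delta^{J-1}} (X_1 - X_0 W)^\top V (X_1 - X_0 W)}
#' over the probability simplex (entries >= 0, summing to 1), where `V` is a
#' diagonal predictor-importance weighting. A tiny ridge term
#' `ridge * ||W||^2` (default 1e-9) makes the minimizer unique when several
#' donor combinations achieve the same loss (e.g. duplicated donors), at
#' negligible bias; ties then resolve to the minimum-norm weights.
#'
#' The problem is a convex quadratic program; it is solved exactly by an
#' active-set method on the nonnegativity constraints with an
#' equality-constrained KKT solve on the working set (the ridge makes the
#' Hessian positive definite, so the iteration terminates finitely).
#'
#' @param V nonnegative predictor weights summing to 1 (length k).
#' @param X1 treated predictor vector (length k).
#' @param X0 donor predictor matrix (k x J).
#' @param ridge uniqueness regularization on `||W||^2`.
#' @param warm optional integer vector of donor indices used to warm-start
#'   the active set (e.g. the support of a previous solve at nearby `V`).
#'   Affects speed only; the ridge-regularized solution is unique.
#' @return numeric vector `W` of length J on the simplex, with attributes
#'   `loss` (the V-weighted quadratic objective, without the ridge term),
#'   `support` (indices of nonzero weights) and `iterations`.
#' @export
solve_w <- function(V, X1, X0, ridge = 1e-9, warm = NULL) {
  X0 <- as.matrix(X0)
  k <- length(X1)
  J <- ncol(X0)
  stopifnot(nrow(X0) == k, length(V) == k)
  if (any(V < -1e-12)) stopf("V must be nonnegative")
  if (abs(sum(V) - 1) > 1e-6) stopf("V must sum to 1")
  V <- pmax(V, 0)

  if (J == 1L) {
    w <- 1
    it <- 0L
  } else {
    sv <- sqrt(V)
    A <- X0 * sv          # rows scaled by sqrt(V)
    b <- X1 * sv
    w <- .simplex_ls(A, b, ridge, warm = warm)
    it <- attr(w, "iterations")
  }
  w <- pmax(as.numeric(w), 0)
  w <- w / sum(w)
  r <- X1 - as.numeric(X0 %*% w)
  structure(w, loss = sum(V * r^2), support = which(w > 0), iterations = it)
}

# Active-set solver: min ||A w - b||^2 + ridge ||w||^2  s.t.  w >= 0, 1'w = 1.
# Works on the thin k x J matrix directly (no J x J Gram matrix): each
# iteration costs O(kJ) plus a small KKT solve on the working set, so large
# donor pools stay cheap. Gradient g(w) = 2 A'(A w - b) + 2 ridge w; with
# multiplier lam on the sum constraint, optimality is g_i = lam on the
# support and g_j >= lam off it. The dual tolerance is kept well below the
# ridge so the ridge genuinely governs tie-breaking among equal-loss
# solutions (minimum-norm weights, e.g. an even split across duplicate
# donors).
.simplex_ls <- function(A, b, ridge, warm = NULL) {
  J <- ncol(A)
  Atb <- as.numeric(crossprod(A, b))
  colA2 <- colSums(A * A)
  scale <- max(1, max(colA2))
  ridge_eff <- if (ridge > 0) ridge else 1e-12 * scale

  obj1 <- colA2 - 2 * Atb       # objective (up to const) at each vertex e_j
  j0 <- which.min(obj1)
  w <- numeric(J)
  if (!is.null(warm) && length(warm) && all(warm %in% seq_len(J))) {
    P <- sort(unique(as.integer(warm)))
    w[P] <- 1 / length(P)
  } else {
    w[j0] <- 1
    P <- j0
  }
  tol <- max(1e-12 * scale, 0.01 * ridge_eff)
  it <- 0L
  max_it <- 100L * J

  repeat {
    it <- it + 1L
    if (it > max_it) stopf("simplex QP did not converge in %d iterations", max_it)
    # equality-constrained solve on the working set P
    np <- length(P)
    Q <- crossprod(A[, P, drop = FALSE]) + diag(ridge_eff, np)
    K <- rbind(cbind(2 * Q, rep(1, np)), c(rep(1, np), 0))
    rhs <- c(2 * Atb[P], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) {  # near-singular working set: nudge the ridge
      Q <- Q + diag(1e-8 * max(1, mean(diag(Q))), np)
      K <- rbind(cbind(2 * Q, rep(1, np)), c(rep(1, np), 0))
      sol <- solve(K, rhs)
    }
    w_new <- numeric(J)
    w_new[P] <- sol[seq_len(np)]
    lam <- -sol[np + 1L]

    if (any(w_new[P] < -tol)) {
      # step from w toward w_new until the first coordinate hits zero
      d <- w_new - w
      neg <- P[w_new[P] < -tol]
      alpha <- min(w[neg] / (w[neg] - w_new[neg]))
      alpha <- max(min(alpha, 1), 0)
      w <- w + alpha * d
      w[neg][w[neg] < tol] <- 0
      P <- which(w > tol)
      if (!length(P)) { w[] <- 0; w[j0] <- 1; P <- j0 }
      next
    }
    w <- w_new
    # dual feasibility off the working set: g_j - lam >= 0
    r <- as.numeric(A %*% w) - b
    g <- 2 * (as.numeric(crossprod(A, r))) + 2 * ridge_eff * w
    off <- which(w == 0)
    if (!length(off)) break
    red <- g[off] - lam
    if (min(red) >= -tol) break
    P <- sort(c(P, off[which.min(red)]))
  }
  structure(w, iterations = it)
}

#' Control parameters for synthetic control fitting
#'
#' @param n_starts number of Dirichlet(1)-sampled starting points for the
#'   outer V search, in addition to the uniform start (which is always
#'   included, so the fitted pre-period MSPE can never exceed the uniform-V
#'   baseline).
#' @param nm_maxit maximum Nelder-Mead iterations per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param ridge uniqueness ridge for the inner W program.
#' @param seed seed for the Dirichlet starts; fits are deterministic given
#'   the seed and do not disturb the caller's RNG state.
#' @return a list of class `scm_control`.
#' @export
scm_control <- function(n_starts = 20, nm_maxit = 250, reltol = 1e-8,
                        ridge = 1e-9, seed = 1L) {
  stopifnot(n_starts >= 0, nm_maxit >= 1)
  structure(list(n_starts = n_starts, nm_maxit = nm_maxit, reltol = reltol,
                 ridge = ridge, seed = seed), class = "scm_control")
}

#' Nested predictor-importance search
#'
#' Chooses V to minimize the pre-treatment outcome mean squared prediction
#' error of the synthetic control implied by [solve_w()]. The V-simplex is
#' searched by multi-start Nelder-Mead on softmax-parameterized coordinates:
#' the uniform V plus `n_starts` Dirichlet(1) draws. Derivative-free search
#' avoids differentiating through the inner quadratic program.
#'
#' @param X predictor object from [build_predictors()].
#' @param Z1 treated pre-period outcome vector.
#' @param Z0 donor pre-period outcome matrix (years x donors).
#' @param control an [scm_control()].
#' @return list with `V`, `W`, `loss` (pre-period MSPE) and the number of
#'   starts that converged.
#' @export
solve_v <- function(X, Z1, Z0, control = scm_control()) {
  k <- nrow(X$X0)
  warm_env <- new.env(parent = emptyenv())
  warm_env$support <- NULL
  mspe_of <- function(V) {
    w <- solve_w(V, X$X1, X$X0, ridge = control$ridge,
                 warm = warm_env$support)
    warm_env$support <- attr(w, "support")
    mean((Z1 - as.numeric(Z0 %*% w))^2)
  }
  if (k == 1L) {
    V <- 1
    w <- solve_w(V, X$X1, X$X0, ridge = control$ridge)
    return(list(V = V, W = as.numeric(w), loss = mspe_of(V), n_converged = 1L))
  }
  starts <- with_seed(control$seed, {
    s <- matrix(0, nrow = 1 + control$n_starts, ncol = k)
    if (control$n_starts > 0) {
      d <- rdirichlet(control$n_starts, rep(1, k))
      s[-1, ] <- log(pmax(d, 1e-12))
    }
    s
  })
  best <- list(loss = Inf, V = NULL)
  n_ok <- 0L
  errs <- character(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn = function(theta) mspe_of(softmax(theta)),
                   method = "Nelder-Mead",
                   control = list(maxit = control$nm_maxit,
                                  reltol = control$reltol)),
      error = function(e) e)
    if (inherits(res, "error")) { errs <- c(errs, conditionMessage(res)); next }
    n_ok <- n_ok + 1L
    if (res$value < best$loss)
      best <- list(loss = res$value, V = softmax(res$par))
  }
  if (n_ok == 0L)
    stopf("all V-search starts failed: %s",
          paste(unique(errs), collapse = "; "))
  V <- best$V / sum(best$V)
  W <- as.numeric(solve_w(V, X$X1, X$X0, ridge = control$ridge))
  list(V = V, W = W, loss = best$loss, n_converged = n_ok)
}
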