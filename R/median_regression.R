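#' Quantile check loss
#'
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u<0\})}; at the median
#' (\eqn{\tau = 0.5}) this is \eqn{|u|/2}.
#'
#' @param u numeric residuals.
#' @param tau quantile level.
#' @return total check loss (scalar).
#' @export
check_loss <- function(u, tau = 0.5) {
  sum(u * (tau - (u < 0)))
}

# One smoothed-IRLS solve. Weights 1/max(|r|, eps) reproduce the
# least-absolute-deviation estimate in the limit eps -> 0; for general tau
# the positive/negative sides are weighted tau and 1-tau.  At the median
# the IRLS estimate is then polished to the exact LAD vertex by a
# basis-exchange step with a dual-feasibility certificate (`lad_polish`):
# Lawson-type reweighting alone zigzags once p residuals pin at zero and
# can stall short of a 1e-8 coefficient tolerance.
irls_lad <- function(X, y, tau = 0.5, eps = 1e-6, max_iter = 200L,
                     tol = 1e-8, start = NULL, weights = NULL) {
  w_case <- if (is.null(weights)) rep(1, length(y)) else weights
  b <- if (is.null(start)) qr.coef(qr(X), y) else start
  converged <- FALSE
  iter <- 0L
  # at the median the exact polish certifies optimality, so IRLS only has
  # to reach its neighbourhood; without it, iterate to the full tolerance
  handoff <- if (tau == 0.5) 1e-4 else tol
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - drop(X %*% b)
    side <- ifelse(r >= 0, tau, 1 - tau)
    w <- w_case * side / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, w)
    b_new <- fit$coefficients
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
    if (tau == 0.5 && delta < handoff) break
  }
  if (tau == 0.5) {
    pol <- lad_polish(X, y, b, w_case)
    if (!is.null(pol)) {
      if (pol$certified) {
        b <- pol$coefficients
        converged <- TRUE
      } else if (!converged && length(y) <= 500L) {
        # degenerate optimum (ties: more zero residuals than parameters)
        # defeats the exchange certificate; solve the weighted problem
        # exactly instead -- w_i |y_i - x_i'b| = |w_i y_i - (w_i x_i)'b|
        b <- tryCatch({
          bs <- lad_simplex(w_case * X, w_case * y)
          converged <- TRUE
          as.numeric(bs)
        }, error = function(e) b)
        names(b) <- colnames(X)
      }
      iter <- iter + pol$iterations
    }
  }
  r <- y - drop(X %*% b)
  list(coefficients = b, iterations = iter, converged = converged,
       objective = sum(w_case * r * (tau - (r < 0))), residuals = r)
}

# Exact (weighted) LAD finishing step.  A LAD optimum interpolates p
# observations; starting from the IRLS estimate, pick the p
# smallest-|residual| rows (rank-completed), solve X_A beta = y_A, and
# test the subgradient optimality certificate: beta minimizes
# sum_i w_i |y_i - x_i' beta| iff g solving
# X_A' g = sum_{i not in A} w_i sign(r_i) x_i has all |g_i| <= w_i.
# While some |g_j| > w_j, move along the direction that frees row j
# (residuals of the other basis rows stay zero) to the first sign
# crossing and exchange.  Case weights let the bootstrap resample by
# multinomial weights on the original rows, which keeps the row set in
# general position (duplicated rows would make the exchange degenerate).
# Returns NULL if no nonsingular basis exists.
lad_polish <- function(X, y, b, w = NULL, tol = 1e-9, max_iter = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(max_iter)) max_iter <- 10L * (n + p)
  r <- y - drop(X %*% b)
  ord <- order(abs(r))
  # rank-greedy basis from the smallest residuals
  A <- integer(0)
  for (i in ord) {
    trial <- c(A, i)
    if (qr(X[trial, , drop = FALSE])$rank == length(trial)) A <- trial
    if (length(A) == p) break
  }
  if (length(A) < p) return(NULL)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(coefficients = b, certified = FALSE, iterations = iter))
    }
    XA <- X[A, , drop = FALSE]
    b <- drop(solve(XA, y[A]))
    r <- y - drop(X %*% b)
    out <- setdiff(seq_len(n), A)
    s <- sign(r[out])
    s[abs(r[out]) <= tol] <- 0          # ties sit at zero: no pull
    cvec <- drop(crossprod(X[out, , drop = FALSE], w[out] * s))
    g <- drop(solve(t(XA), cvec))
    viol <- abs(g) - w[A]
    j <- which.max(viol)
    if (viol[j] <= 1e-7) {
      names(b) <- colnames(X)
      return(list(coefficients = b, certified = TRUE, iterations = iter))
    }
    sigma <- sign(g[j])
    delta <- drop(solve(XA, diag(p)[, j]))     # x_i' delta = 1{i == A[j]}
    a <- sigma * drop(X[out, , drop = FALSE] %*% delta)
    tpos <- r[out] / a
    cand <- which(a != 0 & tpos > tol)
    if (!length(cand)) {
      # degenerate: allow zero-length steps on tied rows
      cand <- which(a != 0 & tpos >= -tol)
      if (!length(cand)) {
        return(list(coefficients = b, certified = FALSE, iterations = iter))
      }
    }
    tmin <- min(tpos[cand])
    enter <- out[cand[which(tpos[cand] <= tmin + tol)][1]]
    A[j] <- enter
  }
}

#' Median (quantile) regression with bootstrap standard errors
#'
#' Estimates the conditional quantile (default: the median) of the
#' outcome by minimizing the check loss
#' \eqn{\sum_i \rho_\tau(y_i - x_i^\top \beta)}.  The estimate is robust
#' to outliers in the outcome, which is why it is the primary model for
#' tract-level prevalence.  Solved by iteratively reweighted least
#' squares with smoothing floor `eps` on the absolute residuals;
#' convergence is declared when the largest coefficient change falls
#' below `tol`.  Non-convergence of the main fit is an error.
#'
#' Standard errors are nonparametric case-resampling bootstrap (rows
#' resampled with replacement, model refit, SE = standard deviation of
#' the replicate estimates) and p-values use the normal approximation
#' \eqn{2\Phi(-|\hat\beta|/SE)}.  Replicates that fail to converge are
#' dropped and counted in the diagnostics.
#'
#' @param table analysis table (complete cases used; dropped rows
#'   counted).
#' @param spec a [design_spec()].
#' @param tau quantile level (default 0.5; other quantiles are exposed
#'   but the package is exercised at the median).
#' @param se_boot_reps bootstrap replicates (default 200); 0 skips SEs.
#' @param seed integer seed for the bootstrap resampling.
#' @param eps IRLS smoothing floor on |residual| (default 1e-6).
#' @param max_iter maximum IRLS iterations (default 200).
#' @param tol convergence tolerance on the max coefficient change.
#' @return an `ftenv_fit` with method `"median"`; diagnostics carry
#'   iterations, convergence flag, final check loss, dropped rows and
#'   bootstrap replicates used.
#' @export
fit_median_regression <- function(table, spec, tau = 0.5,
                                  se_boot_reps = 200L, seed = NULL,
                                  eps = 1e-6, max_iter = 200L, tol = 1e-8) {
  d <- build_design(table, spec)
  X <- d$X; y <- d$y
  p <- ncol(X); n <- length(y)
  if (n < 10 * p) {
    warning(sprintf("only %d complete rows for %d parameters (< 10 per parameter)",
                    n, p), call. = FALSE)
  }
  fit <- irls_lad(X, y, tau = tau, eps = eps, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    stop(sprintf(paste0("median regression did not converge in %d iterations ",
                        "(last objective %.6g)"),
                 max_iter, fit$objective), call. = FALSE)
  }
  b <- fit$coefficients
  se <- rep(NA_real_, p); pv <- rep(NA_real_, p)
  names(se) <- names(pv) <- names(b)
  boot_used <- 0L
  if (se_boot_reps > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    est <- matrix(NA_real_, nrow = se_boot_reps, ncol = p)
    for (r in seq_len(se_boot_reps)) {
      # resample as multinomial case weights so the row set stays in
      # general position (duplicate rows degrade the exact polish)
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      sub <- w > 0L
      bf <- tryCatch(
        irls_lad(X[sub, , drop = FALSE], y[sub], tau = tau, eps = eps,
                 max_iter = max_iter, tol = tol, start = b,
                 weights = w[sub]),
        error = function(e) NULL)
      if (!is.null(bf) && bf$converged) est[r, ] <- bf$coefficients
    }
    ok <- stats::complete.cases(est)
    boot_used <- sum(ok)
    if (boot_used >= 2L) {
      se <- apply(est[ok, , drop = FALSE], 2, stats::sd)
      names(se) <- names(b)
      pv <- 2 * stats::pnorm(-abs(b / se))
    }
  }
  new_fit_result("median", b, se, pv, n,
                 diagnostics = list(iterations = fit$iterations,
                                    converged = fit$converged,
                                    objective = fit$objective,
                                    tau = tau,
                                    dropped_rows = d$dropped,
                                    boot_reps = se_boot_reps,
                                    boot_used = boot_used))
}

#' Exact least-absolute-deviation solution by linear programming
#'
#' Independent oracle for [fit_median_regression()]: solves
#' \deqn{\min_\beta \sum_i |y_i - x_i^\top\beta|}
#' exactly as the linear program
#' \eqn{\min \sum_i (u_i^+ + u_i^-)} subject to
#' \eqn{y - X\beta = u^+ - u^-}, \eqn{u^\pm \ge 0}, via a primal simplex
#' with Bland's rule (anti-cycling).  Intended for small instances
#' (n up to a few hundred).
#'
#' @param table analysis table.
#' @param spec a [design_spec()].
#' @return named coefficient vector attaining the minimal absolute-error
#'   objective (attribute `objective` carries \eqn{\sum|r|}).
#' @export
lad_lp_oracle <- function(table, spec) {
  d <- build_design(table, spec)
  lad_simplex(d$X, d$y)
}

# Primal simplex on min 1'u+ + 1'u- s.t. X(b+ - b-) + u+ - u- = y.
# Columns: [X | -X | I | -I]; Bland's rule for entering and leaving.
lad_simplex <- function(X, y, tol = 1e-9, max_iter = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(max_iter)) max_iter <- 100L * (n + p)
  A <- cbind(X, -X, diag(n), -diag(n))
  cost <- c(rep(0, 2 * p), rep(1, 2 * n))
  ncols <- 2 * p + 2 * n
  # feasible start: u+_i basic if y_i >= 0, else u-_i
  basis <- ifelse(y >= 0, 2 * p + seq_len(n), 2 * p + n + seq_len(n))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("LAD simplex iteration limit reached",
                              call. = FALSE)
    B <- A[, basis, drop = FALSE]
    xB <- solve(B, y)
    pi_ <- solve(t(B), cost[basis])
    red <- cost - drop(crossprod(A, pi_))
    red[basis] <- 0
    enter <- which(red < -tol)
    if (!length(enter)) break              # optimal
    e <- min(enter)                        # Bland: smallest index enters
    w <- solve(B, A[, e])
    pos <- which(w > tol)
    if (!length(pos)) stop("LAD linear program unbounded (degenerate design)",
                           call. = FALSE)
    ratio <- xB[pos] / w[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    leave <- cand[which.min(basis[cand])]  # Bland: smallest basic index leaves
    basis[leave] <- e
  }
  xfull <- numeric(ncols)
  xfull[basis] <- xB
  beta <- xfull[seq_len(p)] - xfull[p + seq_len(p)]
  names(beta) <- colnames(X)
  structure(beta, objective = sum(abs(y - drop(X %*% beta))),
            iterations = iter)
}
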