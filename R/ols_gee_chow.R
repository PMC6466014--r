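#' Ordinary least squares sensitivity model
#'
#' Companion linear model for the median regression: same design,
#' classical (model-based) standard errors, t-distribution p-values.
#'
#' @param table analysis table.
#' @param spec a [design_spec()].
#' @return an `ftenv_fit` with method `"ols"`.
#' @export
fit_ols <- function(table, spec) {
  d <- build_design(table, spec)
  X <- d$X; y <- d$y
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  b <- qr.coef(qrX, y)
  res <- y - drop(X %*% b)
  ssr <- sum(res^2)
  df <- n - p
  sigma2 <- if (df > 0) ssr / df else 0
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * diag(XtX_inv), 0))
  names(se) <- names(b)
  tstat <- b / se
  pv <- 2 * stats::pt(-abs(tstat), df = max(df, 1))
  pv[se == 0] <- ifelse(b[se == 0] == 0, NA_real_, 0)
  new_fit_result("ols", b, se, pv, n,
                 diagnostics = list(sigma2 = sigma2, ssr = ssr, df = df,
                                    dropped_rows = d$dropped))
}

#' GEE temporal trend in state-year means
#'
#' Marginal Gaussian model with identity link for repeated state-level
#' measurements: outcome = state-year mean (e.g. average calories per
#' food post), regressor = calendar year centered at `center_year`,
#' clusters = states, exchangeable working correlation (independence
#' also available), robust (sandwich) standard errors, normal p-values.
#'
#' @param data data.frame with columns `state`, `year`, `value`.
#' @param corstr working correlation: `"exchangeable"` or
#'   `"independence"`.
#' @param center_year year subtracted from `year` before fitting
#'   (default 2015), so the intercept is the expected value in that year.
#' @param max_iter,tol iteration control for the working-correlation
#'   update.
#' @return an `ftenv_fit` with method `"gee"`; coefficient `year` is the
#'   trend per calendar year.  Diagnostics carry the estimated working
#'   correlation `alpha` and scale `phi`.
#' @export
fit_gee_trend <- function(data, corstr = c("exchangeable", "independence"),
                          center_year = 2015, max_iter = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  need <- c("state", "year", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data must have columns state, year, value",
                         call. = FALSE)
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  cl <- split(seq_len(nrow(data)), data$state)
  if (length(cl) < 2L) {
    stop("need at least 2 state clusters for robust GEE standard errors",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, year = data$year - center_year)
  y <- data$value
  n <- length(y); p <- ncol(X)
  b <- qr.coef(qr(X), y)
  alpha <- 0
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% b)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni > 1) {
          s <- sum(r[ix])
          num <- num + (s^2 - sum(r[ix]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha_new <- if (npairs > p) (num / phi) / (npairs - p) else 0
      alpha_new <- min(max(alpha_new, -0.99), 0.99)
    } else {
      alpha_new <- 0
    }
    # GLS step under the working correlation
    M <- matrix(0, p, p); v <- numeric(p)
    for (ix in cl) {
      Xi <- X[ix, , drop = FALSE]
      Ri <- working_corr(length(ix), alpha_new)
      Wi <- solve(Ri)
      M <- M + crossprod(Xi, Wi %*% Xi)
      v <- v + crossprod(Xi, Wi %*% y[ix])
    }
    b_new <- drop(solve(M, v))
    done <- max(abs(b_new - b)) < tol && abs(alpha_new - alpha) < tol
    b <- b_new; alpha <- alpha_new
    if (done) break
  }
  names(b) <- colnames(X)
  # sandwich variance
  r <- y - drop(X %*% b)
  M <- matrix(0, p, p); Bmat <- matrix(0, p, p)
  for (ix in cl) {
    Xi <- X[ix, , drop = FALSE]
    Wi <- solve(working_corr(length(ix), alpha))
    XtW <- crossprod(Xi, Wi)
    M <- M + XtW %*% Xi
    g <- XtW %*% r[ix]
    Bmat <- Bmat + g %*% t(g)
  }
  Minv <- solve(M)
  V <- Minv %*% Bmat %*% Minv
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(b)
  pv <- 2 * stats::pnorm(-abs(b / se))
  pv[se == 0] <- ifelse(b[se == 0] == 0, NA_real_, 0)
  new_fit_result("gee", b, se, pv, n,
                 diagnostics = list(alpha = alpha,
                                    phi = sum(r^2) / (n - p),
                                    n_clusters = length(cl),
                                    corstr = corstr,
                                    center_year = center_year))
}

working_corr <- function(ni, alpha) {
  R <- matrix(alpha, ni, ni)
  diag(R) <- 1
  R
}

#' Chow test for coefficient differences between two groups
#'
#' Tests whether the same linear design has different coefficients in
#' two groups (e.g. male- vs female-specific obesity models) by
#' comparing the pooled residual sum of squares with the sum of the
#' group-specific ones:
#' \deqn{F = \frac{(SSR_{pooled} - SSR_A - SSR_B)/k}
#'            {(SSR_A + SSR_B)/(n_A + n_B - 2k)}}
#' with \eqn{k} parameters (intercept included); p-value from
#' \eqn{F(k,\, n_A + n_B - 2k)}.
#'
#' @param table_a,table_b group analysis tables.
#' @param spec shared [design_spec()].
#' @return list with `statistic`, `p_value`, `df1`, `df2` and the three
#'   residual sums of squares.
#' @export
chow_test <- function(table_a, table_b, spec) {
  ssr_of <- function(tab) {
    d <- build_design(tab, spec)
    b <- qr.coef(qr(d$X), d$y)
    list(ssr = sum((d$y - drop(d$X %*% b))^2), n = length(d$y),
        k = ncol(d$X))
  }
  fa <- ssr_of(table_a)
  fb <- ssr_of(table_b)
  k <- fa$k
  cols <- c(spec$outcome, spec$exposures, spec$covariates)
  pooled <- rbind(table_a[, cols, drop = FALSE], table_b[, cols, drop = FALSE])
  fp <- ssr_of(pooled)
  df2 <- fa$n + fb$n - 2 * k
  if (df2 <= 0) {
    stop("too few observations for the Chow test: n_A + n_B <= 2k",
         call. = FALSE)
  }
  Fstat <- ((fp$ssr - fa$ssr - fb$ssr) / k) / ((fa$ssr + fb$ssr) / df2)
  Fstat <- max(Fstat, 0)          # guard tiny negative float noise
  list(statistic = Fstat,
       p_value = stats::pf(Fstat, k, df2, lower.tail = FALSE),
       df1 = k, df2 = df2,
       ssr_pooled = fp$ssr, ssr_a = fa$ssr, ssr_b = fb$ssr)
}
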