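#' Describe a regression design
#'
#' Names the outcome, the exposure columns of interest (typically the
#' three standardized food-environment variables) and the adjustment
#' covariates.  Used by all model fitters so that every model in a run
#' shares one definition of the design.
#'
#' @param outcome outcome column name.
#' @param exposures character vector of exposure column names.
#' @param covariates character vector of covariate column names.
#' @param intercept include an intercept (default TRUE).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(outcome, exposures,
                        covariates = character(0), intercept = TRUE) {
  nm <- c(outcome, exposures, covariates)
  if (anyDuplicated(nm)) {
    stop("duplicated column name in design: ",
         paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  }
  structure(list(outcome = outcome, exposures = as.character(exposures),
                 covariates = as.character(covariates),
                 intercept = isTRUE(intercept)),
            class = "design_spec")
}

# Build y and the model matrix from an analysis table, complete cases
# only. Errors on missing columns and rank deficiency.
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "design_spec"))
  cols <- c(spec$outcome, spec$exposures, spec$covariates)
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("column(s) not in analysis table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[, cols, drop = FALSE]
  cc <- stats::complete.cases(dat)
  dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  y <- as.numeric(dat[[spec$outcome]])
  xcols <- c(spec$exposures, spec$covariates)
  X <- as.matrix(dat[, xcols, drop = FALSE])
  storage.mode(X) <- "double"
  if (spec$intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(y = y, X = X, dropped = dropped)
}

new_fit_result <- function(method, coefficients, standard_errors, p_values,
                           n_obs, diagnostics = list()) {
  stopifnot(identical(names(coefficients), names(standard_errors)),
            identical(names(coefficients), names(p_values)))
  structure(list(method = method, coefficients = coefficients,
                 standard_errors = standard_errors, p_values = p_values,
                 n_obs = n_obs, diagnostics = diagnostics),
            class = "ftenv_fit")
}

#' @export
print.ftenv_fit <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d\n", x$method, x$n_obs))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fit
#'
#' @param x an `ftenv_fit`.
#' @param ... unused.
#' @return data.frame with columns variable, beta, se, p.
#' @export
as.data.frame.ftenv_fit <- function(x, ...) {
  data.frame(variable = names(x$coefficients),
             beta = unname(x$coefficients),
             se = unname(x$standard_errors),
             p = unname(x$p_values),
             stringsAsFactors = FALSE)
}
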