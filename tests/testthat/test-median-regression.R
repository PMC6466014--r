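test_that("perfect linear data is fit exactly", {
  tab <- data.frame(x = seq_len(20))
  tab$y <- 2 * tab$x
  fit <- fit_median_regression(tab, design_spec("y", "x"), se_boot_reps = 0)
  expect_equal(unname(fit$coefficients[["x"]]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 0,
               tolerance = 1e-6)
  expect_lt(fit$diagnostics$objective, 1e-8)
  expect_true(fit$diagnostics$converged)
})

test_that("the median fit shrugs off an outlier that drags OLS", {
  tab <- data.frame(x = c(0, 1, 2, 3, 4), y = c(0, 1, 2, 3, 100))
  spec <- design_spec("y", "x")
  lp <- lad_lp_oracle(tab, spec)
  med <- suppressWarnings(fit_median_regression(tab, spec, se_boot_reps = 0))
  ols <- suppressWarnings(fit_ols(tab, spec))
  expect_equal(unname(med$coefficients[["x"]]), unname(lp[["x"]]),
               tolerance = 1e-8)
  expect_equal(unname(med$coefficients[["x"]]), 1, tolerance = 1e-8)
  expect_gt(ols$coefficients[["x"]], 5)
})

test_that("median fit never loses to OLS on check loss", {
  set.seed(41)
  for (rep in 1:10) {
    tab <- sim_table(n = 60, sd = 1, seed = rep)
    spec <- design_spec("y", c("x1", "x2"))
    med <- fit_median_regression(tab, spec, se_boot_reps = 0)
    ols <- fit_ols(tab, spec)
    d <- build_design(tab, spec)
    loss_ols <- check_loss(d$y - drop(d$X %*% ols$coefficients))
    expect_lte(med$diagnostics$objective, loss_ols + 1e-10)
  }
})

test_that("LP oracle solves degenerate and constant designs", {
  tab <- data.frame(x = 1:7, y = rep(3.5, 7))
  co <- lad_lp_oracle(tab, design_spec("y", "x"))
  expect_equal(unname(co[["(Intercept)"]]), 3.5, tolerance = 1e-10)
  expect_equal(unname(co[["x"]]), 0, tolerance = 1e-10)
})

test_that("IRLS matches the LP optimum on random instances", {
  set.seed(42)
  for (i in 1:30) {
    inst <- random_lad_instance(n_max = 120, p_max = 5)
    d <- build_design(inst$table, inst$spec)
    lp <- lad_lp_oracle(inst$table, inst$spec)
    fit <- suppressWarnings(
      fit_median_regression(inst$table, inst$spec, se_boot_reps = 0))
    obj_lp <- attr(lp, "objective") / 2          # check loss at tau = 0.5
    expect_lte(fit$diagnostics$objective, obj_lp * (1 + 1e-4) + 1e-12)
  }
})

test_that("median regression is scale and shift equivariant", {
  tab <- sim_table(n = 70, seed = 9)
  spec <- design_spec("y", c("x1", "x2"))
  base <- fit_median_regression(tab, spec, se_boot_reps = 0)

  tab_scaled <- tab; tab_scaled$y <- 3 * tab$y
  scaled <- fit_median_regression(tab_scaled, spec, se_boot_reps = 0)
  expect_equal(scaled$coefficients, 3 * base$coefficients,
               tolerance = 1e-6)

  tab_shift <- tab; tab_shift$y <- tab$y + 10
  shifted <- fit_median_regression(tab_shift, spec, se_boot_reps = 0)
  expect_equal(shifted$coefficients[["(Intercept)"]],
               base$coefficients[["(Intercept)"]] + 10, tolerance = 1e-6)
  expect_equal(shifted$coefficients[c("x1", "x2")],
               base$coefficients[c("x1", "x2")], tolerance = 1e-6)
})

test_that("bootstrap SEs are seeded and reproducible", {
  tab <- sim_table(n = 80, seed = 3)
  spec <- design_spec("y", c("x1", "x2"))
  f1 <- fit_median_regression(tab, spec, se_boot_reps = 50, seed = 7)
  f2 <- fit_median_regression(tab, spec, se_boot_reps = 50, seed = 7)
  expect_identical(f1$standard_errors, f2$standard_errors)
  expect_true(all(f1$standard_errors > 0))
  expect_true(all(f1$p_values >= 0 & f1$p_values <= 1))
  expect_equal(f1$diagnostics$boot_used, 50L)
})

test_that("degenerate designs fail loudly", {
  tab <- sim_table(n = 50, seed = 2)
  tab$x3 <- tab$x1            # exact collinearity
  expect_error(
    fit_median_regression(tab, design_spec("y", c("x1", "x2", "x3")),
                          se_boot_reps = 0),
    "collinear.*x3")
  expect_error(design_spec("y", c("x1", "x1")), "duplicated")
  expect_error(
    fit_median_regression(tab, design_spec("y", "nope"), se_boot_reps = 0),
    "not in analysis table")
})

test_that("small samples warn about parameter count", {
  tab <- sim_table(n = 15, seed = 4)
  expect_warning(
    fit_median_regression(tab, design_spec("y", c("x1", "x2")),
                          se_boot_reps = 0),
    "complete rows")
})
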