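records_df <- function(tract_id, cal, healthy = FALSE, fastfood = FALSE) {
  data.frame(tract_id = tract_id, caloric_density = cal,
             is_healthy = healthy, is_fastfood = fastfood,
             stringsAsFactors = FALSE)
}

test_that("aggregate_tracts computes means and percentages", {
  env <- aggregate_tracts(records_df("a", c(100, 300),
                                     healthy = c(TRUE, FALSE)))
  expect_equal(env$mean_calories, 200)
  expect_equal(env$pct_healthy, 50)
  expect_equal(env$pct_fastfood, 0)

  env1 <- aggregate_tracts(records_df("b", 50, healthy = TRUE,
                                      fastfood = TRUE))
  expect_equal(env1$pct_healthy, 100)
  expect_equal(env1$pct_fastfood, 100)

  env3 <- aggregate_tracts(records_df("c", c(0, 0, 600)))
  expect_equal(env3$mean_calories, 200)
})

test_that("aggregation conserves record counts and respects bounds", {
  set.seed(31)
  n <- 500
  rec <- records_df(sample(sprintf("t%02d", 1:20), n, TRUE),
                    runif(n, 0, 900), runif(n) < 0.3, runif(n) < 0.2)
  rec$tract_id[1:10] <- NA
  envs <- aggregate_tracts(rec)
  expect_equal(sum(envs$n_food_tweets), sum(!is.na(rec$tract_id)))
  expect_true(all(envs$pct_healthy >= 0 & envs$pct_healthy <= 100))
  expect_true(all(envs$pct_fastfood >= 0 & envs$pct_fastfood <= 100))
  for (k in seq_len(nrow(envs))) {
    sub <- rec$caloric_density[!is.na(rec$tract_id) &
                               rec$tract_id == envs$tract_id[k]]
    expect_gte(envs$mean_calories[k], min(sub))
    expect_lte(envs$mean_calories[k], max(sub))
  }
})

test_that("minimum-post filter keeps exactly-at-threshold tracts", {
  envs <- aggregate_tracts(records_df(
    rep(c("a", "b", "c"), times = c(9, 10, 11)), 100))
  flt <- filter_min_tweets(envs, 10)
  expect_setequal(flt$envs$tract_id, c("b", "c"))
  expect_equal(flt$excluded, 1L)

  all_kept <- filter_min_tweets(envs, 1)
  expect_equal(nrow(all_kept$envs), 3L)
  expect_error(filter_min_tweets(envs, 0), "min_tweets")

  empty <- filter_min_tweets(envs[0, ], 10)
  expect_equal(nrow(empty$envs), 0L)
  expect_equal(empty$excluded, 0L)
})

test_that("standardize produces exact z-scores and round-trips", {
  tab <- data.frame(mean_calories = c(1, 2, 3),
                    pct_healthy = c(10, 30, 50),
                    pct_fastfood = c(5, 10, 30))
  z <- standardize(tab)
  expect_equal(z$z_mean_calories, c(-1, 0, 1))
  for (v in c("z_mean_calories", "z_pct_healthy", "z_pct_fastfood")) {
    expect_lt(abs(mean(z[[v]])), 1e-9)
    expect_lt(abs(sd(z[[v]]) - 1), 1e-9)
  }
  # destandardize round-trip
  ctr <- attr(z, "z_center"); scl <- attr(z, "z_scale")
  back <- z$z_pct_healthy * scl[["pct_healthy"]] + ctr[["pct_healthy"]]
  expect_equal(back, tab$pct_healthy, tolerance = 1e-12)

  tab$pct_fastfood <- 7
  expect_error(standardize(tab), "constant variable: pct_fastfood")
  expect_error(standardize(tab[1, , drop = FALSE]), "at least 2")
})

test_that("merge_outcomes inner-joins and reports drops", {
  envs <- data.frame(tract_id = c("A", "B", "C"), mean_calories = 1:3,
                     pct_healthy = 1:3, pct_fastfood = 1:3)
  outc <- data.frame(tract_id = c("B", "C", "D"), obesity = c(30, 31, 32))
  mg <- merge_outcomes(envs, outc)
  expect_setequal(mg$table$tract_id, c("B", "C"))
  expect_equal(mg$dropped_envs, 1L)
  expect_equal(mg$dropped_outcomes, 1L)

  expect_warning(
    empty <- merge_outcomes(envs,
                            data.frame(tract_id = "Z", obesity = 1)),
    "no tracts in common")
  expect_equal(nrow(empty$table), 0L)

  dup <- data.frame(tract_id = c("B", "B"), obesity = c(1, 2))
  expect_error(merge_outcomes(envs, dup), "duplicate tract_id")
})

test_that("state summaries pool posts, not tracts", {
  envs <- aggregate_tracts(records_df(
    rep(c("0100000001", "0100000002"), times = c(10, 30)),
    100, fastfood = rep(c(TRUE, FALSE), times = c(1, 9)) ))
  # tract percentages: 10% (n=10) and 30% (n=30)
  envs$n_fastfood <- c(1L, 9L)
  envs$pct_fastfood <- 100 * envs$n_fastfood / envs$n_food_tweets
  ss <- state_summary(envs)
  expect_equal(ss$summary$pct_fastfood, 25)        # pooled 10/40
  ss_tract <- state_summary(envs, weighting = "tract")
  expect_equal(ss_tract$summary$pct_fastfood, 20)  # plain tract mean

  single <- state_summary(envs[1, , drop = FALSE])
  expect_equal(single$summary$pct_fastfood, envs$pct_fastfood[1])
  expect_equal(single$summary$mean_calories, envs$mean_calories[1])

  # unmappable tracts are skipped and counted
  sm <- data.frame(tract_id = envs$tract_id[1], state = "01")
  ss2 <- state_summary(envs, sm)
  expect_equal(ss2$unmapped, 1L)
  expect_equal(nrow(ss2$summary), 1L)
})
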