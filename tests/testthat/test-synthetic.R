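small_cfg <- function(...) {
  synth_config(seed = 5, n_states = 2, tracts_per_state = 8,
               tweets_per_tract_mean = 40, ...)
}

test_that("tract grid tiles disjoint squares with GEOID-style ids", {
  cfg <- synth_config(seed = 1, n_states = 2, tracts_per_state = 4)
  grid <- gen_tract_grid(cfg)
  expect_length(grid$tracts$tract_id, 8L)
  expect_true(all(nchar(grid$tracts$tract_id) == 11L))
  expect_equal(state_from_geoid(grid$tracts$tract_id), grid$state_map$state)
  # disjoint interiors: no centroid is contained in another tract
  bb <- grid$tracts$bbox
  cx <- (bb[, 1] + bb[, 2]) / 2; cy <- (bb[, 3] + bb[, 4]) / 2
  for (k in seq_len(8)) {
    inside <- vapply(seq_len(8), function(j) {
      point_in_tract(cx[k], cy[k], grid$tracts$geoms[[j]])
    }, logical(1))
    expect_equal(which(inside), k)
  }
})

test_that("tract centroids assign back to their own tract", {
  grid <- gen_tract_grid(small_cfg())
  bb <- grid$tracts$bbox
  rec <- data.frame(lon = (bb[, 1] + bb[, 2]) / 2,
                    lat = (bb[, 3] + bb[, 4]) / 2)
  asn <- assign_tracts(rec, grid$tracts)
  expect_identical(asn$records$tract_id, grid$tracts$tract_id)
  expect_equal(asn$unassigned, 0L)
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "synthA"); d2 <- file.path(tempdir(), "synthB")
  cfg <- small_cfg()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in c("tweets.jsonl", "tracts.geojson", "lexicon.csv",
              "outcomes.csv", "covariates.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero food fraction yields a foodless stream", {
  cfg <- small_cfg(food_fraction = 0, job_fraction = 0)
  dir <- file.path(tempdir(), "nofood")
  b <- simulate_bundle(cfg, dir, min_tweets = 1)
  expect_equal(unname(b$counters["food"]), 0L)
  expect_equal(nrow(b$records), 0L)
})

test_that("the job fraction shows up in the job-filtered counter", {
  cfg <- synth_config(seed = 17, n_states = 2, tracts_per_state = 10,
                      tweets_per_tract_mean = 60, job_fraction = 0.1)
  b <- simulate_bundle(cfg, file.path(tempdir(), "jobs"), min_tweets = 1)
  n <- unname(b$counters["lines"])
  phat <- unname(b$counters["job_filtered"]) / n
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("measured healthy share tracks the latent propensity", {
  cfg <- synth_config(seed = 23, n_states = 2, tracts_per_state = 15,
                      tweets_per_tract_mean = 200, food_fraction = 0.9,
                      job_fraction = 0)
  b <- simulate_bundle(cfg, file.path(tempdir(), "prop"), min_tweets = 1)
  lat <- b$truth$latent_propensities
  m <- merge(b$envs, lat, by = "tract_id")
  expect_gt(cor(m$pct_healthy, m$p_healthy, method = "spearman"), 0.8)
  expect_gt(cor(m$pct_fastfood, m$p_fastfood, method = "spearman"), 0.6)
})

test_that("planted effects are recovered exactly without noise", {
  cfg <- synth_config(seed = 29, n_states = 3, tracts_per_state = 20,
                      tweets_per_tract_mean = 60, noise_sd = 0,
                      covariate_effects = c(pop_density = 0))
  b <- simulate_bundle(cfg, file.path(tempdir(), "exact"))
  mg <- merge_outcomes(b$filtered$envs, b$outcomes)
  an <- standardize(mg$table)
  spec <- design_spec("obesity", c("z_mean_calories", "z_pct_healthy",
                                   "z_pct_fastfood"))
  fit <- fit_median_regression(an, spec, se_boot_reps = 0)
  planted <- cfg$planted_effects["obesity", ]
  expect_equal(unname(fit$coefficients[-1]), unname(planted),
               tolerance = 1e-6)
  expect_equal(b$clipped, 0L)
})

test_that("median regression resists contamination better than OLS", {
  # asymmetric contamination on top of Laplace noise: median regression
  # should track the planted calorie effect with less bias than OLS
  bias_med <- c(); bias_ols <- c()
  for (s in 1:3) {
    cfg <- synth_config(seed = 100 + s, n_states = 3, tracts_per_state = 20,
                        tweets_per_tract_mean = 60, noise_sd = 0.5,
                        noise_kind = "laplace")
    b <- simulate_bundle(cfg, file.path(tempdir(), paste0("cont", s)))
    mg <- merge_outcomes(b$filtered$envs, b$outcomes, b$covariates)
    an <- standardize(mg$table)
    set.seed(s)
    dirty <- sample.int(nrow(an), round(0.1 * nrow(an)))
    an$obesity[dirty] <- an$obesity[dirty] + 25    # one-sided outliers
    spec <- design_spec("obesity",
                        c("z_mean_calories", "z_pct_healthy",
                          "z_pct_fastfood"),
                        intersect(names(an), c("pop_density", "pct_65older",
                                               "urban")))
    planted <- cfg$planted_effects["obesity", "mean_calories"]
    med <- suppressWarnings(fit_median_regression(an, spec, se_boot_reps = 0))
    ols <- fit_ols(an, spec)
    bias_med <- c(bias_med, med$coefficients[["z_mean_calories"]] - planted)
    bias_ols <- c(bias_ols, ols$coefficients[["z_mean_calories"]] - planted)
  }
  expect_lt(mean(abs(bias_med)), mean(abs(bias_ols)) + 0.02)
})

test_that("yearly calorie drift is planted in the stream", {
  cfg <- synth_config(seed = 37, n_states = 3, tracts_per_state = 15,
                      tweets_per_tract_mean = 150, food_fraction = 0.6,
                      job_fraction = 0)
  b <- simulate_bundle(cfg, file.path(tempdir(), "drift"), min_tweets = 1)
  yearly <- tapply(b$records$caloric_density, b$records$year, mean)
  years <- as.integer(names(yearly))
  slope <- coef(lm(yearly ~ years))[["years"]]
  expect_gt(slope, 0.4 * cfg$trend_kcal_per_year)
  expect_lt(slope, 2.0 * cfg$trend_kcal_per_year)
})

test_that("config validation catches nonsense", {
  expect_error(synth_config(n_states = 0), "at least one")
  expect_error(synth_config(food_fraction = 1.2), "food_fraction")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})
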