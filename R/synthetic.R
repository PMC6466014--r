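#' Reference planted effect sizes
#'
#' Default z-scale effects used by the synthetic generator: the change in
#' outcome prevalence (percentage points) per one standard deviation of
#' each tract food-environment variable.  The defaults are sized like
#' published census-tract associations between social-media food
#' indicators and cardiometabolic outcomes: small positive effects of
#' caloric density and fast-food share on obesity and hypertension, a
#' protective effect of healthy-food share, and null-ish diabetes
#' effects.
#'
#' @return 3 x 3 numeric matrix; rows obesity, diabetes, hypertension;
#'   columns mean_calories, pct_healthy, pct_fastfood.
#' @export
default_planted_effects <- function() {
  m <- rbind(
    obesity      = c(0.19, -0.30, 0.15),
    diabetes     = c(0.02, -0.02, -0.02),
    hypertension = c(0.16, -0.13, 0.12)
  )
  colnames(m) <- c("mean_calories", "pct_healthy", "pct_fastfood")
  m
}

covariate_names <- function() {
  c("pop_density", "pct_65older", "pct_male", "pct_black", "pct_hispanic",
    "urban", "pct_relatives", "pct_unmarried", "household_size",
    "pct_owner_occupied", "income_inequality")
}

#' Synthetic-world configuration
#'
#' One object holding every knob of the synthetic data world: geography,
#' post volume, latent tract propensities, planted regression effects,
#' covariate effects, outcome noise and the yearly calorie drift.
#' Defaults describe a desk-scale world of 10 states x 60 tracts with
#' ~80 posts per tract.
#'
#' @param seed integer RNG seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @param n_states,tracts_per_state synthetic geography size.
#' @param cell_deg tract square edge, degrees.
#' @param tweets_per_tract_mean Poisson mean posts per tract.
#' @param food_fraction probability a (non-job) post is a food post.
#' @param job_fraction probability a post is a job posting (these mention
#'   food, so they exercise the filter order).
#' @param healthy_shape,fastfood_shape Beta(a, b) shapes for the latent
#'   per-tract healthy / fast-food propensities; the default Beta(2, 10)
#'   has mean ~0.17, matching the 7-23% state-level mention shares seen
#'   in real food-post data.
#' @param terms_per_tweet integer choices for food terms per food post.
#' @param years calendar years covered.
#' @param trend_kcal_per_year planted yearly drift in expected calories
#'   per food post (default 15.87 kcal/year).
#' @param planted_effects outcome x exposure matrix of z-scale effects
#'   (default [default_planted_effects()]).
#' @param baselines named baseline prevalences (%).
#' @param covariate_effects named per-SD contributions of the 11
#'   demographic covariates to every outcome.
#' @param noise_sd outcome noise standard deviation (percentage points).
#' @param noise_kind `"gaussian"` or `"laplace"`.
#' @param sex_effect_delta added to the calorie effect in the
#'   female-specific obesity surface (0 = identical male/female models).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_states = 10L,
                         tracts_per_state = 60L,
                         cell_deg = 0.05,
                         tweets_per_tract_mean = 80,
                         food_fraction = 0.35,
                         job_fraction = 0.05,
                         healthy_shape = c(2, 10),
                         fastfood_shape = c(2, 10),
                         terms_per_tweet = 1:3,
                         years = 2015:2018,
                         trend_kcal_per_year = 15.87,
                         planted_effects = default_planted_effects(),
                         baselines = c(obesity = 30, diabetes = 10,
                                       hypertension = 32),
                         covariate_effects = c(
                           pop_density = 0.3, pct_65older = 0.5,
                           pct_male = -0.2, pct_black = 0.4,
                           pct_hispanic = 0.2, urban = 0.5,
                           pct_relatives = 0.1, pct_unmarried = 0.1,
                           household_size = 0.2,
                           pct_owner_occupied = -0.3,
                           income_inequality = 0.4),
                         noise_sd = 1.0,
                         noise_kind = c("gaussian", "laplace"),
                         sex_effect_delta = 0) {
  noise_kind <- match.arg(noise_kind)
  if (n_states < 1 || tracts_per_state < 1) {
    stop("need at least one state and one tract per state", call. = FALSE)
  }
  if (food_fraction < 0 || food_fraction > 1 || job_fraction < 0 ||
      job_fraction >= 1) {
    stop("food_fraction must be in [0,1], job_fraction in [0,1)",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_states = as.integer(n_states),
    tracts_per_state = as.integer(tracts_per_state), cell_deg = cell_deg,
    tweets_per_tract_mean = tweets_per_tract_mean,
    food_fraction = food_fraction, job_fraction = job_fraction,
    healthy_shape = healthy_shape, fastfood_shape = fastfood_shape,
    terms_per_tweet = as.integer(terms_per_tweet), years = as.integer(years),
    trend_kcal_per_year = trend_kcal_per_year,
    planted_effects = planted_effects, baselines = baselines,
    covariate_effects = covariate_effects, noise_sd = noise_sd,
    noise_kind = noise_kind, sex_effect_delta = sex_effect_delta
  ), class = "synth_config")
}

#' The bundled stand-in food lexicon
#'
#' Loads the ~60-term synthetic lexicon shipped with the package
#' (`inst/extdata/lexicon_synthetic.csv`).  It is a hand-made stand-in
#' with plausible kcal/100 g values, *not* a nutrient-database extract;
#' any user lexicon CSV with the same columns can replace it.
#'
#' @return a `food_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon_synthetic.csv",
                           package = "foodtweetenv", mustWork = TRUE))
}

#' Generate the synthetic tract grid
#'
#' Non-overlapping axis-aligned square tracts tiling one rectangle per
#' state; states are laid out side by side with a gap.  Tract ids follow
#' the real GEOID layout (11 characters, first two = state code), so
#' [state_from_geoid()] works on them.  Purely deterministic: no RNG.
#'
#' @param cfg a [synth_config()].
#' @return list with `tracts` (a `tract_set`) and `state_map`
#'   (data.frame tract_id, state).
#' @export
gen_tract_grid <- function(cfg) {
  ncols <- ceiling(sqrt(cfg$tracts_per_state))
  nrows <- ceiling(cfg$tracts_per_state / ncols)
  d <- cfg$cell_deg
  ids <- character(0); geoms <- list(); states <- character(0)
  for (s in seq_len(cfg$n_states)) {
    sx <- (s - 1) * (ncols + 2) * d      # 2-cell gap between states
    scode <- sprintf("%02d", s)
    for (t in seq_len(cfg$tracts_per_state)) {
      i <- (t - 1) %% ncols
      j <- (t - 1) %/% ncols
      x0 <- sx + i * d; y0 <- j * d
      ring <- rbind(c(x0, y0), c(x0 + d, y0), c(x0 + d, y0 + d),
                    c(x0, y0 + d), c(x0, y0))
      ids <- c(ids, paste0(scode, sprintf("%09d", t)))
      geoms[[length(geoms) + 1L]] <- list(list(ring))
      states <- c(states, scode)
    }
  }
  list(tracts = new_tract_set(ids, geoms),
       state_map = data.frame(tract_id = ids, state = states,
                              stringsAsFactors = FALSE))
}

#' Write a tract set as GeoJSON
#'
#' @param tracts a `tract_set`.
#' @param path output path.
#' @param id_property property name for the tract id (default `GEOID`).
#' @return `path`, invisibly.
#' @export
write_tracts_geojson <- function(tracts, path, id_property = "GEOID") {
  feat <- lapply(seq_along(tracts$tract_id), function(k) {
    parts <- tracts$geoms[[k]]
    coords <- lapply(parts, function(part) {
      lapply(part, function(ring) {
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
      })
    })
    geometry <- if (length(parts) == 1L) {
      list(type = "Polygon", coordinates = coords[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    props <- list(); props[[id_property]] <- tracts$tract_id[k]
    list(type = "Feature", properties = props, geometry = geometry)
  })
  gj <- list(type = "FeatureCollection", features = feat)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# Per-tract latent propensities, deterministic given the seeded RNG state.
draw_propensities <- function(cfg, tract_id) {
  n <- length(tract_id)
  p_h <- stats::rbeta(n, cfg$healthy_shape[1], cfg$healthy_shape[2])
  p_f <- stats::rbeta(n, cfg$fastfood_shape[1], cfg$fastfood_shape[2])
  over <- p_h + p_f > 0.95
  scl <- ifelse(over, 0.95 / (p_h + p_f), 1)
  data.frame(tract_id = tract_id, p_healthy = p_h * scl,
             p_fastfood = p_f * scl, stringsAsFactors = FALSE)
}

# Exponential-tilt weights over a calorie pool so the weighted mean hits
# `target`; solves for the tilt rate by root finding.
calorie_tilt_weights <- function(cal, target) {
  if (length(cal) == 1L) return(1)
  z <- (cal - mean(cal)) / stats::sd(cal)    # overflow-safe scale
  lim <- 30
  # weighted mean is monotone in the tilt; clamp target inside the
  # attainable range at |g| = lim
  wm <- function(g) { w <- exp(g * z - max(g * z)); sum(w * cal) / sum(w) }
  target <- min(max(target, wm(-lim) + 1e-9), wm(lim) - 1e-9)
  g <- stats::uniroot(function(g) wm(g) - target,
                      lower = -lim, upper = lim, tol = 1e-12)$root
  w <- exp(g * z - max(g * z))
  w / sum(w)
}

filler_words <- function() {
  c("good", "morning", "sunny", "day", "walking", "around", "downtown",
    "with", "friends", "after", "the", "game", "and", "then", "some",
    "music", "before", "heading", "home", "tonight", "weekend", "vibes",
    "lovely", "view", "from", "here")
}

#' Generate a synthetic geotagged post stream
#'
#' Per tract, `Poisson(tweets_per_tract_mean)` posts uniformly placed in
#' the tract square.  A post is a job posting with probability
#' `job_fraction` (its text contains an exclusion phrase *and* a food
#' term, exercising the filter order), otherwise a food post with
#' probability `food_fraction`.  Food posts embed 1-3 lexicon terms in
#' filler text, with the term class driven by the tract's latent healthy
#' and fast-food propensities and the term-within-class choice tilted by
#' year so that the expected calories per food post drift upward by
#' `trend_kcal_per_year`.
#'
#' Call under a seeded RNG (e.g. via [simulate_bundle()]) for
#' reproducibility.
#'
#' @param cfg a [synth_config()].
#' @param tracts a `tract_set` from [gen_tract_grid()].
#' @param lex a `food_lexicon`.
#' @param propensities data.frame from `draw_propensities` (internal);
#'   generated when `NULL`.
#' @return list with `lines` (character JSONL lines) and `truth`
#'   (data.frame of per-tract latent propensities).
#' @export
gen_tweets <- function(cfg, tracts, lex, propensities = NULL) {
  if (is.null(propensities)) {
    propensities <- draw_propensities(cfg, tracts$tract_id)
  }
  ent <- lex$entries
  pools <- list(
    healthy = which(ent$healthy),
    fastfood = which(ent$fastfood & !ent$healthy),
    neutral = which(!ent$healthy & !ent$fastfood)
  )
  mean_k <- mean(cfg$terms_per_tweet)
  # per-year, per-pool sampling weights implementing the calorie drift
  year0 <- min(cfg$years)
  weights <- lapply(cfg$years, function(y) {
    lapply(pools, function(rows) {
      cal <- ent$calories_per_100g[rows]
      calorie_tilt_weights(cal, mean(cal) +
                             cfg$trend_kcal_per_year * (y - year0) / mean_k)
    })
  })
  names(weights) <- as.character(cfg$years)

  fill <- filler_words()
  excl <- default_exclusion_terms()
  lines <- character(0)
  tid_counter <- 0L
  nt <- length(tracts$tract_id)
  n_posts <- stats::rpois(nt, cfg$tweets_per_tract_mean)
  for (k in seq_len(nt)) {
    n <- n_posts[k]
    if (!n) next
    bb <- tracts$bbox[k, ]
    lon <- stats::runif(n, bb[1] + 1e-6, bb[2] - 1e-6)
    lat <- stats::runif(n, bb[3] + 1e-6, bb[4] - 1e-6)
    yr <- sample(cfg$years, n, replace = TRUE)
    doy <- sample.int(364, n, replace = TRUE)
    sec <- sample.int(86400, n, replace = TRUE) - 1L
    ts <- sprintf("%d-01-01T00:00:00Z", yr)
    ts <- format(as.POSIXct(ts, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%OSZ") +
                   (doy - 1) * 86400 + sec,
                 "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    u <- stats::runif(n)
    is_job <- u < cfg$job_fraction
    is_food <- !is_job &
      (u - cfg$job_fraction) / (1 - cfg$job_fraction) <
        cfg$food_fraction
    p_h <- propensities$p_healthy[k]
    p_f <- propensities$p_fastfood[k]
    # filler padding for every post
    lens <- sample(3:6, n, replace = TRUE)
    pad <- sample(fill, sum(lens), replace = TRUE)
    pad_of <- split(pad, rep.int(seq_len(n), lens))
    texts <- vapply(pad_of, paste, character(1), collapse = " ")
    jb <- which(is_job)
    if (length(jb)) {
      texts[jb] <- paste(sample(excl, length(jb), replace = TRUE),
                         vapply(pad_of[jb], function(p) paste(p[1:2],
                                collapse = " "), character(1)),
                         ent$term[sample.int(nrow(ent), length(jb),
                                             replace = TRUE)])
    }
    fd <- which(is_food)
    if (length(fd)) {
      nterm <- sample(cfg$terms_per_tweet, length(fd), replace = TRUE)
      tot <- sum(nterm)
      owner <- rep.int(seq_along(fd), nterm)
      cls <- sample(c("healthy", "fastfood", "neutral"), tot,
                    replace = TRUE,
                    prob = c(p_h, p_f, max(1 - p_h - p_f, 0.01)))
      term_year <- yr[fd][owner]
      terms <- character(tot)
      for (y in unique(term_year)) {
        wy <- weights[[as.character(y)]]
        for (cl in c("healthy", "fastfood", "neutral")) {
          sel <- which(term_year == y & cls == cl)
          if (!length(sel)) next
          rows <- pools[[cl]]
          terms[sel] <- ent$term[rows[sample.int(length(rows), length(sel),
                                                 replace = TRUE,
                                                 prob = wy[[cl]])]]
        }
      }
      term_str <- vapply(split(terms, owner), paste, character(1),
                         collapse = " ")
      texts[fd] <- paste(
        vapply(pad_of[fd], function(p) paste(p[1:2], collapse = " "),
               character(1)),
        term_str,
        vapply(pad_of[fd], function(p) paste(p[-(1:2)], collapse = " "),
               character(1)))
    }
    tid <- tid_counter + seq_len(n)
    tid_counter <- tid_counter + n
    lines <- c(lines, sprintf(
      '{"id":"t%07d","created_at":"%s","lon":%.8f,"lat":%.8f,"text":"%s"}',
      tid, ts, lon, lat, texts))
  }
  list(lines = lines, truth = propensities)
}

rlaplace <- function(n, sd) {
  b <- sd / sqrt(2)
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

#' Generate outcome prevalences and covariates with planted effects
#'
#' Takes the *measured* tract food-environment table (the analysis set
#' after the minimum-post filter), z-standardizes the three exposures
#' within it, and builds each outcome as
#' `baseline + beta_cal z_cal + beta_healthy z_healthy +
#' beta_fastfood z_fastfood + covariate effects + noise`, clipped to
#' `[0.1, 99.9]` (clip count reported).  Because the planted effects act
#' on the measured z-scale, a correctly specified regression recovers
#' them without attenuation from post-sampling noise.
#'
#' Also emits `obesity_male` / `obesity_female` surfaces whose calorie
#' effects differ by `sex_effect_delta` (0 by default), for Chow-test
#' exercises.
#'
#' Call under a seeded RNG for reproducibility.
#'
#' @param cfg a [synth_config()].
#' @param envs measured tract table (needs tract_id, mean_calories,
#'   pct_healthy, pct_fastfood).
#' @return list with `outcomes` (tract_id + 5 prevalence columns),
#'   `covariates` (tract_id + 11 covariates), `clipped` (count) and
#'   `truth` (planted parameters actually used).
#' @export
gen_outcomes <- function(cfg, envs) {
  n <- nrow(envs)
  pe <- cfg$planted_effects
  if (n < 2L) {
    empty <- data.frame(tract_id = character(0))
    for (oc in c(rownames(pe), "obesity_male", "obesity_female")) {
      empty[[oc]] <- numeric(0)
    }
    cov0 <- data.frame(tract_id = character(0))
    for (v in covariate_names()) cov0[[v]] <- numeric(0)
    return(list(outcomes = empty, covariates = cov0, clipped = 0L,
                truth = list(planted_effects = pe,
                             baselines = cfg$baselines,
                             covariate_effects = cfg$covariate_effects,
                             noise_sd = cfg$noise_sd,
                             noise_kind = cfg$noise_kind,
                             sex_effect_delta = cfg$sex_effect_delta)))
  }
  z <- scale(as.matrix(envs[, c("mean_calories", "pct_healthy",
                                "pct_fastfood")]))
  cov <- data.frame(
    tract_id = envs$tract_id,
    pop_density = stats::rlnorm(n, 8, 0.5),
    pct_65older = pmin(pmax(stats::rnorm(n, 13, 4), 0), 60),
    pct_male = stats::rnorm(n, 49, 2),
    pct_black = 100 * stats::rbeta(n, 2, 8),
    pct_hispanic = 100 * stats::rbeta(n, 2, 8),
    urban = stats::rbinom(n, 1, 0.8),
    pct_relatives = pmax(stats::rnorm(n, 6, 2), 0),
    pct_unmarried = pmax(stats::rnorm(n, 7, 2), 0),
    household_size = pmax(stats::rnorm(n, 2.6, 0.3), 1),
    pct_owner_occupied = pmin(pmax(stats::rnorm(n, 60, 15), 0), 100),
    income_inequality = pmin(pmax(stats::rnorm(n, 0.43, 0.05), 0.2), 0.7),
    stringsAsFactors = FALSE
  )
  gamma <- cfg$covariate_effects
  cov_contrib <- rowSums(vapply(names(gamma), function(v) {
    x <- cov[[v]]
    s <- stats::sd(x)
    if (s == 0) rep(0, n) else gamma[[v]] * (x - mean(x)) / s
  }, numeric(n)))
  noise <- function() {
    if (cfg$noise_sd == 0) rep(0, n)
    else if (cfg$noise_kind == "laplace") rlaplace(n, cfg$noise_sd)
    else stats::rnorm(n, 0, cfg$noise_sd)
  }
  clipped <- 0L
  mk <- function(beta, baseline) {
    raw <- baseline + drop(z %*% beta) + cov_contrib + noise()
    out <- pmin(pmax(raw, 0.1), 99.9)
    clipped <<- clipped + sum(out != raw)
    out
  }
  outcomes <- data.frame(tract_id = envs$tract_id, stringsAsFactors = FALSE)
  for (oc in rownames(pe)) {
    outcomes[[oc]] <- mk(pe[oc, ], cfg$baselines[[oc]])
  }
  beta_m <- pe["obesity", ]
  beta_f <- beta_m + c(cfg$sex_effect_delta, 0, 0)
  outcomes$obesity_male <- mk(beta_m, cfg$baselines[["obesity"]])
  outcomes$obesity_female <- mk(beta_f, cfg$baselines[["obesity"]])
  list(outcomes = outcomes, covariates = cov, clipped = clipped,
       truth = list(planted_effects = pe, baselines = cfg$baselines,
                    covariate_effects = gamma, noise_sd = cfg$noise_sd,
                    noise_kind = cfg$noise_kind,
                    sex_effect_delta = cfg$sex_effect_delta))
}

#' Generate a state-year mean-calorie series with a planted trend
#'
#' Direct generator for the GEE trend analysis: for each state,
#' `value = base + state_intercept + slope * (year - min(year)) + noise`.
#'
#' @param slope planted trend, kcal per year.
#' @param n_states number of states.
#' @param years calendar years.
#' @param base grand-mean calories in the first year.
#' @param state_sd SD of state intercept deviations.
#' @param noise_sd SD of the residual noise (0 = noise-free).
#' @param seed optional seed.
#' @return data.frame with columns state, year, value.
#' @export
gen_trend_series <- function(slope, n_states = 10L, years = 2015:2018,
                             base = 200, state_sd = 20, noise_sd = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- stats::rnorm(n_states, 0, state_sd)
  grid <- expand.grid(state = sprintf("%02d", seq_len(n_states)),
                      year = years, stringsAsFactors = FALSE)
  grid$value <- base + a[match(grid$state, sprintf("%02d", seq_len(n_states)))] +
    slope * (grid$year - min(years)) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid[order(grid$state, grid$year), ]
}

#' Generate and write a full synthetic input bundle
#'
#' Runs every generator under `cfg$seed` and writes `tweets.jsonl`,
#' `tracts.geojson`, `lexicon.csv`, `outcomes.csv`, `covariates.csv`,
#' `state_map.csv` and `truth.json` (the planted parameters) to `dir`.
#' Because the planted outcome effects act on the *measured* tract
#' variables, the generator internally runs the processing pipeline
#' (match, assign, aggregate, filter) on its own posts before
#' generating outcomes.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @param lex lexicon to embed (default [default_lexicon()]).
#' @param min_tweets minimum-food-post filter used for the analysis set
#'   (default 10).
#' @return invisible list with all in-memory pieces (tracts, records,
#'   envs, outcomes, covariates, truth, counters).
#' @export
simulate_bundle <- function(cfg, dir, lex = default_lexicon(),
                            min_tweets = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  grid <- gen_tract_grid(cfg)
  tw <- gen_tweets(cfg, grid$tracts, lex)
  tweets_path <- file.path(dir, "tweets.jsonl")
  writeLines(tw$lines, tweets_path)
  write_tracts_geojson(grid$tracts, file.path(dir, "tracts.geojson"))
  write_lexicon(lex, file.path(dir, "lexicon.csv"))
  utils::write.csv(grid$state_map, file.path(dir, "state_map.csv"),
                   row.names = FALSE)

  ps <- process_stream(tweets_path, lex)
  asn <- assign_tracts(ps$records, grid$tracts)
  envs <- aggregate_tracts(asn$records)
  flt <- filter_min_tweets(envs, min_tweets)
  oc <- gen_outcomes(cfg, flt$envs)
  utils::write.csv(oc$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(oc$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- c(oc$truth,
             list(seed = cfg$seed,
                  trend_kcal_per_year = cfg$trend_kcal_per_year,
                  latent_propensities = tw$truth,
                  min_tweets = min_tweets))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(tracts = grid$tracts, state_map = grid$state_map,
                 records = asn$records, counters = ps$counters,
                 unassigned = asn$unassigned, envs = envs,
                 filtered = flt, outcomes = oc$outcomes,
                 covariates = oc$covariates, clipped = oc$clipped,
                 truth = truth))
}
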