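#' Read a run configuration file
#'
#' YAML (`.yaml`/`.yml`, requires the yaml package) or JSON (`.json`).
#' Recognized keys: input paths `tweets`, `tracts`, `lexicon`,
#' `outcomes`, `covariates` (optional), `exclusions` (optional),
#' `state_map` (optional CSV tract_id,state; default: GEOID prefix);
#' `out_dir`; numbers `min_tweets` (10), `boot` (200), `seed` (1);
#' `outcome_list` (default obesity, diabetes, hypertension);
#' `covariate_cols` (default: the 11 demographic covariates present);
#' `state_weighting` ("tweet" or "tract"); `id_property` ("GEOID");
#' `chow` (optional list with `group_a`, `group_b`: two outcome columns
#' to compare under the same design).
#'
#' @param path config file path.
#' @param overrides named list merged over the file values (CLI wins).
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use .yaml or .json)",
         call. = FALSE)
  }
  raw[names(overrides)] <- overrides
  run_config(raw)
}

#' Build a run configuration from a list
#'
#' @param x named list of settings (see [read_run_config()]).
#' @return list of class `run_config` with defaults filled in.
#' @export
run_config <- function(x = list()) {
  defaults <- list(
    tweets = NULL, tracts = NULL, lexicon = NULL, outcomes = NULL,
    covariates = NULL, exclusions = NULL, state_map = NULL,
    out_dir = ".", min_tweets = 10L, boot = 200L, seed = 1L,
    outcome_list = c("obesity", "diabetes", "hypertension"),
    covariate_cols = NULL, state_weighting = "tweet",
    id_property = "GEOID", chow = NULL
  )
  defaults[names(x)] <- x
  structure(defaults, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' process -> assign -> aggregate -> filter -> merge -> standardize ->
#' per-outcome median and OLS fits -> state summary -> GEE trend ->
#' optional Chow comparison.  Writes `manifest.json` (counters at every
#' stage, seed, package version), one `table1_<outcome>.csv` per
#' outcome (variable, beta, se, p for median and OLS), plus
#' `state_summary.csv` and `trend.csv` to `cfg$out_dir`.
#'
#' @param cfg a `run_config`.
#' @return invisible list with `manifest`, `fits` (per outcome, median +
#'   ols), `analysis` table, `state_summary`, `trend` fit (or NULL) and
#'   `chow` result (or NULL).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  required <- c("tweets", "tracts", "lexicon", "outcomes")
  for (key in required) {
    if (is.null(cfg[[key]])) stop("config is missing input path: ", key,
                                  call. = FALSE)
    if (!file.exists(cfg[[key]])) stop("input file not found: ", cfg[[key]],
                                       call. = FALSE)
  }
  for (key in c("covariates", "exclusions", "state_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("input file not found: ", cfg[[key]], call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  lex <- stage("lexicon", load_lexicon(cfg$lexicon))
  excl <- stage("exclusions", if (is.null(cfg$exclusions)) {
    default_exclusion_terms()
  } else {
    read_exclusion_terms(cfg$exclusions)
  })
  ps <- stage("process", process_stream(cfg$tweets, lex, excl))
  tracts <- stage("tracts", load_tracts(cfg$tracts, cfg$id_property))
  asn <- stage("assign", assign_tracts(ps$records, tracts))
  envs <- stage("aggregate", aggregate_tracts(asn$records))
  flt <- stage("filter", filter_min_tweets(envs, cfg$min_tweets))

  # tract ids must stay character: GEOIDs have leading zeros
  outcomes <- stage("outcomes",
                    utils::read.csv(cfg$outcomes, stringsAsFactors = FALSE,
                                    colClasses = c(tract_id = "character")))
  covs <- if (is.null(cfg$covariates)) NULL else {
    stage("covariates",
          utils::read.csv(cfg$covariates, stringsAsFactors = FALSE,
                          colClasses = c(tract_id = "character")))
  }
  mg <- stage("merge", merge_outcomes(flt$envs, outcomes, covs))
  analysis <- stage("standardize", standardize(mg$table))

  cov_cols <- cfg$covariate_cols
  if (is.null(cov_cols)) cov_cols <- intersect(covariate_names(),
                                               names(analysis))
  zvars <- c("z_mean_calories", "z_pct_healthy", "z_pct_fastfood")

  fits <- list()
  for (i in seq_along(cfg$outcome_list)) {
    oc <- cfg$outcome_list[i]
    spec <- design_spec(oc, zvars, cov_cols)
    med <- stage(paste0("median:", oc),
                 fit_median_regression(analysis, spec,
                                       se_boot_reps = cfg$boot,
                                       seed = cfg$seed + i))
    ols <- stage(paste0("ols:", oc), fit_ols(analysis, spec))
    fits[[oc]] <- list(median = med, ols = ols)
    tab <- rbind(cbind(method = "median", as.data.frame(med)),
                 cbind(method = "ols", as.data.frame(ols)))
    utils::write.csv(tab, file.path(cfg$out_dir,
                                    paste0("table1_", oc, ".csv")),
                     row.names = FALSE)
  }

  state_of <- if (is.null(cfg$state_map)) state_from_geoid else {
    utils::read.csv(cfg$state_map, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  ss <- stage("state_summary",
              state_summary(flt$envs, state_of,
                            weighting = cfg$state_weighting))
  utils::write.csv(ss$summary, file.path(cfg$out_dir, "state_summary.csv"),
                   row.names = FALSE)

  trend <- NULL
  sy <- stage("trend", state_year_calories(asn$records, state_of))
  if (length(unique(sy$state)) >= 2 && length(unique(sy$year)) >= 2) {
    trend <- stage("trend", fit_gee_trend(sy))
    utils::write.csv(as.data.frame(trend),
                     file.path(cfg$out_dir, "trend.csv"), row.names = FALSE)
  }

  chow <- NULL
  if (!is.null(cfg$chow)) {
    ga <- cfg$chow$group_a; gb <- cfg$chow$group_b
    ta <- analysis; ta$group_outcome <- analysis[[ga]]
    tb <- analysis; tb$group_outcome <- analysis[[gb]]
    spec <- design_spec("group_outcome", zvars, cov_cols)
    chow <- stage("chow", chow_test(ta, tb, spec))
  }

  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("foodtweetenv")),
    counters = as.list(ps$counters),
    unassigned = asn$unassigned,
    tracts_aggregated = nrow(envs),
    tracts_excluded_min_tweets = flt$excluded,
    min_tweets = cfg$min_tweets,
    dropped_envs = mg$dropped_envs,
    dropped_outcomes = mg$dropped_outcomes,
    analysis_tracts = nrow(analysis),
    boot = cfg$boot,
    outcomes = cfg$outcome_list,
    z_check = vapply(zvars, function(v) {
      c(mean = mean(analysis[[v]]), sd = stats::sd(analysis[[v]]))
    }, numeric(2))
  )
  manifest$z_check <- as.list(as.data.frame(manifest$z_check))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, fits = fits, analysis = analysis,
                 state_summary = ss$summary, trend = trend, chow = chow))
}

# Post-weighted state-year mean caloric density from assigned records.
state_year_calories <- function(records, state_of = state_from_geoid) {
  r <- records[!is.na(records$tract_id), , drop = FALSE]
  state <- if (is.function(state_of)) {
    state_of(r$tract_id)
  } else {
    state_of$state[match(r$tract_id, state_of$tract_id)]
  }
  ok <- !is.na(state)
  agg <- stats::aggregate(r$caloric_density[ok],
                          by = list(state = state[ok], year = r$year[ok]),
                          FUN = mean)
  names(agg)[3] <- "value"
  agg[order(agg$state, agg$year), ]
}

#' Render a human-readable run report
#'
#' Per-outcome coefficient tables with `*` marking p < 0.05, the state
#' summary, and the trend slope.  Idempotent: rendering the same results
#' twice gives the same text.
#'
#' @param results list returned by [run_all()].
#' @return character vector of report lines.
#' @export
make_report <- function(results) {
  lines <- c("Food-environment analysis report",
             "================================", "")
  for (oc in names(results$fits)) {
    med <- results$fits[[oc]]$median
    df <- as.data.frame(med)
    lines <- c(lines, sprintf("Outcome: %s (median regression, n = %d)",
                              oc, med$n_obs))
    star <- ifelse(!is.na(df$p) & df$p < 0.05, " *", "")
    lines <- c(lines, sprintf("  %-22s %8.4f (SE %.4f, p %.4g)%s",
                              df$variable, df$beta, df$se, df$p, star), "")
  }
  ss <- results$state_summary
  if (!is.null(ss) && nrow(ss)) {
    lines <- c(lines, "State summary (post-weighted):",
               sprintf("  %-6s n=%6d  cal=%7.1f  healthy=%5.1f%%  fastfood=%5.1f%%",
                       ss$state, ss$n_food_tweets, ss$mean_calories,
                       ss$pct_healthy, ss$pct_fastfood), "")
  }
  if (!is.null(results$trend)) {
    lines <- c(lines, sprintf(
      "Yearly calorie trend (GEE): %+.2f kcal/year (robust SE %.3f)",
      results$trend$coefficients[["year"]],
      results$trend$standard_errors[["year"]]))
  }
  if (!is.null(results$chow)) {
    lines <- c(lines, sprintf(
      "Chow test: F(%d, %d) = %.3f, p = %.4g",
      results$chow$df1, results$chow$df2, results$chow$statistic,
      results$chow$p_value))
  }
  lines
}
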