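#' Aggregate food-post records to tract-level food-environment variables
#'
#' For every tract with at least one assigned food post: the number of
#' food posts, mean caloric density (kcal), percent of food posts
#' mentioning a healthy food, and percent mentioning fast food.  Raw
#' flagged counts and the calorie sum are kept so that state summaries
#' can be post-weighted exactly.
#'
#' @param records data.frame with `tract_id`, `caloric_density`,
#'   `is_healthy`, `is_fastfood` (rows with `NA` tract_id are ignored).
#' @return data.frame, one row per tract: tract_id, n_food_tweets,
#'   sum_calories, n_healthy, n_fastfood, mean_calories, pct_healthy,
#'   pct_fastfood.
#' @export
aggregate_tracts <- function(records) {
  r <- records[!is.na(records$tract_id), , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(tract_id = character(0), n_food_tweets = integer(0),
                      sum_calories = numeric(0), n_healthy = integer(0),
                      n_fastfood = integer(0), mean_calories = numeric(0),
                      pct_healthy = numeric(0), pct_fastfood = numeric(0),
                      stringsAsFactors = FALSE))
  }
  f <- factor(r$tract_id)
  n <- as.integer(table(f))
  out <- data.frame(
    tract_id = levels(f),
    n_food_tweets = n,
    sum_calories = as.numeric(tapply(r$caloric_density, f, sum)),
    n_healthy = as.integer(tapply(r$is_healthy, f, sum)),
    n_fastfood = as.integer(tapply(r$is_fastfood, f, sum)),
    stringsAsFactors = FALSE
  )
  out$mean_calories <- out$sum_calories / out$n_food_tweets
  out$pct_healthy <- 100 * out$n_healthy / out$n_food_tweets
  out$pct_fastfood <- 100 * out$n_fastfood / out$n_food_tweets
  rownames(out) <- NULL
  out
}

#' Drop tracts with too few food posts
#'
#' Tracts with fewer than `min_tweets` food posts are excluded to protect
#' the construct validity of the tract indicators; a tract with exactly
#' `min_tweets` posts is kept.
#'
#' @param envs tract table from [aggregate_tracts()].
#' @param min_tweets minimum food-post count (default 10).
#' @return list with `envs` (filtered table) and `excluded` (count).
#' @export
filter_min_tweets <- function(envs, min_tweets = 10L) {
  if (!is.numeric(min_tweets) || min_tweets < 1) {
    stop("min_tweets must be >= 1", call. = FALSE)
  }
  keep <- envs$n_food_tweets >= min_tweets
  list(envs = envs[keep, , drop = FALSE], excluded = sum(!keep))
}

#' Merge tract food-environment variables with outcomes and covariates
#'
#' Inner join on `tract_id`.  Standardization of the exposure variables
#' is done *after* this join (on the analysis set) by [standardize()].
#'
#' @param envs filtered tract table.
#' @param outcomes data.frame keyed by `tract_id` with outcome
#'   prevalences (and optionally covariates).
#' @param covariates optional additional data.frame keyed by `tract_id`.
#' @return list with `table` (merged analysis table), `dropped_envs` and
#'   `dropped_outcomes` (rows lost from each side of the join).
#' @export
merge_outcomes <- function(envs, outcomes, covariates = NULL) {
  if (anyDuplicated(envs$tract_id)) {
    stop("duplicate tract_id in food-environment table", call. = FALSE)
  }
  if (anyDuplicated(outcomes$tract_id)) {
    stop("duplicate tract_id in outcome table", call. = FALSE)
  }
  merged <- merge(envs, outcomes, by = "tract_id", sort = TRUE)
  if (!is.null(covariates)) {
    if (anyDuplicated(covariates$tract_id)) {
      stop("duplicate tract_id in covariate table", call. = FALSE)
    }
    merged <- merge(merged, covariates, by = "tract_id", sort = TRUE)
  }
  if (!nrow(merged)) {
    warning("no tracts in common between food-environment and outcome tables",
            call. = FALSE)
  }
  list(table = merged,
       dropped_envs = nrow(envs) - nrow(merged),
       dropped_outcomes = nrow(outcomes) - nrow(merged))
}

#' Z-standardize exposure variables on the analysis set
#'
#' Adds `z_<var>` columns with sample mean 0 and sample standard
#' deviation 1 (n-1 denominator), computed over the rows of the table as
#' given — i.e. the tracts that survived the minimum-post filter and the
#' outcome merge, so a coefficient reads as the change per one standard
#' deviation within the modeled sample.
#'
#' @param table analysis table.
#' @param vars variables to standardize.
#' @return table with `z_` columns and attributes `z_center`, `z_scale`.
#' @export
standardize <- function(table,
                        vars = c("mean_calories", "pct_healthy",
                                 "pct_fastfood")) {
  if (nrow(table) < 2L) stop("need at least 2 tracts to standardize",
                             call. = FALSE)
  center <- numeric(0); scale <- numeric(0)
  for (v in vars) {
    x <- table[[v]]
    if (is.null(x)) stop("column not found: ", v, call. = FALSE)
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize constant variable: ", v, call. = FALSE)
    }
    table[[paste0("z_", v)]] <- (x - m) / s
    center[v] <- m; scale[v] <- s
  }
  attr(table, "z_center") <- center
  attr(table, "z_scale") <- scale
  table
}

#' State-level summaries of the food-environment variables
#'
#' By default summaries are post-weighted: the state percent fast food is
#' total fast-food-flagged food posts over total food posts (x100), and
#' the state mean caloric density is the calorie total over the post
#' total — i.e. pooled over posts, not averaged over tracts.  Set
#' `weighting = "tract"` for unweighted tract means.
#'
#' @param envs tract table from [aggregate_tracts()] (filtered or not).
#' @param state_of either a function mapping tract ids to state codes or
#'   a data.frame with columns `tract_id`, `state`.  For 11-digit GEOIDs
#'   use [state_from_geoid()].
#' @param weighting `"tweet"` (pooled over posts, default) or `"tract"`.
#' @return list with `summary` (data.frame: state, n_tracts,
#'   n_food_tweets, mean_calories, pct_healthy, pct_fastfood) and
#'   `unmapped` (tracts without a state, skipped).
#' @export
state_summary <- function(envs, state_of = state_from_geoid,
                          weighting = c("tweet", "tract")) {
  weighting <- match.arg(weighting)
  state <- if (is.function(state_of)) {
    state_of(envs$tract_id)
  } else {
    state_of$state[match(envs$tract_id, state_of$tract_id)]
  }
  ok <- !is.na(state) & nzchar(state)
  unmapped <- sum(!ok)
  e <- envs[ok, , drop = FALSE]
  f <- factor(state[ok])
  agg <- function(x) as.numeric(tapply(x, f, sum))
  out <- data.frame(
    state = levels(f),
    n_tracts = as.integer(table(f)),
    n_food_tweets = as.integer(agg(e$n_food_tweets)),
    stringsAsFactors = FALSE
  )
  if (weighting == "tweet") {
    out$mean_calories <- agg(e$sum_calories) / out$n_food_tweets
    out$pct_healthy <- 100 * agg(e$n_healthy) / out$n_food_tweets
    out$pct_fastfood <- 100 * agg(e$n_fastfood) / out$n_food_tweets
  } else {
    tmean <- function(x) as.numeric(tapply(x, f, mean))
    out$mean_calories <- tmean(e$mean_calories)
    out$pct_healthy <- tmean(e$pct_healthy)
    out$pct_fastfood <- tmean(e$pct_fastfood)
  }
  rownames(out) <- NULL
  list(summary = out, unmapped = unmapped)
}

#' Extract the state code from a tract GEOID
#'
#' Real census-tract GEOIDs are 11 characters whose first two digits are
#' the state FIPS code; the synthetic generator follows the same layout.
#'
#' @param tract_id character vector.
#' @return character vector of 2-character state codes.
#' @export
state_from_geoid <- function(tract_id) substr(as.character(tract_id), 1, 2)
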