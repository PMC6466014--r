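#' Default job-posting exclusion phrases
#'
#' Posts advertising jobs frequently mention food venues without saying
#' anything about what people eat, so they are excluded before food-term
#' matching.  The upstream phrase list is not published; this configurable
#' default covers the common templates.
#'
#' @return character vector of exclusion phrases.
#' @export
default_exclusion_terms <- function() {
  c("hiring", "job opening", "apply now", "careers", "job alert",
    "now recruiting", "we are recruiting", "join our team",
    "click to apply", "job posting")
}

#' Read exclusion phrases from a text file
#'
#' One phrase per line; blank lines and lines starting with `#` ignored.
#'
#' @param path file path.
#' @return character vector of phrases.
#' @export
read_exclusion_terms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Test whether a post is a job posting
#'
#' TRUE iff any exclusion phrase occurs in the text on word boundaries
#' after normalization.  Vectorized over `text`.
#'
#' @param text character vector of raw post text.
#' @param exclusion_terms character vector of phrases
#'   (default [default_exclusion_terms()]).
#' @return logical vector.
#' @export
#' @examples
#' is_job_posting(c("We're hiring! Barista wanted", "I ate a burrito"))
is_job_posting <- function(text, exclusion_terms = default_exclusion_terms()) {
  if (!length(text)) return(logical(0))
  norm <- paste0(" ", normalize_text(text), " ")
  phrases <- normalize_text(exclusion_terms)
  phrases <- phrases[nzchar(phrases)]
  out <- rep(FALSE, length(text))
  for (ph in phrases) {
    out <- out | grepl(paste0(" ", ph, " "), norm, fixed = TRUE)
  }
  out
}

# Greedy matcher core operating on a token vector. Returns integer rows of
# lex$entries, deduplicated, in order of first occurrence.
match_tokens <- function(toks, lex) {
  n <- length(toks)
  if (!n) return(integer(0))
  idx <- lex$index
  lex_tokens <- lex$tokens
  hits <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- idx[[toks[i]]]
    adv <- 1L
    if (!is.null(cand)) {
      for (row in cand) {          # candidates sorted longest-first
        tt <- lex_tokens[[row]]
        len <- length(tt)
        if (i + len - 1L <= n && all(tt == toks[i:(i + len - 1L)])) {
          hits <- c(hits, row)
          adv <- len
          break
        }
      }
    }
    i <- i + adv
  }
  unique(hits)
}

#' Match food terms in free text
#'
#' Tokenizes the normalized text and scans left to right; at each position
#' the longest lexicon term starting there wins (multi-word greedy match)
#' and the scan advances past it.  Matches respect word boundaries (no
#' substring hits inside tokens) and each distinct term counts at most
#' once per post.
#'
#' @param text a single character string.
#' @param lex a `food_lexicon`.
#' @return data.frame of matched lexicon entries (possibly 0 rows) with
#'   columns term, calories_per_100g, healthy, fastfood.
#' @export
#' @examples
#' lex <- build_lexicon(c("apple", "apple pie", "pizza"),
#'                      c(52, 237, 266), c(1, 0, 0), c(0, 0, 0))
#' match_food_terms("i love apple pie and pizza", lex)$term
match_food_terms <- function(text, lex) {
  stopifnot(inherits(lex, "food_lexicon"), length(text) == 1L)
  toks <- tokenize(normalize_text(text))[[1]]
  rows <- match_tokens(toks, lex)
  lex$entries[rows, c("term", "calories_per_100g", "healthy", "fastfood"),
              drop = FALSE]
}

#' Score one post
#'
#' Applies the job-posting filter first (a job post mentioning food is
#' excluded), then food-term matching.  Returns `NULL` unless the post is
#' a food post, otherwise a one-row record with the per-post caloric
#' density (sum of matched terms' kcal/100 g, each distinct term counted
#' once) and the healthy / fast-food flags (any matched term in the
#' class).
#'
#' @param tweet list or one-row data.frame with fields `id`, `created_at`
#'   (ISO-8601), `lon`, `lat`, `text`.
#' @param lex a `food_lexicon`.
#' @param exclusion_terms job-posting phrases.
#' @return one-row data.frame (tweet_id, timestamp, year, lon, lat,
#'   caloric_density, is_healthy, is_fastfood, matched_terms) or `NULL`.
#' @export
score_tweet <- function(tweet, lex,
                        exclusion_terms = default_exclusion_terms()) {
  txt <- as.character(tweet$text)
  if (is.na(txt) || is_job_posting(txt, exclusion_terms)) return(NULL)
  m <- match_food_terms(txt, lex)
  if (!nrow(m)) return(NULL)
  ts <- parse_timestamp(as.character(tweet$created_at))
  data.frame(
    tweet_id = as.character(tweet$id),
    timestamp = format_timestamp(ts),
    year = timestamp_year(ts),
    lon = as.numeric(tweet$lon),
    lat = as.numeric(tweet$lat),
    caloric_density = sum(m$calories_per_100g),
    is_healthy = any(m$healthy),
    is_fastfood = any(m$fastfood),
    matched_terms = paste(m$term, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

# Timestamps are treated as UTC; the calendar year used for trend
# analysis is the UTC year.
parse_timestamp <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS%z",
                            "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%d"))
}
format_timestamp <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
timestamp_year <- function(ts) as.integer(format(ts, "%Y", tz = "UTC"))

#' Process a JSONL stream of geotagged posts
#'
#' Reads one JSON object per line (keys `id`, `created_at`, `lon`, `lat`,
#' `text`), drops unparseable lines and records with malformed
#' coordinates or timestamps (counted, not fatal), filters job postings,
#' matches food terms, and scores every food post.
#'
#' @param path path to a JSONL file.
#' @param lex a `food_lexicon`.
#' @param exclusion_terms job-posting phrases.
#' @return list with `records` (data.frame, one row per food post: columns
#'   as in [score_tweet()]) and `counters` (named integer vector: lines,
#'   malformed, job_filtered, non_food, food).  Conservation holds:
#'   lines = malformed + job_filtered + non_food + food.
#' @export
process_stream <- function(path, lex,
                           exclusion_terms = default_exclusion_terms()) {
  stopifnot(inherits(lex, "food_lexicon"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_lines <- length(lines)
  counters <- c(lines = n_lines, malformed = 0L, job_filtered = 0L,
                non_food = 0L, food = 0L)
  empty <- empty_records()
  if (!n_lines) return(list(records = empty, counters = counters))

  stream_df <- function(ln) {
    con <- textConnection(ln)
    on.exit(try(close(con), silent = TRUE))
    jsonlite::stream_in(con, simplifyDataFrame = TRUE, verbose = FALSE)
  }
  parsed <- tryCatch(stream_df(lines), error = function(e) NULL)
  if (is.null(parsed)) {          # malformed line(s): validate one by one
    ok <- vapply(lines, function(l) isTRUE(jsonlite::validate(l)),
                 logical(1), USE.NAMES = FALSE)
    parsed <- if (any(ok)) stream_df(lines[ok]) else NULL
  } else {
    ok <- rep(TRUE, n_lines)
  }
  if (is.null(parsed) || !nrow(parsed)) {
    counters["malformed"] <- n_lines
    return(list(records = empty, counters = counters))
  }
  need <- c("id", "created_at", "lon", "lat", "text")
  have <- intersect(need, names(parsed))
  for (col in setdiff(need, have)) parsed[[col]] <- NA
  lon <- suppressWarnings(as.numeric(parsed$lon))
  lat <- suppressWarnings(as.numeric(parsed$lat))
  ts <- suppressWarnings(parse_timestamp(as.character(parsed$created_at)))
  bad <- is.na(lon) | is.na(lat) | abs(lon) > 180 | abs(lat) > 90 |
    is.na(ts) | is.na(parsed$text) | is.na(parsed$id)
  counters["malformed"] <- sum(!ok) + sum(bad)
  keep <- which(!bad)
  if (!length(keep)) return(list(records = empty, counters = counters))

  txt <- as.character(parsed$text)[keep]
  job <- is_job_posting(txt, exclusion_terms)
  counters["job_filtered"] <- sum(job)
  keep <- keep[!job]
  txt <- txt[!job]
  if (!length(keep)) return(list(records = empty, counters = counters))

  tok_list <- tokenize(normalize_text(txt))
  ent <- lex$entries
  # fast vectorized prefilter: a post with no lexicon first-token at all
  # cannot match anything, so skip the positional scan for it
  all_tok <- unlist(tok_list, use.names = FALSE)
  owner <- rep.int(seq_along(tok_list), lengths(tok_list))
  may_match <- tabulate(owner[all_tok %in% ls(lex$index)],
                        nbins = length(tok_list)) > 0L
  match_rows <- vector("list", length(tok_list))
  match_rows[] <- list(integer(0))
  match_rows[may_match] <- lapply(tok_list[may_match], match_tokens,
                                  lex = lex)
  is_food <- lengths(match_rows) > 0L
  n_food <- sum(is_food)
  counters["food"] <- n_food
  counters["non_food"] <- length(keep) - n_food
  if (!n_food) return(list(records = empty, counters = counters))
  fi <- keep[is_food]                      # indices into parsed
  mr <- match_rows[is_food]
  records <- data.frame(
    tweet_id = as.character(parsed$id[fi]),
    timestamp = format_timestamp(ts[fi]),
    year = timestamp_year(ts[fi]),
    lon = lon[fi], lat = lat[fi],
    caloric_density = vapply(mr, function(r) sum(ent$calories_per_100g[r]),
                             numeric(1)),
    is_healthy = vapply(mr, function(r) any(ent$healthy[r]), logical(1)),
    is_fastfood = vapply(mr, function(r) any(ent$fastfood[r]), logical(1)),
    matched_terms = vapply(mr, function(r) paste(ent$term[r], collapse = ";"),
                           character(1)),
    stringsAsFactors = FALSE
  )
  list(records = records, counters = counters)
}

empty_records <- function() {
  data.frame(tweet_id = character(0), timestamp = character(0),
             year = integer(0), lon = numeric(0), lat = numeric(0),
             caloric_density = numeric(0), is_healthy = logical(0),
             is_fastfood = logical(0), matched_terms = character(0),
             stringsAsFactors = FALSE)
}
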