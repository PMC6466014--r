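#' Normalize free text or lexicon terms
#'
#' Canonical form used everywhere terms and post text are compared:
#' lowercase, `#` and `@` characters removed (so `"#pizza"` matches
#' `"pizza"`), tokens split on whitespace, punctuation stripped from token
#' edges, empty tokens dropped, and internal whitespace collapsed to a
#' single space.
#'
#' @param x character vector.
#' @return character vector of normalized strings.
#' @export
#' @examples
#' normalize_text(c("  Apple  PIE ", "#pizza!!", "don't"))
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[#@]", "", x)
  x <- gsub("(^|[[:space:]])[[:punct:]]+", "\\1", x)   # punct at token starts
  x <- gsub("[[:punct:]]+([[:space:]]|$)", "\\1", x)   # punct at token ends
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Tokenize normalized text
#'
#' @param x character vector already passed through [normalize_text()].
#' @return list of character token vectors.
#' @keywords internal
tokenize <- function(x) {
  strsplit(x, " ", fixed = TRUE)
}

#' Load a calorie-annotated food lexicon from CSV
#'
#' The lexicon drives food-post detection: each term carries a caloric
#' density (kcal per 100 g) and two class flags, healthy and fast food.
#' Terms may be multi-word ("big mac"); matching is done on word
#' boundaries by [match_food_terms()].  The CSV must have the header
#' `term,calories_per_100g,healthy,fastfood` with the flags encoded 0/1.
#'
#' Terms are normalized (see [normalize_text()]) on load; duplicates after
#' normalization are an error, as are negative calories.  A term flagged
#' both healthy and fast food is legal but triggers a warning.
#'
#' @param path path to the lexicon CSV.
#' @return an object of class `food_lexicon`: a list with `entries`
#'   (data.frame of term, calories_per_100g, healthy, fastfood, n_tokens),
#'   `tokens` (list of per-term token vectors), `index` (environment
#'   mapping first token to candidate entry rows) and `max_tokens`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("term", "calories_per_100g", "healthy", "fastfood")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("lexicon CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  build_lexicon(raw$term, raw$calories_per_100g, raw$healthy, raw$fastfood)
}

#' Build a food lexicon from vectors
#'
#' Programmatic constructor used by [load_lexicon()], the synthetic-data
#' generator, and tests.
#'
#' @param term character vector of terms (normalized internally).
#' @param calories_per_100g numeric vector of caloric densities, kcal/100 g.
#' @param healthy,fastfood 0/1 or logical class flags.
#' @return a `food_lexicon` object; see [load_lexicon()].
#' @export
build_lexicon <- function(term, calories_per_100g, healthy, fastfood) {
  term_norm <- normalize_text(term)
  empty <- !nzchar(term_norm)
  if (any(empty)) {
    stop("lexicon row(s) ", paste(which(empty), collapse = ", "),
         ": term empty after normalization", call. = FALSE)
  }
  cal <- as.numeric(calories_per_100g)
  if (anyNA(cal)) {
    stop("lexicon row(s) ", paste(which(is.na(cal)), collapse = ", "),
         ": calories_per_100g not numeric", call. = FALSE)
  }
  if (any(cal < 0)) {
    stop("lexicon row(s) ", paste(which(cal < 0), collapse = ", "),
         ": negative calories_per_100g", call. = FALSE)
  }
  dup <- duplicated(term_norm)
  if (any(dup)) {
    stop("duplicate lexicon term(s) after normalization: ",
         paste(unique(term_norm[dup]), collapse = ", "), call. = FALSE)
  }
  healthy <- as.logical(as.integer(healthy))
  fastfood <- as.logical(as.integer(fastfood))
  if (anyNA(healthy) || anyNA(fastfood)) {
    stop("healthy/fastfood flags must be 0/1", call. = FALSE)
  }
  both <- healthy & fastfood
  if (any(both)) {
    warning("lexicon term(s) flagged both healthy and fast food: ",
            paste(term_norm[both], collapse = ", "), call. = FALSE)
  }
  tokens <- tokenize(term_norm)
  n_tokens <- lengths(tokens)
  entries <- data.frame(
    term = term_norm,
    calories_per_100g = cal,
    healthy = healthy,
    fastfood = fastfood,
    n_tokens = n_tokens,
    stringsAsFactors = FALSE
  )
  # first-token index; candidates stored longest-first so the greedy
  # matcher can take the first token-wise hit
  index <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  first <- vapply(tokens, `[`, character(1), 1L)
  for (tok in unique(first)) {
    rows <- which(first == tok)
    assign(tok, rows[order(-n_tokens[rows])], envir = index)
  }
  structure(
    list(entries = entries, tokens = tokens, index = index,
         max_tokens = max(c(0L, n_tokens))),
    class = "food_lexicon"
  )
}

#' Write a lexicon back to CSV
#'
#' Inverse of [load_lexicon()] on normalized entries (round-trip identity).
#'
#' @param lex a `food_lexicon`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "food_lexicon"))
  out <- lex$entries[, c("term", "calories_per_100g", "healthy", "fastfood")]
  out$healthy <- as.integer(out$healthy)
  out$fastfood <- as.integer(out$fastfood)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Summarize a lexicon
#'
#' @param lex a `food_lexicon`.
#' @return list with `total`, `healthy` and `fastfood` term counts.
#' @export
lexicon_summary <- function(lex) {
  stopifnot(inherits(lex, "food_lexicon"))
  list(
    total = nrow(lex$entries),
    healthy = sum(lex$entries$healthy),
    fastfood = sum(lex$entries$fastfood)
  )
}

#' @export
print.food_lexicon <- function(x, ...) {
  s <- lexicon_summary(x)
  cat(sprintf(
    "<food_lexicon> %d terms (%d healthy, %d fast food), up to %d tokens\n",
    s$total, s$healthy, s$fastfood, x$max_tokens))
  invisible(x)
}
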