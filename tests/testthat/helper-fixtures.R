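# Shared fixtures and independent oracles.  Everything is built in code;
# nothing is read from disk except files the tests themselves write.

tiny_lexicon <- function() {
  build_lexicon(
    term = c("pizza", "apple", "apple pie", "big mac", "salad"),
    calories_per_100g = c(266, 52, 237, 257, 20),
    healthy = c(0, 1, 0, 0, 1),
    fastfood = c(0, 0, 0, 1, 0)
  )
}

write_tweet_jsonl <- function(tweets, path = tempfile(fileext = ".jsonl")) {
  lines <- vapply(tweets, function(tw) {
    jsonlite::toJSON(tw, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  path
}

tweet <- function(id, text, lon = 0.5, lat = 0.5,
                  created_at = "2016-06-01T12:00:00Z") {
  list(id = id, created_at = created_at, lon = lon, lat = lat, text = text)
}

# Brute-force matcher oracle: enumerate every boundary-respecting
# (position, term) hit, then resolve overlaps longest-first with leftmost
# tie-break; returns the set of matched terms.
match_oracle <- function(text, lex) {
  toks <- foodtweetenv:::tokenize(normalize_text(text))[[1]]
  ent <- lex$entries
  cand <- list()
  for (row in seq_len(nrow(ent))) {
    tt <- lex$tokens[[row]]
    len <- length(tt)
    if (len > length(toks)) next
    for (start in seq_len(length(toks) - len + 1L)) {
      if (all(toks[start:(start + len - 1L)] == tt)) {
        cand[[length(cand) + 1L]] <- c(start = start, len = len, row = row)
      }
    }
  }
  if (!length(cand)) return(character(0))
  cand <- do.call(rbind, cand)
  taken <- rep(FALSE, length(toks))
  hits <- integer(0)
  cand <- cand[order(-cand[, "len"], cand[, "start"]), , drop = FALSE]
  for (k in seq_len(nrow(cand))) {
    span <- cand[k, "start"]:(cand[k, "start"] + cand[k, "len"] - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      hits <- c(hits, cand[k, "row"])
    }
  }
  sort(unique(ent$term[hits]))
}

# Random text built from lexicon terms and filler words.
random_text <- function(lex, n_tokens = 12) {
  pieces <- character(0)
  fill <- c("the", "a", "my", "very", "today", "morning", "lovely", "city",
            "walk", "over", "there", "again")
  while (length(pieces) < n_tokens) {
    if (stats::runif(1) < 0.4) {
      pieces <- c(pieces, lex$entries$term[sample.int(nrow(lex$entries), 1)])
    } else {
      pieces <- c(pieces, sample(fill, 1))
    }
  }
  paste(pieces, collapse = " ")
}

unit_square <- function(x0 = 0, y0 = 0, d = 1) {
  rbind(c(x0, y0), c(x0 + d, y0), c(x0 + d, y0 + d), c(x0, y0 + d),
        c(x0, y0))
}

# n x n grid of unit-square tracts with ids "01", "02", ... row-major.
square_grid <- function(n) {
  ids <- sprintf("%02d", seq_len(n * n))
  geoms <- list()
  k <- 0
  for (j in seq_len(n)) for (i in seq_len(n)) {
    k <- k + 1
    geoms[[k]] <- list(list(unit_square(i - 1, j - 1)))
  }
  new_tract_set(ids, geoms)
}

# Small regression fixture with known latent coefficients.
sim_table <- function(n = 80, beta = c(1, 2, -1), sd = 0.3, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + rnorm(n, 0, sd)
  data.frame(y = y, x1 = x1, x2 = x2)
}

# Random LAD instance for IRLS-vs-LP property tests.
random_lad_instance <- function(n_max = 200, p_max = 6) {
  n <- sample(15:n_max, 1)
  p <- sample(1:p_max, 1)             # predictors excl. intercept
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p + 1)
  y <- beta[1] + drop(X %*% beta[-1]) + rt(n, df = 2)
  tab <- as.data.frame(X)
  tab$y <- y
  list(table = tab,
       spec = design_spec("y", colnames(X)))
}
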