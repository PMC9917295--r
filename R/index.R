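#' Sentiment codes for tweet classes
#'
#' The published coding of tweet sentiment: positive tweets are coded 0,
#' neutral 2, and negative 4.
#'
#' @return Named integer vector `c(positive = 0, neutral = 2, negative = 4)`.
#' @export
sentiment_codes <- function() {
  c(positive = 0L, neutral = 2L, negative = 4L)
}

#' Classify the sentiment of one tokenized tweet
#'
#' The tweet's polarity score is the sum of the lexicon polarities of its
#' tokens; the label is positive if the sum is > 0, negative if < 0, and
#' neutral if exactly 0 (including the no-lexicon-hit case).
#'
#' @param tokens Character vector of cleaned tokens.
#' @param lexicon A `sentiment_lexicon`.
#' @return List with elements `label` (`"positive"`, `"neutral"` or
#'   `"negative"`), `code` (0, 2 or 4) and `score` (the polarity sum).
#' @export
classify_sentiment <- function(tokens, lexicon) {
  s <- sum(token_polarity(lexicon, tokens))
  label <- if (s > 0) "positive" else if (s < 0) "negative" else "neutral"
  list(label = label, code = unname(sentiment_codes()[label]), score = s)
}

#' Hourly GNH from sentiment counts
#'
#' The sentiment-balance score of an hour, scaled to 0-10 with higher values
#' indicating higher happiness:
#' \deqn{GNH = 5 \left(1 + \frac{n_{pos} - n_{neg}}{n_{pos} + n_{neg}}\right)}
#' Neutral tweets do not enter the balance. An hour whose tweets are all
#' neutral scores the midpoint 5. Vectorized over counts.
#'
#' @param n_pos,n_neg,n_neu Nonnegative tweet counts (neutral counts default
#'   to 0 and only matter for input checking).
#' @return GNH scores in `[0, 10]`.
#' @export
#' @examples
#' gnh_hourly(10, 0, 3)  # all-positive hour: 10
#' gnh_hourly(4, 4)      # balanced hour: 5
gnh_hourly <- function(n_pos, n_neg, n_neu = 0) {
  if (any(n_pos < 0, na.rm = TRUE) || any(n_neg < 0, na.rm = TRUE) ||
      any(n_neu < 0, na.rm = TRUE)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  polar <- n_pos + n_neg
  ifelse(polar > 0, 5 * (1 + (n_pos - n_neg) / polar), 5)
}

#' Daily GNH from hourly scores
#'
#' The arithmetic mean of the available (non-missing) hourly scores of a
#' local calendar day. A day without any scored hour is missing, not an
#' error.
#'
#' @param hourly_scores Numeric vector of hourly GNH values (may contain
#'   `NA`).
#' @return The daily mean, or `NA` for an empty day.
#' @export
gnh_daily <- function(hourly_scores) {
  x <- hourly_scores[!is.na(hourly_scores)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

#' Per-tweet emotion scores
#'
#' Each emotion's tweet score is the sum of the word intensities of the
#' tweet's lexicon hits, clipped at the scale maximum 10; a tweet with no
#' hits scores all-zero.
#'
#' @param tokens Character vector of cleaned tokens.
#' @param lexicon An `emotion_lexicon`.
#' @return Named numeric 8-vector in emotion order, each entry in `[0, 10]`.
#' @export
score_emotions <- function(tokens, lexicon) {
  if (length(tokens) == 0L) {
    return(stats::setNames(numeric(8L), emotion_names()))
  }
  pmin(colSums(token_emotions(lexicon, tokens)), 10)
}

#' Daily emotion means
#'
#' Component-wise arithmetic mean of per-tweet emotion vectors over a day.
#'
#' @param tweet_vectors Numeric matrix with 8 emotion columns, one row per
#'   tweet (e.g. rbind of [score_emotions()] results).
#' @return Named 8-vector of daily means, or all-`NA` for an empty day.
#' @export
emotion_daily <- function(tweet_vectors) {
  if (is.null(tweet_vectors) || NROW(tweet_vectors) == 0L) {
    return(stats::setNames(rep(NA_real_, 8L), emotion_names()))
  }
  stats::setNames(colMeans(matrix(tweet_vectors, ncol = 8L)), emotion_names())
}

#' Default keyword lists for the three context variables
#'
#' The topical keyword lists behind the context series: tweets about the
#' economy are scored for fear, tweets about loneliness for sadness, and
#' tweets about national institutions for trust. Lists are matched
#' case-insensitively after cleaning; multi-word entries match as contiguous
#' token phrases. The duplicated entry in the loneliness list is kept once
#' (set semantics).
#'
#' @return Named list of character vectors with elements `economy`,
#'   `loneliness`, `institutions`.
#' @export
default_keyword_sets <- function() {
  list(
    economy = c("jobs", "economy", "saving", "work", "wages", "income",
                "inflation", "stock market", "investment", "unemployment",
                "unemployed", "employment rate", "tech start-up",
                "venture capital"),
    loneliness = unique(c("lonely", "loneliness", "alone", "isolation",
                          "abandoned", "social distancing", "lonesome",
                          "by oneself", "solitary", "outcast",
                          "companionless", "solitary", "homesick")),
    institutions = c("parliament", "ministry", "minister", "senator", "MPs",
                     "legislator", "political", "politics", "prime minister")
  )
}

# emotion each context subset is scored on
context_emotions <- c(economy = "fear", loneliness = "sadness",
                      institutions = "trust")

#' Does a tokenized tweet match a keyword list?
#'
#' Single-word keywords match as whole tokens; multi-word keywords as
#' contiguous token sequences. Keywords are normalised through the same
#' cleaning rules as tweet text, so e.g. `"MPs"` matches the token `"mps"`
#' and `"tech start-up"` matches the cleaned phrase `"tech start up"`.
#'
#' @param tokens Character vector of cleaned tokens.
#' @param keywords Character vector of keywords/phrases.
#' @return `TRUE` if at least one keyword matches.
#' @export
matches_keywords <- function(tokens, keywords) {
  kw <- tokenize(clean_text(keywords))
  kw <- kw[lengths(kw) > 0L]
  for (phrase in kw) {
    m <- length(phrase)
    if (m == 1L) {
      if (phrase %in% tokens) return(TRUE)
    } else if (length(tokens) >= m) {
      hits <- which(tokens == phrase[1L])
      for (h in hits) {
        if (h + m - 1L <= length(tokens) &&
            all(tokens[h:(h + m - 1L)] == phrase)) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

#' Filter prepared tweets by a named keyword set
#'
#' @param tweets Tibble from [prepare_tweets()] (needs the `tokens` column).
#' @param keyword_set One of `"economy"`, `"loneliness"`, `"institutions"`.
#' @param keyword_sets Named list of keyword vectors, defaulting to
#'   [default_keyword_sets()]; an unknown `keyword_set` name is a
#'   configuration error.
#' @return The matching subset of `tweets`.
#' @export
filter_by_keywords <- function(tweets, keyword_set,
                               keyword_sets = default_keyword_sets()) {
  if (!keyword_set %in% names(keyword_sets)) {
    stop("unknown keyword set '", keyword_set, "'; available: ",
         paste(names(keyword_sets), collapse = ", "), call. = FALSE)
  }
  kw <- keyword_sets[[keyword_set]]
  keep <- vapply(tweets$tokens, matches_keywords, logical(1), keywords = kw)
  tweets[keep, , drop = FALSE]
}

#' Build the per-country daily series table
#'
#' The composition of the whole scoring stage: per-tweet sentiment codes and
#' emotion vectors, hourly sentiment-balance GNH averaged into daily GNH,
#' daily emotion means, and the three keyword-filtered context series
#' (economy -> fear, loneliness -> sadness, institutions -> trust). One row
#' per country-day with tweets; days with no tweets are absent. Context
#' columns are `NA` on days with no tweets in the subset.
#'
#' @param tweets Tibble from [read_tweets()].
#' @param sentiment_lexicon A `sentiment_lexicon`.
#' @param emotion_lexicon An `emotion_lexicon`.
#' @param tz_map Country -> timezone map, see [prepare_tweets()].
#' @param keyword_sets Keyword lists, see [filter_by_keywords()].
#' @return Tibble with columns `country`, `date`, `n_tweets`, `n_pos`,
#'   `n_neu`, `n_neg`, `gnh`, the 8 emotions, `econ_fear`,
#'   `loneliness_sad`, `inst_trust`.
#' @export
build_daily_series <- function(tweets, sentiment_lexicon, emotion_lexicon,
                               tz_map = default_tz_map(),
                               keyword_sets = default_keyword_sets()) {
  tw <- prepare_tweets(tweets, tz_map = tz_map)
  emo <- emotion_names()
  if (nrow(tw) == 0L) {
    out <- tibble::tibble(country = character(0),
                          date = as.Date(character(0)),
                          n_tweets = integer(0), n_pos = integer(0),
                          n_neu = integer(0), n_neg = integer(0),
                          gnh = numeric(0))
    for (e in emo) out[[e]] <- numeric(0)
    out$econ_fear <- numeric(0)
    out$loneliness_sad <- numeric(0)
    out$inst_trust <- numeric(0)
    return(out)
  }

  pol <- vapply(tw$tokens, function(t) sum(token_polarity(sentiment_lexicon, t)),
                numeric(1))
  tw$sent <- ifelse(pol > 0, "pos", ifelse(pol < 0, "neg", "neu"))
  escore <- t(vapply(tw$tokens, score_emotions, numeric(8L),
                     lexicon = emotion_lexicon))
  colnames(escore) <- emo

  key_day <- paste(tw$country, tw$local_date)

  # hourly GNH -> daily mean over hours that contain tweets
  key_hour <- paste(key_day, tw$local_hour)
  hp <- rowsum((tw$sent == "pos") + 0, key_hour)
  hn <- rowsum((tw$sent == "neg") + 0, key_hour)
  hour_gnh <- gnh_hourly(hp[, 1L], hn[, 1L])
  hour_day <- sub(" [0-9]+$", "", rownames(hp))
  day_gnh <- tapply(hour_gnh, hour_day, mean)

  counts <- function(flag) rowsum(flag + 0, key_day)[, 1L]
  n_tweets <- counts(rep(TRUE, nrow(tw)))
  n_pos <- counts(tw$sent == "pos")
  n_neg <- counts(tw$sent == "neg")
  n_neu <- counts(tw$sent == "neu")
  emo_day <- rowsum(escore, key_day) / n_tweets

  days <- sort(names(n_tweets))
  out <- tibble::tibble(
    country = sub(" .*$", "", days),
    date = as.Date(sub("^[A-Z]+ ", "", days)),
    n_tweets = as.integer(n_tweets[days]),
    n_pos = as.integer(n_pos[days]),
    n_neu = as.integer(n_neu[days]),
    n_neg = as.integer(n_neg[days]),
    gnh = as.numeric(day_gnh[days])
  )
  for (e in emo) out[[e]] <- as.numeric(emo_day[days, e])

  ctx_cols <- c(economy = "econ_fear", loneliness = "loneliness_sad",
                institutions = "inst_trust")
  for (set in names(ctx_cols)) {
    sub_keep <- vapply(tw$tokens, matches_keywords, logical(1),
                       keywords = keyword_sets[[set]])
    col <- rep(NA_real_, nrow(out))
    if (any(sub_keep)) {
      e <- context_emotions[[set]]
      sub_key <- key_day[sub_keep]
      sub_val <- escore[sub_keep, e]
      means <- tapply(sub_val, sub_key, mean)
      col[match(names(means), days)] <- as.numeric(means)
    }
    out[[ctx_cols[[set]]]] <- col
  }
  out
}

#' Write or read a daily series table as CSV
#'
#' Tidy CSV, one row per country-day, dates ISO-8601.
#'
#' @param series Tibble from [build_daily_series()].
#' @param path File path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(country = "character"))
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}
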