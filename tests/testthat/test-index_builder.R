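sent <- read_sentiment_lexicon(write_fixture_sentiment())
emol <- read_emotion_lexicon(write_fixture_emotions())

test_that("tweets are classified and coded positive 0 / neutral 2 / negative 4", {
  expect_equal(sentiment_codes(),
               c(positive = 0L, neutral = 2L, negative = 4L))
  pos <- classify_sentiment(c("i", "love", "dogs"), sent)
  expect_equal(pos$label, "positive"); expect_equal(pos$code, 0L)
  neg <- classify_sentiment(c("i", "hate", "rain"), sent)
  expect_equal(neg$label, "negative"); expect_equal(neg$code, 4L)
  neu <- classify_sentiment(c("the", "table"), sent)
  expect_equal(neu$label, "neutral"); expect_equal(neu$code, 2L)
  tie <- classify_sentiment(c("love", "hate"), sent)
  expect_equal(tie$code, 2L)
})

test_that("hourly GNH follows the sentiment-balance formula on 0-10", {
  expect_equal(gnh_hourly(10, 0, 3), 10)
  expect_equal(gnh_hourly(4, 4, 0), 5)
  expect_equal(gnh_hourly(3, 1, 2), 7.5)
  expect_equal(gnh_hourly(0, 7), 0)
  expect_equal(gnh_hourly(0, 0, 5), 5)  # all-neutral hour sits at the midpoint
  expect_error(gnh_hourly(-1, 0), "nonnegative")
})

test_that("hourly GNH is bounded and monotone in the positive count", {
  set.seed(7)
  np <- sample(0:50, 300, replace = TRUE)
  nn <- sample(0:50, 300, replace = TRUE)
  g <- gnh_hourly(np, nn)
  expect_true(all(g >= 0 & g <= 10))
  # swap one negative for one positive, total fixed: score never decreases
  has_neg <- nn > 0
  g2 <- gnh_hourly(np[has_neg] + 1, nn[has_neg] - 1)
  expect_true(all(g2 >= g[has_neg]))
})

test_that("daily GNH is the mean of available hourly scores", {
  expect_equal(gnh_daily(c(10, 5)), 7.5)
  expect_equal(gnh_daily(c(7, 7, 7)), 7)
  expect_true(is.na(gnh_daily(numeric(0))))
  expect_equal(gnh_daily(c(NA, 6, 8)), 7)
})

test_that("per-tweet emotion scores sum word intensities with clipping at 10", {
  v <- score_emotions(c("such", "fury"), emol)
  expect_equal(unname(v["anger"]), 6)
  expect_equal(unname(v["disgust"]), 4)
  expect_equal(unname(score_emotions(c("plain", "words"), emol)),
               rep(0, 8))
  # two anger hits 6 + 6 clip at the scale maximum
  v2 <- score_emotions(c("fury", "fury"), emol)
  expect_equal(unname(v2["anger"]), 10)
  expect_equal(unname(v2["disgust"]), 8)
  expect_equal(unname(score_emotions(character(0), emol)), rep(0, 8))
})

test_that("daily emotion means average per-tweet scores", {
  m <- rbind(c(0, rep(0, 7)), c(4, rep(0, 7)), c(6, rep(0, 7)))
  d <- emotion_daily(m)
  expect_equal(unname(d["anger"]), 10 / 3)
  expect_equal(round(unname(d["anger"]), 1), 3.3)
  expect_equal(unname(emotion_daily(rbind(c(6, rep(0, 7))))["anger"]), 6)
  expect_equal(unname(emotion_daily(matrix(0, 2, 8))), rep(0, 8))
  expect_true(all(is.na(emotion_daily(NULL))))
})

test_that("keyword matching covers tokens, phrases, and case folding", {
  tok <- function(s) tokenize(clean_text(s))[[1]]
  ks <- default_keyword_sets()
  expect_true(matches_keywords(tok("unemployment is rising"), ks$economy))
  expect_false(matches_keywords(tok("i love dogs"), ks$loneliness))
  expect_true(matches_keywords(tok("the prime minister spoke"),
                               ks$institutions))
  # "minister" alone also matches; "ministerial" must not (whole tokens)
  expect_false(matches_keywords(tok("ministerial business"), ks$institutions))
  expect_true(matches_keywords(tok("MPs voted today"), ks$institutions))
  expect_true(matches_keywords(tok("a tech start-up here"), ks$economy))
  # the duplicated loneliness keyword is kept once
  expect_equal(sum(ks$loneliness == "solitary"), 1L)
})

test_that("filter_by_keywords validates the set name and subsets the stream", {
  tw <- tibble::tibble(text = c("jobs market news", "nice weather"),
                       tokens = tokenize(clean_text(c("jobs market news",
                                                      "nice weather"))))
  sub <- filter_by_keywords(tw, "economy")
  expect_equal(nrow(sub), 1L)
  expect_error(filter_by_keywords(tw, "sports"), "unknown keyword set")
})

test_that("build_daily_series matches the brute-force oracle on small streams", {
  lex <- gen_lexicons(5, 80)
  for (seed in 1:4) {
    sc <- stream_scenario(countries = c("FR", "ZA"), n_days = 2,
                          tweets_per_day = sample(5:25, 1), seed = seed)
    set.seed(seed)
    tw <- gen_tweet_stream(sc, lex)
    got <- build_daily_series(tw, lex$sentiment, lex$emotion)
    want <- brute_force_daily_series(tw, lex$sentiment, lex$emotion)
    expect_equal(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      w <- want[[paste(got$country[i], got$date[i])]]
      expect_equal(got$n_tweets[i], w$n)
      expect_equal(got$n_pos[i], w$n_pos)
      expect_equal(got$n_neg[i], w$n_neg)
      expect_equal(got$gnh[i], w$gnh)
      expect_equal(as.numeric(got[i, emotion_names()]),
                   unname(w$emotions))
    }
  }
})

test_that("daily series counts are conserved and ranges respected", {
  lex <- gen_lexicons(2, 60)
  sc <- stream_scenario(countries = c("FR", "NZ", "ZA"), n_days = 3,
                        tweets_per_day = 120, seed = 8)
  ds <- build_daily_series(gen_tweet_stream(sc, lex), lex$sentiment,
                           lex$emotion)
  expect_equal(ds$n_pos + ds$n_neu + ds$n_neg, ds$n_tweets)
  expect_true(all(ds$gnh >= 0 & ds$gnh <= 10))
  vals <- as.matrix(ds[, c(emotion_names(), "econ_fear", "loneliness_sad",
                           "inst_trust")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 10)))
})

test_that("context series average the named emotion over the keyword subset", {
  # two economy tweets with fear words, one plain tweet; single day
  lines <- c(
    jsonl_line("1", "2020-05-04T10:00:00Z", "FR", "jobs dread ahead"),
    jsonl_line("2", "2020-05-04T11:00:00Z", "FR", "economy worried signals"),
    jsonl_line("3", "2020-05-04T12:00:00Z", "FR", "sunny afternoon"))
  ds <- build_daily_series(read_tweets(write_tweet_jsonl(lines)), sent, emol)
  expect_equal(ds$econ_fear, (5 + 2) / 2)   # mean of fear 5 and fear 2
  expect_true(is.na(ds$inst_trust))         # no institutions tweets that day
  # context column differs from the all-tweet emotion (no aliasing)
  expect_false(isTRUE(all.equal(ds$econ_fear, ds$fear)))
})
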