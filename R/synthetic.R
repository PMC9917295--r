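#' Generate fixture sentiment and emotion lexicons
#'
#' Builds a deterministic synthetic vocabulary of distinct lowercase
#' letter-only tokens and partitions it into positive, negative and neutral
#' words; a subset of the neutral words carries emotion intensities on the
#' 0-10 scale. Tokens never collide with the default context keywords, so
#' keyword filtering and lexicon scoring stay independent.
#'
#' @param seed Integer seed; the result is a pure function of
#'   `(seed, vocab_size)`.
#' @param vocab_size Total number of tokens (>= 16).
#' @return List with elements `sentiment` (a `sentiment_lexicon`), `emotion`
#'   (an `emotion_lexicon`), and `vocab` (list of `positive`, `negative`,
#'   `neutral` token vectors).
#' @export
gen_lexicons <- function(seed, vocab_size = 120L) {
  if (vocab_size < 16L) stop("vocab_size must be >= 16", call. = FALSE)
  set.seed(seed)
  reserved <- unique(unlist(tokenize(clean_text(
    unlist(default_keyword_sets())))))
  words <- character(0)
  while (length(words) < vocab_size) {
    need <- vocab_size - length(words)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(letters, sample(5:8, 1L), replace = TRUE), collapse = "")
    }, character(1))
    words <- unique(c(words, setdiff(cand, reserved)))
  }
  words <- words[seq_len(vocab_size)]

  n_pos <- max(4L, floor(vocab_size / 4))
  n_neg <- max(4L, floor(vocab_size / 4))
  pos <- words[seq_len(n_pos)]
  neg <- words[n_pos + seq_len(n_neg)]
  neu <- words[-(seq_len(n_pos + n_neg))]

  sent <- new_sentiment_lexicon(
    stats::setNames(c(rep(1, n_pos), rep(-1, n_neg)), c(pos, neg)))

  # emotion words drawn from the neutral pool, a few per emotion
  emo <- emotion_names()
  per_emo <- max(2L, floor(length(neu) / (2L * length(emo))))
  emo_words <- sample(neu, per_emo * length(emo))
  m <- matrix(0, nrow = length(emo_words), ncol = 8L,
              dimnames = list(sort(emo_words), emo))
  for (i in seq_along(emo)) {
    w <- emo_words[(i - 1L) * per_emo + seq_len(per_emo)]
    m[w, emo[i]] <- sample(2:8, per_emo, replace = TRUE)
  }
  list(sentiment = sent, emotion = new_emotion_lexicon(m),
       vocab = list(positive = pos, negative = neg, neutral = neu))
}

#' Describe a synthetic tweet-stream scenario
#'
#' The scenario fixes the study conditions a generated stream emulates: the
#' countries and date range, daily volume, the daily sentiment mixture
#' (positive/negative/neutral shares on the simplex), per-emotion word
#' injection rates, context keyword injection rates, and the decoration
#' noise (mentions, hashtags, digits, emojis) that exercises the cleaner.
#'
#' @param countries ISO alpha-2 codes (must be covered by `tz_map` at build
#'   time).
#' @param start_date First local calendar day (`Date` or string).
#' @param n_days Number of days.
#' @param tweets_per_day Tweets per country-day.
#' @param p_pos,p_neg Daily positive/negative shares; scalars or vectors of
#'   length `n_days`. `p_neu` is the complement and all three must stay on
#'   the simplex.
#' @param emotion_rates Named numeric vector (subset of [emotion_names()]):
#'   probability that a tweet carries one word of that emotion.
#' @param keyword_rates Named numeric vector over
#'   `c("economy", "loneliness", "institutions")`: probability that a tweet
#'   has a context keyword injected.
#' @param noise_rate Probability of each decoration type per tweet.
#' @param seed Integer seed.
#' @return A `stream_scenario` list.
#' @export
stream_scenario <- function(countries = c("FR", "NZ"),
                            start_date = "2020-03-02", n_days = 7L,
                            tweets_per_day = 500L,
                            p_pos = 0.45, p_neg = 0.25,
                            emotion_rates = c(anger = 0.10, fear = 0.12,
                                              trust = 0.15, sadness = 0.08,
                                              joy = 0.12, disgust = 0.05,
                                              surprise = 0.06,
                                              anticipation = 0.08),
                            keyword_rates = c(economy = 0.05,
                                              loneliness = 0.03,
                                              institutions = 0.04),
                            noise_rate = 0.25, seed = 1L) {
  p_pos <- rep_len(p_pos, n_days)
  p_neg <- rep_len(p_neg, n_days)
  if (any(p_pos < 0 | p_neg < 0 | p_pos + p_neg > 1 + 1e-12)) {
    stop("daily sentiment shares must lie on the simplex", call. = FALSE)
  }
  stopifnot(all(emotion_rates >= 0 & emotion_rates <= 1),
            all(keyword_rates >= 0 & keyword_rates <= 1))
  structure(list(countries = countries,
                 start_date = as.Date(start_date), n_days = as.integer(n_days),
                 tweets_per_day = as.integer(tweets_per_day),
                 p_pos = p_pos, p_neg = p_neg,
                 emotion_rates = emotion_rates,
                 keyword_rates = keyword_rates,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "stream_scenario")
}

#' Generate a synthetic tweet stream
#'
#' Draws tweets per country-day with a multinomial sentiment class per the
#' scheduled shares; positive/negative tweets carry one or two words of the
#' matching polarity plus neutral filler, neutral tweets only filler.
#' Emotion words and context keywords are injected at the scenario's rates,
#' and a fixed small set of decorations (an @-mention, a hashtag, digits, an
#' emoji) is sprinkled in so the cleaning stage is exercised. Deterministic:
#' the same scenario and lexicons give a byte-identical file.
#'
#' @param scenario A [stream_scenario()].
#' @param lexicons Result of [gen_lexicons()].
#' @param path Optional JSONL output path; when given the stream is written
#'   one JSON object per line.
#' @return Tibble of tweet records (`id`, `timestamp` in UTC, `country`,
#'   `text`), invisibly if `path` is given.
#' @export
gen_tweet_stream <- function(scenario, lexicons, path = NULL) {
  stopifnot(inherits(scenario, "stream_scenario"))
  set.seed(scenario$seed)
  vocab <- lexicons$vocab
  emo_lex <- unclass(lexicons$emotion)
  emo_words <- lapply(emotion_names(),
                      function(e) rownames(emo_lex)[emo_lex[, e] > 0])
  names(emo_words) <- emotion_names()
  kw_sets <- default_keyword_sets()
  tz_map <- default_tz_map()
  decorations <- c("@somebody", "#topic", "42", "\U0001F600", "\U0001F622")

  dates <- scenario$start_date + seq_len(scenario$n_days) - 1L
  rows <- vector("list", length(scenario$countries) * scenario$n_days)
  idx <- 0L
  serial <- 0L
  for (cc in scenario$countries) {
    tz <- if (cc %in% names(tz_map)) tz_map[[cc]] else "UTC"
    for (d in seq_len(scenario$n_days)) {
      n <- scenario$tweets_per_day
      probs <- c(scenario$p_pos[d], scenario$p_neg[d],
                 1 - scenario$p_pos[d] - scenario$p_neg[d])
      cls <- sample(c("pos", "neg", "neu"), n, replace = TRUE, prob = probs)
      texts <- character(n)
      for (i in seq_len(n)) {
        w <- sample(vocab$neutral, sample(3:6, 1L), replace = TRUE)
        if (cls[i] == "pos") {
          w <- c(w, sample(vocab$positive, sample(1:2, 1L), replace = TRUE))
        } else if (cls[i] == "neg") {
          w <- c(w, sample(vocab$negative, sample(1:2, 1L), replace = TRUE))
        }
        for (e in names(scenario$emotion_rates)) {
          if (stats::runif(1) < scenario$emotion_rates[[e]] &&
              length(emo_words[[e]]) > 0L) {
            w <- c(w, sample(emo_words[[e]], 1L))
          }
        }
        for (ks in names(scenario$keyword_rates)) {
          if (stats::runif(1) < scenario$keyword_rates[[ks]]) {
            w <- c(w, sample(kw_sets[[ks]], 1L))
          }
        }
        w <- sample(w)  # shuffle word order
        if (stats::runif(1) < scenario$noise_rate) {
          w <- append(w, sample(decorations, 1L),
                      after = sample(0:length(w), 1L))
        }
        texts[i] <- paste(w, collapse = " ")
      }
      # local times on the scheduled day, expressed in UTC
      hour <- sample(0:23, n, replace = TRUE)
      minute <- sample(0:59, n, replace = TRUE)
      local <- as.POSIXct(paste0(dates[d], sprintf(" %02d:%02d:00", hour,
                                                   minute)), tz = tz)
      ids <- sprintf("t%08d", serial + seq_len(n))
      serial <- serial + n
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        id = ids,
        timestamp = as.POSIXct(format(local, tz = "UTC",
                                      format = "%Y-%m-%d %H:%M:%S"),
                               tz = "UTC"),
        country = cc, text = texts)
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(idx)])
  if (!is.null(path)) {
    ts <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    lines <- sprintf('{"id":"%s","timestamp":"%s","country":"%s","text":"%s"}',
                     out$id, ts, out$country, out$text)
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Describe a synthetic panel scenario
#'
#' Fixes the data-generating process for a weekly country panel drawn from
#' the dynamic panel model itself: true coefficients, two-wave Gaussian
#' epidemic curves, a step-function stringency schedule responding to the
#' waves, a linear mobility response, emotion/context series, and one-way
#' cluster (country) random effects with idiosyncratic noise and an
#' optional AR(1) component.
#'
#' Default coefficients are the combined-model magnitudes reported for this
#' design (lag 0.922; cases -0.039; mobility 0.004; expected stringency
#' decrease -0.032, increase -0.049; intercept 0.536), with noise scales
#' chosen so the fitted model explains about 85% of the variance, and seven
#' Northern plus three Southern countries.
#'
#' @param G Number of countries (>= 2).
#' @param T_weeks Number of ISO weeks of 2020 covered (<= 52, starting
#'   W01).
#' @param countries Optional country codes; default the ten study-country
#'   codes when `G = 10`, otherwise synthetic codes with a 70/30
#'   North/South split.
#' @param alpha,rho,beta_cases,beta_mobility,beta_decr,beta_incr True
#'   coefficients (`|rho| < 1`).
#' @param beta_emotions Named numeric vector of true emotion coefficients
#'   (default all zero; name a subset to plant effects).
#' @param beta_context Named vector over
#'   `c("econ_fear", "inst_trust", "loneliness_sad")` (default zero).
#' @param sigma_c Cluster random-effect SD (> 0).
#' @param sigma_e Idiosyncratic SD (> 0).
#' @param ar1 AR(1) coefficient of the idiosyncratic part (0 disables).
#' @param seed Integer seed.
#' @return A `panel_scenario` list.
#' @export
panel_scenario <- function(G = 10L, T_weeks = 52L, countries = NULL,
                           alpha = 0.536, rho = 0.922,
                           beta_cases = -0.039, beta_mobility = 0.004,
                           beta_decr = -0.032, beta_incr = -0.049,
                           beta_emotions = NULL, beta_context = NULL,
                           sigma_c = 0.03, sigma_e = 0.10, ar1 = 0,
                           seed = 1L) {
  if (G < 2L) stop("need G >= 2 countries", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1 (stationarity)", call. = FALSE)
  if (sigma_c <= 0 || sigma_e <= 0) stop("noise SDs must be > 0", call. = FALSE)
  be <- stats::setNames(numeric(8L), emotion_names())
  if (!is.null(beta_emotions)) {
    stopifnot(all(names(beta_emotions) %in% emotion_names()))
    be[names(beta_emotions)] <- beta_emotions
  }
  bc <- c(econ_fear = 0, inst_trust = 0, loneliness_sad = 0)
  if (!is.null(beta_context)) {
    stopifnot(all(names(beta_context) %in% names(bc)))
    bc[names(beta_context)] <- beta_context
  }
  if (is.null(countries)) {
    countries <- if (G == 10L) names(default_tz_map()) else {
      sprintf("S%02d", seq_len(G))
    }
  }
  stopifnot(length(countries) == G)
  structure(list(G = as.integer(G), T_weeks = as.integer(T_weeks),
                 countries = countries, alpha = alpha, rho = rho,
                 beta_cases = beta_cases, beta_mobility = beta_mobility,
                 beta_decr = beta_decr, beta_incr = beta_incr,
                 beta_emotions = be, beta_context = bc,
                 sigma_c = sigma_c, sigma_e = sigma_e, ar1 = ar1,
                 seed = as.integer(seed)),
            class = "panel_scenario")
}

#' Generate a weekly panel from the dynamic panel model
#'
#' Builds covariate paths from the scenario's wave/step schedules, then
#' simulates weekly GNH forward from the model with cluster-correlated
#' errors. The returned panel has the same columns [assemble_panel()]
#' produces, plus the truth record for recovery studies.
#'
#' @param scenario A [panel_scenario()].
#' @return List with `panel` (tibble) and `truth` (named numeric vector of
#'   the true coefficients, named by regressor column).
#' @export
gen_panel <- function(scenario) {
  stopifnot(inherits(scenario, "panel_scenario"))
  set.seed(scenario$seed)
  G <- scenario$G; T_w <- scenario$T_weeks
  countries <- scenario$countries
  hemi_map <- default_hemisphere_map()
  extra <- setdiff(countries, names(hemi_map))
  if (length(extra) > 0L) {
    n_s <- max(1L, round(0.3 * length(extra)))
    hemi_extra <- stats::setNames(
      rep(c("S", "N"), c(n_s, length(extra) - n_s)), extra)
    hemi_map <- c(hemi_map, hemi_extra)
  }

  # week scaffolding: ISO weeks of 2020 starting W01 (Thursday 2020-01-02)
  thursdays <- as.Date("2020-01-02") + 7 * (seq_len(T_w) - 1L)
  weeks <- iso_week(thursdays)
  emo <- emotion_names()
  ctx <- c("econ_fear", "inst_trust", "loneliness_sad")

  panels <- vector("list", G)
  for (gi in seq_len(G)) {
    cc <- countries[gi]
    t <- seq_len(T_w)
    # two-wave Gaussian epidemic curve (weekly mean new cases per million)
    p1 <- 12 + stats::runif(1, -2, 2); p2 <- 45 + stats::runif(1, -3, 2)
    h1 <- stats::runif(1, 40, 120); h2 <- stats::runif(1, 80, 250)
    w1 <- stats::runif(1, 2.5, 4); w2 <- stats::runif(1, 3, 5)
    cases <- h1 * exp(-(t - p1)^2 / (2 * w1^2)) +
      h2 * exp(-(t - p2)^2 / (2 * w2^2))
    cases <- pmax(0, cases * exp(stats::rnorm(T_w, 0, 0.15)))
    # stringency: steps up around each wave, relaxes in between
    s <- rep(15, T_w)
    s[t >= p1 - 2 & t <= p1 + 8] <- 70
    s[t > p1 + 8 & t <= p1 + 14] <- 40
    s[t >= p2 - 2] <- 65
    s <- pmin(100, pmax(0, s))
    mobility <- 2 + 0.15 * s + stats::rnorm(T_w, 0, 1)

    emat <- matrix(0, T_w, 8L, dimnames = list(NULL, emo))
    for (e in emo) {
      lvl <- stats::runif(1, 2, 5)
      emat[, e] <- as.numeric(stats::filter(stats::rnorm(T_w, 0, 0.3),
                                            0.5, method = "recursive")) + lvl
    }
    cmat <- matrix(0, T_w, 3L, dimnames = list(NULL, ctx))
    for (c2 in ctx) {
      lvl <- stats::runif(1, 2, 5)
      cmat[, c2] <- as.numeric(stats::filter(stats::rnorm(T_w, 0, 0.4),
                                             0.4, method = "recursive")) + lvl
    }

    ihs_c <- ihs(cases)
    d_ihs <- c(NA_real_, diff(ihs_c))
    dum <- stringency_change_dummies(s)
    cal <- calendar_dummies(thursdays, rep(cc, T_w), hemisphere_map = hemi_map)

    xb <- ifelse(is.na(d_ihs), 0, scenario$beta_cases * d_ihs) +
      scenario$beta_mobility * mobility +
      ifelse(is.na(dum$decr_next), 0, scenario$beta_decr * dum$decr_next) +
      ifelse(is.na(dum$incr_next), 0, scenario$beta_incr * dum$incr_next) +
      drop(emat %*% scenario$beta_emotions) +
      drop(cmat %*% scenario$beta_context)

    c_i <- stats::rnorm(1, 0, scenario$sigma_c)
    eps <- stats::rnorm(T_w, 0, scenario$sigma_e)
    if (scenario$ar1 != 0) {
      eps <- as.numeric(stats::filter(eps, scenario$ar1,
                                      method = "recursive"))
    }
    gnh <- numeric(T_w)
    steady <- (scenario$alpha + mean(xb)) / (1 - scenario$rho)
    gnh[1L] <- steady + c_i / (1 - scenario$rho) + eps[1L]
    for (tt in 2:T_w) {
      gnh[tt] <- scenario$alpha + scenario$rho * gnh[tt - 1L] + xb[tt] +
        c_i + eps[tt]
    }

    sp <- split_case_changes(d_ihs)
    pc <- tibble::tibble(
      country = cc, week = weeks, thursday = thursdays,
      gnh = gnh, lag_gnh = c(NA_real_, gnh[-T_w]),
      cases_pm = cases, ihs_cases = ihs_c, d_ihs_cases = d_ihs,
      d_ihs_cases_incr = sp$increase, d_ihs_cases_decr = sp$decrease,
      stringency = s, residential_mobility = mobility,
      decr_next = dum$decr_next, incr_next = dum$incr_next)
    for (e in emo) pc[[e]] <- emat[, e]
    for (c2 in ctx) pc[[c2]] <- cmat[, c2]
    pc$month <- cal$month
    pc$spring <- cal$spring
    pc$summer <- cal$summer
    pc$fall <- cal$fall
    panels[[gi]] <- pc
  }
  panel <- dplyr::bind_rows(panels)
  truth <- c(`(Intercept)` = scenario$alpha, lag_gnh = scenario$rho,
             d_ihs_cases = scenario$beta_cases,
             residential_mobility = scenario$beta_mobility,
             decr_next = scenario$beta_decr, incr_next = scenario$beta_incr,
             stats::setNames(as.numeric(scenario$beta_emotions), emo),
             stats::setNames(as.numeric(scenario$beta_context), ctx))
  list(panel = panel, truth = truth)
}
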