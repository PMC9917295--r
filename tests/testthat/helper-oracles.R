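# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written as plain, slow, per-item code so it
# shares no logic with the package implementations it checks.

# Brute-force daily series: enumerate every tweet one by one.
brute_force_daily_series <- function(tweets, sent_lex, emo_lex,
                                     tz_map = default_tz_map()) {
  rows <- list()
  for (i in seq_len(nrow(tweets))) {
    tz <- tz_map[[tweets$country[i]]]
    lt <- format(tweets$timestamp[i], tz = tz, format = "%Y-%m-%d %H")
    toks <- tokenize(clean_text(tweets$text[i]))[[1]]
    pol <- 0
    for (tk in toks) pol <- pol + token_polarity(sent_lex, tk)
    ev <- rep(0, 8)
    for (tk in toks) ev <- ev + as.numeric(token_emotions(emo_lex, tk))
    ev <- pmin(ev, 10)
    rows[[i]] <- list(country = tweets$country[i],
                      date = substr(lt, 1, 10), hour = substr(lt, 12, 13),
                      cls = if (pol > 0) "pos" else if (pol < 0) "neg" else "neu",
                      ev = ev, toks = list(toks))
  }
  keys <- sapply(rows, function(r) paste(r$country, r$date))
  out <- list()
  for (kd in sort(unique(keys))) {
    sub <- rows[keys == kd]
    hours <- sapply(sub, `[[`, "hour")
    hg <- c()
    for (h in unique(hours)) {
      hs <- sub[hours == h]
      np <- sum(sapply(hs, `[[`, "cls") == "pos")
      nn <- sum(sapply(hs, `[[`, "cls") == "neg")
      hg <- c(hg, if (np + nn > 0) 5 * (1 + (np - nn) / (np + nn)) else 5)
    }
    em <- rowMeans(sapply(sub, `[[`, "ev"))
    out[[kd]] <- list(
      country = sub[[1]]$country, date = sub[[1]]$date,
      n = length(sub),
      n_pos = sum(sapply(sub, `[[`, "cls") == "pos"),
      n_neg = sum(sapply(sub, `[[`, "cls") == "neg"),
      n_neu = sum(sapply(sub, `[[`, "cls") == "neu"),
      gnh = mean(hg), emotions = em)
  }
  out
}

# Normal-equation OLS, the textbook way.
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X) %*% (t(X) %*% y))
}

# Exhaustive Spearman permutation p-value via expand.grid filtering
# (independent of the package's recursive permutation generator).
perm_spearman_p <- function(x, y) {
  n <- length(x)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n)))
  is_perm <- apply(grid, 1, function(r) length(unique(r)) == n)
  perms <- grid[is_perm, , drop = FALSE]
  rho_obs <- cor(rank(x), rank(y))
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# ---- fixture builders -------------------------------------------------------

write_fixture_sentiment <- function(path = tempfile(fileext = ".tsv"),
                                    extra = character(0)) {
  writeLines(c("# fixture sentiment lexicon",
               "love\t1", "good\t1", "great\t1", "happy\t1",
               "hate\t-1", "awful\t-1", "terrible\t-1", "gloomy\t-1",
               extra), path)
  path
}

write_fixture_emotions <- function(path = tempfile(fileext = ".tsv"),
                                   extra = character(0)) {
  writeLines(c("# fixture emotion lexicon",
               "fury\tanger\t6", "fury\tdisgust\t4",
               "dread\tfear\t5", "worried\tfear\t2",
               "reliable\ttrust\t3", "gloomy\tsadness\t4",
               "love\tjoy\t2", "love\ttrust\t1",
               "shock\tsurprise\t5", "eager\tanticipation\t3",
               extra), path)
  path
}

write_tweet_jsonl <- function(records, path = tempfile(fileext = ".jsonl")) {
  writeLines(records, path)
  path
}

jsonl_line <- function(id, ts, country, text) {
  sprintf('{"id":"%s","timestamp":"%s","country":"%s","text":"%s"}',
          id, ts, country, text)
}

# A small deterministic covariate table covering the given dates.
make_covariates <- function(countries, dates, stringency = NULL) {
  out <- NULL
  for (cc in countries) {
    n <- length(dates)
    s <- if (is.null(stringency)) rep(c(20, 60), length.out = n) else
      rep_len(stringency, n)
    out <- rbind(out, data.frame(
      country = cc, date = dates,
      new_cases = seq_len(n) * 10, population = 5e6,
      stringency = s, residential_mobility = 5 + seq_len(n) %% 7))
  }
  tibble::as_tibble(out)
}

# Regressor set of the combined panel model, used across test files.
combined_regressors <- function() {
  c("lag_gnh", "d_ihs_cases", "residential_mobility", "decr_next",
    "incr_next")
}
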