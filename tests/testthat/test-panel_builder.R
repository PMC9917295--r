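test_that("7-day centered moving average preserves constants and obeys edges", {
  expect_equal(moving_average_7d(rep(7, 10)),
               c(NA, NA, NA, 7, 7, 7, 7, NA, NA, NA))
  ma <- moving_average_7d(1:14)
  expect_equal(ma[7], 7)      # mean of 4..10
  expect_true(all(is.na(ma[c(1:3, 12:14)])))
  expect_true(all(is.na(moving_average_7d(1:6))))
  # a missing value poisons every window containing it
  x <- c(1:5, NA, 7:14)
  expect_true(all(is.na(moving_average_7d(x)[3:9])))
})

test_that("weekly aggregation means ISO weeks and applies the 4-day rule", {
  # 2020-01-06 is Monday of ISO week 2020-W02
  days <- as.Date("2020-01-06") + 0:6
  w <- weekly_aggregate(days, rep(6.5, 7))
  expect_equal(w$value, 6.5)
  expect_equal(w$week, "2020-W02")
  expect_equal(w$thursday, as.Date("2020-01-09"))

  w2 <- weekly_aggregate(days, 1:7)
  expect_equal(w2$value, 4)

  w3 <- weekly_aggregate(days[1:3], 1:3)
  expect_equal(nrow(w3), 0L)                       # 3 observed days: dropped
  w4 <- weekly_aggregate(days[1:3], 1:3, min_days = 3)
  expect_equal(w4$value, 2)                        # rule is configurable
})

test_that("ihs matches its closed form and asymptotics", {
  expect_equal(ihs(0), 0)
  expect_equal(ihs(1), 0.881374, tolerance = 1e-6)
  # identity vs an independent implementation to 12 significant digits
  x <- c(0, 10^seq(-3, 6, by = 0.5))
  expect_equal(ihs(x), asinh(x), tolerance = 1e-12)
  expect_equal(ihs(-x), -ihs(x))
  expect_true(all(diff(ihs(seq(-5, 5, by = 0.1))) > 0))
  expect_lt(abs(ihs(1e6) - log(2e6)), 1e-6)
})

test_that("cases per million scales by population", {
  expect_equal(cases_per_million(100, 1e6), 100)
  expect_equal(cases_per_million(0, 5e6), 0)
  expect_equal(cases_per_million(57, 6e5), 95)
  expect_error(cases_per_million(1, 0), "positive")
})

test_that("stringency change dummies anticipate the next week", {
  d <- stringency_change_dummies(c(50, 60))
  expect_equal(d$decr_next[1], 0); expect_equal(d$incr_next[1], 1)
  d <- stringency_change_dummies(c(60, 60))
  expect_equal(d$decr_next[1], 0); expect_equal(d$incr_next[1], 0)
  d <- stringency_change_dummies(c(60, 50))
  expect_equal(d$decr_next[1], 1); expect_equal(d$incr_next[1], 0)
  expect_true(all(is.na(d[2, ])))                  # final week has no t+1
  set.seed(3)
  d <- stringency_change_dummies(sample(0:100, 40, replace = TRUE))
  ok <- stats::complete.cases(d)
  expect_true(all(d$decr_next[ok] + d$incr_next[ok] <= 1))
})

test_that("case-change split reconstructs the difference", {
  s <- split_case_changes(c(0.3, -0.2, 0))
  expect_equal(s$increase, c(0.3, 0, 0))
  expect_equal(s$decrease, c(0, -0.2, 0))
  set.seed(11)
  d <- rnorm(200)
  s <- split_case_changes(d)
  expect_equal(s$increase + s$decrease, d)
  expect_true(all(s$increase >= 0) && all(s$decrease <= 0))
})

test_that("calendar dummies are hemisphere-aware with Winter as reference", {
  th <- as.Date("2020-04-16")  # Thursday of the week containing 15 April
  fr <- calendar_dummies(th, "FR")
  expect_equal(c(fr$spring, fr$summer, fr$fall), c(1, 0, 0))
  za <- calendar_dummies(th, "ZA")
  expect_equal(c(za$spring, za$summer, za$fall), c(0, 0, 1))
  de <- calendar_dummies(as.Date("2020-01-16"), "DE")
  expect_equal(c(de$spring, de$summer, de$fall), c(0, 0, 0))
  expect_equal(de$month, 1L)
  expect_error(calendar_dummies(th, "QQ"), "hemisphere")
  # season dummies never overlap
  ths <- as.Date("2020-01-02") + 7 * (0:51)
  cal <- calendar_dummies(ths, rep("NZ", 52))
  expect_true(all(cal$spring + cal$summer + cal$fall <= 1))
})

test_that("assemble_panel joins country-weeks, lags within country", {
  lex <- gen_lexicons(3, 80)
  sc <- stream_scenario(countries = c("FR", "NZ"), start_date = "2020-03-02",
                        n_days = 21, tweets_per_day = 60, seed = 2)
  daily <- build_daily_series(gen_tweet_stream(sc, lex), lex$sentiment,
                              lex$emotion)
  cov <- make_covariates(c("FR", "NZ"),
                         as.Date("2020-03-02") + 0:20)
  panel <- assemble_panel(daily, cov)
  expect_equal(nrow(panel), 6L)                    # 3 full ISO weeks x 2
  expect_true(all(is.na(panel$lag_gnh[panel$week == "2020-W10"])))
  for (cc in c("FR", "NZ")) {
    sub <- panel[panel$country == cc, ]
    expect_equal(sub$lag_gnh[-1], sub$gnh[-nrow(sub)])
    expect_equal(sub$d_ihs_cases[-1], diff(ihs(sub$cases_pm)))
  }
  # join conservation: every row is one country-week, no duplication
  expect_false(any(duplicated(panel[, c("country", "week")])))
  # increase/decrease parts reconstruct the change
  ok <- !is.na(panel$d_ihs_cases)
  expect_equal(panel$d_ihs_cases_incr[ok] + panel$d_ihs_cases_decr[ok],
               panel$d_ihs_cases[ok])
})

test_that("a source missing early weeks shrinks the join, not the machinery", {
  lex <- gen_lexicons(3, 80)
  sc <- stream_scenario(countries = c("FR", "NZ"), start_date = "2020-03-02",
                        n_days = 28, tweets_per_day = 50, seed = 4)
  daily <- build_daily_series(gen_tweet_stream(sc, lex), lex$sentiment,
                              lex$emotion)
  cov <- make_covariates(c("FR", "NZ"), as.Date("2020-03-02") + 0:27)
  # mobility unobserved for the first 14 days (2 ISO weeks)
  cov$residential_mobility[cov$date <= "2020-03-15"] <- NA
  panel <- assemble_panel(daily, cov)
  full <- assemble_panel(daily, make_covariates(c("FR", "NZ"),
                                                as.Date("2020-03-02") + 0:27))
  expect_equal(nrow(panel), nrow(full))            # rows survive the join
  expect_equal(sum(is.na(panel$residential_mobility)), 4L)  # 2 weeks x 2
})

test_that("panel and daily series round-trip through CSV", {
  lex <- gen_lexicons(6, 60)
  sc <- stream_scenario(countries = "FR", n_days = 8, tweets_per_day = 40,
                        seed = 6)
  daily <- build_daily_series(gen_tweet_stream(sc, lex), lex$sentiment,
                              lex$emotion)
  p <- tempfile(fileext = ".csv")
  write_daily_series(daily, p)
  back <- read_daily_series(p)
  expect_equal(back$gnh, daily$gnh)
  expect_equal(back$date, daily$date)
})
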