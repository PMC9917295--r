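#' Seven-day centered moving average
#'
#' Smooths a daily series with the centered 7-day window (t-3 ... t+3) used
#' for the descriptive daily figures. Windows containing any missing value
#' are missing; the first and last three positions are always missing (no
#' edge extrapolation).
#'
#' @param x Numeric vector ordered by date, one entry per consecutive day.
#' @return Numeric vector of the same length.
#' @export
moving_average_7d <- function(x) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= 7L) {
    cs <- cumsum(c(0, x))
    idx <- 4:(n - 3L)
    out[idx] <- (cs[idx + 4L] - cs[idx - 3L]) / 7
  }
  out
}

#' ISO-8601 week label and representative Thursday
#'
#' Weeks follow ISO-8601 (Monday-Sunday); the representative date of a week
#' (used for calendar dummies) is its Thursday, which always falls in the
#' ISO year-week it labels.
#'
#' @param date A `Date` vector.
#' @return For `iso_week()`, labels like `"2020-W15"`; for
#'   `iso_week_thursday()`, the `Date` of that week's Thursday.
#' @export
iso_week <- function(date) {
  format(as.Date(date), "%G-W%V")
}

#' @rdname iso_week
#' @export
iso_week_thursday <- function(date) {
  date <- as.Date(date)
  wd <- as.integer(format(date, "%u"))  # 1 = Monday
  date + (4L - wd)
}

#' Aggregate a daily series to ISO weeks
#'
#' Weekly value = mean of the observed daily values in the ISO week
#' (Mon-Sun). Weeks with fewer than `min_days` observed (non-missing) days
#' are dropped.
#'
#' @param date `Date` vector.
#' @param value Numeric vector aligned with `date`.
#' @param min_days Completeness rule: minimum observed days per retained
#'   week (default 4).
#' @return Tibble with columns `week` (ISO label), `thursday` (Date),
#'   `value`.
#' @export
weekly_aggregate <- function(date, value, min_days = 4L) {
  keep <- !is.na(value)
  date <- date[keep]
  value <- value[keep]
  if (length(date) == 0L) {
    return(tibble::tibble(week = character(0),
                          thursday = as.Date(character(0)),
                          value = numeric(0)))
  }
  wk <- iso_week(date)
  n <- tapply(value, wk, length)
  m <- tapply(value, wk, mean)
  th <- tapply(iso_week_thursday(date), wk, function(d) d[1L])
  ok <- n >= min_days
  tibble::tibble(week = names(m)[ok],
                 thursday = as.Date(as.numeric(th[ok]), origin = "1970-01-01"),
                 value = as.numeric(m[ok]))
}

#' Inverse hyperbolic sine transform
#'
#' \deqn{ihs(x) = \ln(x + \sqrt{x^2 + 1})}
#' Log-like for large `x` but defined (and 0) at zero, which makes it the
#' standard transform for case counts that hit zero.
#'
#' @param x Numeric vector.
#' @return Transformed values.
#' @export
ihs <- function(x) {
  # odd-symmetric evaluation: identical to ln(x + sqrt(x^2 + 1)) but avoids
  # the catastrophic cancellation that form suffers for large negative x
  sign(x) * log(abs(x) + sqrt(x^2 + 1))
}

#' New cases per million inhabitants
#'
#' @param new_cases Nonnegative daily case counts.
#' @param population Population size(s), must be positive.
#' @return `new_cases * 1e6 / population`.
#' @export
cases_per_million <- function(new_cases, population) {
  if (any(population <= 0, na.rm = TRUE)) {
    stop("population must be positive", call. = FALSE)
  }
  new_cases * 1e6 / population
}

#' Next-week stringency change dummies
#'
#' For a weekly stringency series `S(t)` the anticipation dummies are
#' `decr_next(t) = 1` iff `S(t+1) - S(t) < 0` and `incr_next(t) = 1` iff
#' `S(t+1) - S(t) > 0`; both are 0 when unchanged and both missing for the
#' final week (no `t+1`).
#'
#' @param weekly_stringency Numeric vector ordered by week.
#' @return Tibble with columns `decr_next`, `incr_next` (0/1/NA).
#' @export
stringency_change_dummies <- function(weekly_stringency) {
  n <- length(weekly_stringency)
  d <- c(diff(weekly_stringency), NA_real_)
  tibble::tibble(decr_next = ifelse(is.na(d), NA_real_, as.numeric(d < 0)),
                 incr_next = ifelse(is.na(d), NA_real_, as.numeric(d > 0)))
}

#' Split a differenced series into increase and decrease parts
#'
#' `increase = max(delta, 0)`, `decrease = min(delta, 0)`; the parts always
#' reconstruct the difference (`increase + decrease = delta`).
#'
#' @param delta Numeric vector of first differences.
#' @return Tibble with columns `increase`, `decrease`.
#' @export
split_case_changes <- function(delta) {
  tibble::tibble(increase = pmax(delta, 0), decrease = pmin(delta, 0))
}

#' Month and season dummies for a week
#'
#' The month is taken from the week's representative Thursday. Seasons are
#' meteorological and hemisphere-aware: in the North, Spring = Mar-May,
#' Summer = Jun-Aug, Fall = Sep-Nov; in the South shifted six months.
#' Winter is the omitted reference category. The hemisphere shift is what
#' keeps pooled month and season dummies from being perfectly collinear in
#' a two-hemisphere sample.
#'
#' @param thursday `Date` vector of week Thursdays.
#' @param country Country codes aligned with `thursday`.
#' @param hemisphere_map Named vector country -> `"N"`/`"S"`, defaulting to
#'   [default_hemisphere_map()]; an unmapped country is a configuration
#'   error.
#' @return Tibble with columns `month` (integer 1-12), `spring`, `summer`,
#'   `fall` (0/1).
#' @export
calendar_dummies <- function(thursday, country,
                             hemisphere_map = default_hemisphere_map()) {
  unknown <- setdiff(unique(country), names(hemisphere_map))
  if (length(unknown) > 0L) {
    stop("no hemisphere configured for country: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  month <- as.integer(format(thursday, "%m"))
  hemi <- unname(hemisphere_map[country])
  # shift southern months by 6 so the northern season lookup applies
  m_eff <- ifelse(hemi == "S", (month + 5L) %% 12L + 1L, month)
  tibble::tibble(
    month = month,
    spring = as.numeric(m_eff %in% 3:5),
    summer = as.numeric(m_eff %in% 6:8),
    fall = as.numeric(m_eff %in% 9:11)
  )
}

#' Read a daily covariate table from CSV
#'
#' Expected columns: `country, date, new_cases, population, stringency,
#' residential_mobility` and optionally `unemployment`.
#'
#' @param path CSV path.
#' @return Tibble with `date` parsed as `Date`.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(country = "character"))
  req <- c("country", "date", "new_cases", "population", "stringency",
           "residential_mobility")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("covariate file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (any(df$stringency < 0 | df$stringency > 100, na.rm = TRUE)) {
    stop("stringency outside [0, 100]", call. = FALSE)
  }
  if (any(df$new_cases < 0, na.rm = TRUE)) {
    stop("new_cases must be nonnegative", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Assemble the weekly country panel
#'
#' Merges the Twitter daily series with the covariate table into one row per
#' country-week holding every regressor of the dynamic panel model: weekly
#' mean GNH and its within-country lag, the first difference of the IHS of
#' weekly mean new cases per million (plus its increase/decrease split and
#' the level behind a switch), weekly mean residential mobility, next-week
#' stringency change dummies, weekly means of the 8 emotions and 3 context
#' variables, and month/season dummies.
#'
#' Rows are produced for the inner join of country-weeks present in both
#' sources; model-specific complete-case dropping happens at fit time, so
#' columns here may contain `NA` (e.g. the lag in each country's first week,
#' the dummies in its last).
#'
#' @param daily_series Tibble from [build_daily_series()].
#' @param covariates Tibble as from [read_covariates()].
#' @param min_days Weekly completeness rule passed to [weekly_aggregate()].
#' @param hemisphere_map See [calendar_dummies()].
#' @return Tibble, one row per country-week, ordered by country then week.
#' @export
assemble_panel <- function(daily_series, covariates, min_days = 4L,
                           hemisphere_map = default_hemisphere_map()) {
  emo <- emotion_names()
  twitter_cols <- c("gnh", emo, "econ_fear", "loneliness_sad", "inst_trust")
  cov_cols <- c("cases_pm", "stringency", "residential_mobility")

  cov <- covariates
  cov$cases_pm <- cases_per_million(cov$new_cases, cov$population)

  weekly_block <- function(df, cols) {
    res <- NULL
    for (cc in unique(df$country)) {
      sub <- df[df$country == cc, , drop = FALSE]
      base <- NULL
      for (col in cols) {
        w <- weekly_aggregate(sub$date, sub[[col]], min_days = min_days)
        names(w)[names(w) == "value"] <- col
        base <- if (is.null(base)) w else
          dplyr::full_join(base, w, by = c("week", "thursday"))
      }
      if (!is.null(base) && nrow(base) > 0L) {
        base$country <- cc
        res <- dplyr::bind_rows(res, base)
      }
    }
    res
  }

  tw <- weekly_block(daily_series, twitter_cols)
  cv <- weekly_block(cov, cov_cols)
  if (is.null(tw) || is.null(cv)) stop("no overlapping country-weeks", call. = FALSE)
  panel <- dplyr::inner_join(tw, cv, by = c("country", "week", "thursday"))
  if (nrow(panel) == 0L) stop("no overlapping country-weeks", call. = FALSE)
  panel <- panel[order(panel$country, panel$week), , drop = FALSE]

  by_country <- function(x, f) {
    unlist(lapply(split(x, panel$country), f), use.names = FALSE)
  }
  panel <- panel[order(panel$country, panel$week), , drop = FALSE]

  panel$lag_gnh <- by_country(panel$gnh, function(v) c(NA_real_, v[-length(v)]))
  panel$ihs_cases <- ihs(panel$cases_pm)
  panel$d_ihs_cases <- by_country(panel$ihs_cases, function(v) c(NA_real_, diff(v)))
  sp <- split_case_changes(panel$d_ihs_cases)
  panel$d_ihs_cases_incr <- sp$increase
  panel$d_ihs_cases_decr <- sp$decrease

  dum <- do.call(rbind, lapply(split(panel$stringency, panel$country),
                               stringency_change_dummies))
  panel$decr_next <- dum$decr_next
  panel$incr_next <- dum$incr_next

  cal <- calendar_dummies(panel$thursday, panel$country,
                          hemisphere_map = hemisphere_map)
  panel$month <- cal$month
  panel$spring <- cal$spring
  panel$summer <- cal$summer
  panel$fall <- cal$fall

  nm_first <- c("country", "week", "thursday", "gnh", "lag_gnh")
  tibble::as_tibble(panel[, c(nm_first, setdiff(names(panel), nm_first))])
}

#' Write or read a panel table as CSV
#'
#' @param panel Tibble from [assemble_panel()].
#' @param path File path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(country = "character"))
  if ("thursday" %in% names(df)) df$thursday <- as.Date(df$thursday)
  tibble::as_tibble(df)
}
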