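#' Default country -> IANA timezone map for the ten study countries
#'
#' Tweets are timestamped in UTC but bucketed into hours and days of the
#' country's local civil time, so "the mean GNH per day" refers to a local
#' calendar day. Multi-zone countries use the zone of the most populous city.
#'
#' @return Named character vector, ISO-3166 alpha-2 code -> IANA zone.
#' @export
default_tz_map <- function() {
  c(AU = "Australia/Sydney", BE = "Europe/Brussels", FR = "Europe/Paris",
    GB = "Europe/London", DE = "Europe/Berlin", IT = "Europe/Rome",
    LU = "Europe/Luxembourg", NZ = "Pacific/Auckland",
    ZA = "Africa/Johannesburg", ES = "Europe/Madrid")
}

#' Default country -> hemisphere map for the ten study countries
#'
#' Used by [calendar_dummies()] to shift meteorological seasons by six
#' months in the Southern hemisphere.
#'
#' @return Named character vector with values `"N"` or `"S"`.
#' @export
default_hemisphere_map <- function() {
  c(AU = "S", BE = "N", FR = "N", GB = "N", DE = "N", IT = "N",
    LU = "N", NZ = "S", ZA = "S", ES = "N")
}

#' Read tweet records from a JSON-lines file
#'
#' Each line holds one JSON object with fields `id`, `timestamp` (ISO-8601,
#' UTC), `country` (ISO-3166 alpha-2), and `text`. Malformed lines and lines
#' missing a required field are skipped and counted, not fatal; an unreadable
#' file is fatal.
#'
#' @param path Path to the JSONL file.
#' @param countries Optional character vector restricting records to the
#'   configured study countries; records for other countries are skipped and
#'   counted. `NULL` (default) keeps all.
#' @return A tibble with columns `id`, `timestamp` (POSIXct, UTC),
#'   `country`, `text`, carrying the number of skipped lines in
#'   `attr(, "n_skipped")`.
#' @export
read_tweets <- function(path, countries = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  req <- c("id", "timestamp", "country", "text")
  parse1 <- function(ln) {
    obj <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) return(NULL)
    if (!all(req %in% names(obj))) return(NULL)
    vals <- obj[req]
    if (any(vapply(vals, function(v) length(v) != 1L || is.na(v), TRUE))) {
      return(NULL)
    }
    ts <- parse_utc(as.character(obj$timestamp))
    if (is.na(ts)) return(NULL)
    tibble::tibble(id = as.character(obj$id), timestamp = ts,
                   country = toupper(as.character(obj$country)),
                   text = as.character(obj$text))
  }
  parsed <- lapply(lines, parse1)
  ok <- !vapply(parsed, is.null, TRUE)
  n_skipped <- sum(!ok)
  out <- if (any(ok)) {
    dplyr::bind_rows(parsed[ok])
  } else {
    tibble::tibble(id = character(0),
                   timestamp = as.POSIXct(character(0), tz = "UTC"),
                   country = character(0), text = character(0))
  }
  if (!is.null(countries)) {
    drop <- !(out$country %in% toupper(countries))
    n_skipped <- n_skipped + sum(drop)
    out <- out[!drop, , drop = FALSE]
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Clean raw tweet text
#'
#' Total, vectorized, and idempotent normalisation of tweet text down to the
#' ASCII-letter alphabet the lexicons use. Rules, applied in this fixed
#' order:
#'
#' 1. non-ASCII codepoints (covers emojis) and control characters are
#'    removed, then digits;
#' 2. tokens beginning `http`/`https` (URLs and the bare letters) are
#'    removed whole;
#' 3. `@`-mentions are removed whole; remaining bare `@` and `#` symbols are
#'    removed so a hashtag keeps its word (`#dogs` -> `dogs`);
#' 4. punctuation is replaced by spaces, except apostrophes between letters
#'    (`don't` survives);
#' 5. lowercased; runs of whitespace collapsed; trimmed.
#'
#' Digits and non-ASCII bytes are stripped before the URL rule so that a
#' token like `1https…` cannot resurface as a fresh `https` token, which
#' keeps the function idempotent.
#'
#' @param x Character vector of raw tweet texts.
#' @return Character vector of cleaned texts containing only ASCII letters,
#'   spaces and intra-word apostrophes.
#' @export
#' @examples
#' clean_text("@john I love #dogs 123 \U0001F600 https t.co x")
clean_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  # 1. keep printable ASCII only (drops emojis + control chars), then digits
  x <- iconv(x, from = "UTF-8", to = "ASCII", sub = "")
  x[is.na(x)] <- ""
  x <- gsub("[^\\x20-\\x7E]", " ", x, perl = TRUE)
  x <- gsub("[0-9]", "", x)
  # 2. URL-ish tokens: anything starting http/https up to whitespace
  x <- gsub("\\bhttps?[^ ]*", " ", x, ignore.case = TRUE, perl = TRUE)
  # 3. @mentions whole, then bare @ / # symbols (hashtag word survives)
  x <- gsub("@[A-Za-z_']+", " ", x, perl = TRUE)
  x <- gsub("[@#]", "", x, fixed = FALSE)
  # 4. punctuation -> space, protecting intra-word apostrophes
  x <- gsub("[^A-Za-z' ]", " ", x, perl = TRUE)
  x <- gsub("(?<![A-Za-z])'|'(?![A-Za-z])", " ", x, perl = TRUE)
  # 5. case + whitespace
  x <- tolower(x)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

#' Tokenize cleaned text
#'
#' Splits on whitespace and drops empty tokens. Input is assumed to be
#' output of [clean_text()].
#'
#' @param cleaned Character vector of cleaned texts.
#' @return A list of character vectors, one per input element.
#' @export
tokenize <- function(cleaned) {
  lapply(strsplit(as.character(cleaned), " ", fixed = TRUE),
         function(t) t[nzchar(t)])
}

#' Attach cleaned tokens and local time to tweet records
#'
#' Convenience step combining [clean_text()], [tokenize()] and the
#' UTC -> local-time conversion used for hourly/daily bucketing.
#'
#' @param tweets Tibble from [read_tweets()].
#' @param tz_map Named character vector country -> IANA timezone;
#'   defaults to [default_tz_map()]. Countries absent from the map are an
#'   error.
#' @return The input tibble with list-column `tokens` and columns
#'   `local_date` (Date) and `local_hour` (integer 0-23).
#' @export
prepare_tweets <- function(tweets, tz_map = default_tz_map()) {
  missing_tz <- setdiff(unique(tweets$country), names(tz_map))
  if (length(missing_tz) > 0L) {
    stop("no timezone configured for country: ",
         paste(missing_tz, collapse = ", "), call. = FALSE)
  }
  tweets$tokens <- tokenize(clean_text(tweets$text))
  n <- nrow(tweets)
  tweets$local_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  tweets$local_hour <- rep(NA_integer_, n)
  for (cc in unique(tweets$country)) {
    i <- which(tweets$country == cc)
    lt <- format(tweets$timestamp[i], tz = tz_map[[cc]],
                 format = "%Y-%m-%d %H")
    tweets$local_date[i] <- as.Date(substr(lt, 1, 10))
    tweets$local_hour[i] <- as.integer(substr(lt, 12, 13))
  }
  tweets
}

# ---- internal ---------------------------------------------------------------

parse_utc <- function(x) {
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y-%m-%d"),
             optional = TRUE)
}
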