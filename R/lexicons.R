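#' The fixed emotion order used throughout the package
#'
#' Eight basic emotions of the Plutchik wheel, in the canonical order every
#' emotion vector, lexicon column, and daily series in this package follows.
#'
#' @return Character vector of length 8:
#'   `anger, fear, anticipation, trust, surprise, sadness, joy, disgust`.
#' @export
#' @examples
#' emotion_names()
emotion_names <- function() {
  c("anger", "fear", "anticipation", "trust", "surprise", "sadness",
    "joy", "disgust")
}

#' Read a sentiment lexicon from TSV
#'
#' A sentiment lexicon maps lowercase ASCII tokens to a polarity of `+1`
#' (positive) or `-1` (negative). The file is UTF-8, tab-separated, two
#' columns `token<TAB>polarity`, with optional `#` comment lines and blank
#' lines. Duplicate rows repeating the same polarity are collapsed; duplicate
#' tokens with conflicting polarity are rejected.
#'
#' @param path Path to the TSV file.
#' @return A `sentiment_lexicon`: named numeric vector of polarities.
#' @export
read_sentiment_lexicon <- function(path) {
  rows <- read_lexicon_rows(path, n_fields = 2L)
  if (nrow(rows) == 0L) {
    return(new_sentiment_lexicon(stats::setNames(numeric(0), character(0))))
  }
  token <- rows[[1L]]
  polarity <- suppressWarnings(as.numeric(rows[[2L]]))
  bad <- which(is.na(polarity) | !(polarity %in% c(-1, 1)))
  if (length(bad) > 0L) {
    stop("malformed polarity (must be -1 or +1) at line ", rows$line[bad[1L]],
         " of ", path, call. = FALSE)
  }
  validate_tokens(token, rows$line, path)
  # collapse exact duplicates, reject conflicts
  agg <- tapply(polarity, token, function(p) length(unique(p)))
  conflict <- names(agg)[agg > 1L]
  if (length(conflict) > 0L) {
    stop("conflicting polarity for token(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }
  keep <- !duplicated(token)
  new_sentiment_lexicon(stats::setNames(polarity[keep], token[keep]))
}

#' Read an emotion lexicon from TSV
#'
#' An emotion lexicon maps lowercase ASCII tokens to an 8-vector of
#' intensities on the emotions of [emotion_names()], each on the 0-10 scale.
#' The file is UTF-8, tab-separated, three columns
#' `token<TAB>emotion<TAB>intensity`; rows for the same token are merged into
#' one vector and unlisted emotions default to 0. Lexicons scored on another
#' scale can be rescaled at load time via `scale_max` (intensities are
#' multiplied by `10 / scale_max`).
#'
#' @param path Path to the TSV file.
#' @param scale_max Maximum of the intensity scale used in the file
#'   (default 10, i.e. no rescaling).
#' @return An `emotion_lexicon`: numeric matrix, one row per token
#'   (rownames), 8 emotion columns.
#' @export
read_emotion_lexicon <- function(path, scale_max = 10) {
  stopifnot(is.numeric(scale_max), length(scale_max) == 1L, scale_max > 0)
  rows <- read_lexicon_rows(path, n_fields = 3L)
  emo <- emotion_names()
  if (nrow(rows) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = 8L, dimnames = list(NULL, emo))
    return(new_emotion_lexicon(m))
  }
  token <- rows[[1L]]
  emotion <- rows[[2L]]
  intensity <- suppressWarnings(as.numeric(rows[[3L]]))
  bad <- which(is.na(intensity))
  if (length(bad) > 0L) {
    stop("malformed intensity at line ", rows$line[bad[1L]], " of ", path,
         call. = FALSE)
  }
  unknown <- which(!(emotion %in% emo))
  if (length(unknown) > 0L) {
    stop("unknown emotion name '", emotion[unknown[1L]], "' at line ",
         rows$line[unknown[1L]], " of ", path, call. = FALSE)
  }
  intensity <- intensity * (10 / scale_max)
  out_of_range <- which(intensity < 0 | intensity > 10)
  if (length(out_of_range) > 0L) {
    stop("intensity outside [0, 10] (after any rescaling) at line ",
         rows$line[out_of_range[1L]], " of ", path, call. = FALSE)
  }
  validate_tokens(token, rows$line, path)
  toks <- sort(unique(token))
  m <- matrix(0, nrow = length(toks), ncol = 8L,
              dimnames = list(toks, emo))
  # later rows for the same (token, emotion) overwrite earlier ones
  m[cbind(match(token, toks), match(emotion, emo))] <- intensity
  new_emotion_lexicon(m)
}

#' Write lexicons back to TSV
#'
#' Inverse of the readers; a written lexicon reloads to identical entries.
#'
#' @param lexicon A `sentiment_lexicon` or `emotion_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  if (inherits(lexicon, "sentiment_lexicon")) {
    lines <- paste(names(lexicon), format_num(unclass(lexicon)), sep = "\t")
  } else if (inherits(lexicon, "emotion_lexicon")) {
    m <- unclass(lexicon)
    idx <- which(m != 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    lines <- paste(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]],
                   format_num(m[idx]), sep = "\t")
  } else {
    stop("not a lexicon object", call. = FALSE)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Query token polarity
#'
#' Absent tokens return the neutral element 0 and never error.
#'
#' @param lexicon A `sentiment_lexicon`.
#' @param tokens Character vector of tokens.
#' @return Numeric vector of polarities in `{-1, 0, +1}`.
#' @export
token_polarity <- function(lexicon, tokens) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  p <- unclass(lexicon)[tokens]
  p[is.na(p)] <- 0
  unname(p)
}

#' Query token emotion intensities
#'
#' Absent tokens return the all-zero vector and never error.
#'
#' @param lexicon An `emotion_lexicon`.
#' @param tokens Character vector of tokens.
#' @return Numeric matrix, one row per token, 8 emotion columns.
#' @export
token_emotions <- function(lexicon, tokens) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  m <- unclass(lexicon)
  i <- match(tokens, rownames(m))
  out <- matrix(0, nrow = length(tokens), ncol = 8L,
                dimnames = list(NULL, emotion_names()))
  hit <- !is.na(i)
  if (any(hit)) out[hit, ] <- m[i[hit], , drop = FALSE]
  out
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  p <- unclass(x)
  cat("<sentiment_lexicon> ", length(p), " tokens (",
      sum(p > 0), " positive, ", sum(p < 0), " negative)\n", sep = "")
  invisible(x)
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  m <- unclass(x)
  cat("<emotion_lexicon> ", nrow(m), " tokens x 8 emotions (scale 0-10)\n",
      sep = "")
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

new_sentiment_lexicon <- function(entries) {
  structure(entries, class = "sentiment_lexicon")
}

new_emotion_lexicon <- function(m) {
  structure(m, class = "emotion_lexicon")
}

# Parse a lexicon TSV into a data.frame of fields plus original line numbers.
read_lexicon_rows <- function(path, n_fields) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  line_no <- seq_along(raw)
  keep <- !grepl("^\\s*(#|$)", raw)
  raw <- raw[keep]
  line_no <- line_no[keep]
  if (length(raw) == 0L) {
    out <- as.data.frame(matrix(character(0), ncol = n_fields))
    out$line <- integer(0)
    return(out)
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(n != n_fields)
  if (length(bad) > 0L) {
    stop("malformed row (expected ", n_fields, " tab-separated fields) at line ",
         line_no[bad[1L]], " of ", path, call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  out[] <- lapply(out, trimws)
  out$line <- line_no
  out
}

validate_tokens <- function(token, line_no, path) {
  bad <- which(token == "" | grepl("[^a-z']", token))
  if (length(bad) > 0L) {
    stop("invalid token '", token[bad[1L]], "' at line ", line_no[bad[1L]],
         " of ", path, " (tokens must be non-empty lowercase ASCII)",
         call. = FALSE)
  }
  invisible(TRUE)
}

format_num <- function(x) {
  formatC(x, format = "g", digits = 15)
}
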