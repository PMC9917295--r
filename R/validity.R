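#' Rank countries by an indicator's period mean
#'
#' Descending-value ranking (1 = highest) with average ranks on ties, the
#' cross-sectional side of the convergent-validity exercise.
#'
#' @param series_means Named numeric vector, country -> period mean.
#' @return Named numeric vector of ranks (a permutation of 1..n up to
#'   average-rank ties).
#' @export
rank_countries <- function(series_means) {
  if (length(series_means) < 3L) {
    stop("need at least 3 countries to rank", call. = FALSE)
  }
  if (is.null(names(series_means)) || any(!nzchar(names(series_means)))) {
    stop("series_means must be named by country", call. = FALSE)
  }
  rank(-series_means, ties.method = "average")
}

#' Rank agreement between two country rankings
#'
#' Spearman's rho over the shared countries, with an exact permutation
#' p-value (enumeration of all n! rank permutations) for n <= 8 and the
#' t-approximation above that.
#'
#' @param r1,r2 Named rank vectors (e.g. from [rank_countries()]).
#' @return List with `rho`, `p_value`, `n`, and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
rank_agreement <- function(r1, r2) {
  shared <- intersect(names(r1), names(r2))
  if (length(shared) == 0L) stop("disjoint country sets", call. = FALSE)
  if (length(shared) < 3L) stop("need at least 3 shared countries", call. = FALSE)
  x <- rank(r1[shared]); y <- rank(r2[shared])
  n <- length(shared)
  rho <- stats::cor(x, y)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rho_null <- apply(perms, 1L, function(p) stats::cor(x, y[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(1, p)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Time-series correlation between two weekly series
#'
#' Pearson correlation over the overlapping periods of two aligned series,
#' optionally first-differencing both beforehand (the default exercise
#' correlates *changes*). Pairwise-complete observations are used.
#'
#' @param x,y Numeric vectors aligned on the same periods.
#' @param difference First-difference both series before correlating.
#' @return List with `r`, `p_value`, `n` (pairs used).
#' @export
series_correlation <- function(x, y, difference = TRUE) {
  if (length(x) != length(y)) stop("series must be aligned", call. = FALSE)
  if (difference) {
    x <- diff(x)
    y <- diff(y)
  }
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 8L) stop("need at least 8 overlapping periods", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

# All permutations of 1..n as an (n!) x n matrix; recursive, fine for n <= 8.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}
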