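#' Run the full pipeline from a configuration
#'
#' Orchestrates ingest -> daily indices -> weekly panel -> (optionally) the
#' model ladder, writing tidy CSV outputs and a JSON run manifest that is
#' sufficient to re-run the pipeline identically (config snapshot, input
#' file digests, seed, stage timings and row counts, package version).
#' Re-running with identical inputs and seed produces identical numeric
#' outputs.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' fields:
#' \preformatted{
#' tweets: path/to/tweets.jsonl
#' sentiment_lexicon: path/to/sentiment.tsv
#' emotion_lexicon: path/to/emotion.tsv
#' covariates: path/to/covariates.csv
#' output_dir: path/to/outputs
#' seed: 42              # optional, default 1
#' run_ladder: true      # optional, default false
#' bootstrap_B: 199      # optional, default 199
#' min_week_days: 4      # optional weekly completeness rule
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @return List with `outputs` (paths of written files), `ladder` (when
#'   run), and `manifest` (the manifest list, also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  required <- c("tweets", "sentiment_lexicon", "emotion_lexicon",
                "covariates", "output_dir")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0L) {
    stop("config is missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (f in c("tweets", "sentiment_lexicon", "emotion_lexicon",
              "covariates")) {
    if (!file.exists(config[[f]])) {
      stop("config field '", f, "': file not found: ", config[[f]],
           call. = FALSE)
    }
  }
  seed <- as.integer(config$seed %||% 1L)
  run_ladder <- isTRUE(config$run_ladder)
  B <- as.integer(config$bootstrap_B %||% 199L)
  min_days <- as.integer(config$min_week_days %||% 4L)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- list()
  counts <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  sent <- stage("lexicons", read_sentiment_lexicon(config$sentiment_lexicon))
  emol <- read_emotion_lexicon(config$emotion_lexicon)
  tweets <- stage("ingest", read_tweets(config$tweets))
  counts$tweets <- nrow(tweets)
  counts$tweets_skipped <- attr(tweets, "n_skipped")

  daily <- stage("daily_series",
                 build_daily_series(tweets, sent, emol))
  counts$country_days <- nrow(daily)
  daily_path <- file.path(config$output_dir, "daily_series.csv")
  write_daily_series(daily, daily_path)

  cov <- read_covariates(config$covariates)
  panel <- stage("panel", assemble_panel(daily, cov, min_days = min_days))
  counts$country_weeks <- nrow(panel)
  counts$countries <- length(unique(panel$country))
  panel_path <- file.path(config$output_dir, "panel.csv")
  write_panel(panel, panel_path)

  outputs <- c(daily_series = daily_path, panel = panel_path)
  ladder <- NULL
  if (run_ladder) {
    ladder <- stage("models",
                    run_model_ladder(panel,
                                     spec_args = list(B = B, seed = seed)))
    ladder_path <- file.path(config$output_dir, "model_ladder.csv")
    utils::write.csv(ladder$summary, ladder_path, row.names = FALSE)
    outputs["model_ladder"] <- ladder_path
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gnhpanel")),
    config = config,
    input_digests = as.list(tools::md5sum(c(
      tweets = config$tweets,
      sentiment_lexicon = config$sentiment_lexicon,
      emotion_lexicon = config$emotion_lexicon,
      covariates = config$covariates))),
    seed = seed,
    stage_seconds = timings,
    counts = counts
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  outputs["manifest"] <- manifest_path
  list(outputs = outputs, ladder = ladder, manifest = manifest)
}

#' Replicate the model ladder from a deposited panel dataset
#'
#' Bypasses the tweet stages: reads a Stata DTA file holding an already
#' assembled country-week panel, maps its columns onto the panel layout via
#' a user-editable column map, and runs the model ladder on it. When a
#' reference table of published coefficients is supplied, the result
#' includes a side-by-side comparison.
#'
#' @param dta_path Path to the `.dta` file.
#' @param column_map Named character vector: names are the panel column
#'   names used by this package (`gnh`, `lag_gnh`, `d_ihs_cases`,
#'   `residential_mobility`, `decr_next`, `incr_next`, `country`, `month`,
#'   `spring`, `summer`, `fall`, the emotions, the context variables),
#'   values the corresponding DTA column names. Identity entries may be
#'   omitted for columns already named that way.
#' @param spec_args Extra [regression_spec()] arguments (e.g. `B`, `seed`).
#' @param retained_emotions Passed to [run_model_ladder()]; defaults to
#'   step-wise selection when the emotion columns are present.
#' @param reference Optional data frame with columns `model`, `term`,
#'   `estimate` of published coefficients to place beside the recomputed
#'   ones.
#' @param bootstrap Attach bootstrap p-values to the ladder fits.
#' @return List with `panel`, `ladder`, and (when `reference` is given)
#'   `comparison`.
#' @export
replicate_from_dta <- function(dta_path, column_map = character(0),
                               spec_args = list(), retained_emotions = NULL,
                               reference = NULL, bootstrap = FALSE) {
  if (!file.exists(dta_path)) stop("file not found: ", dta_path, call. = FALSE)
  raw <- foreign::read.dta(dta_path)
  for (target in names(column_map)) {
    src <- column_map[[target]]
    if (!src %in% names(raw)) {
      stop("column map entry '", target, "' -> '", src,
           "' not found in DTA; available columns: ",
           paste(names(raw), collapse = ", "), call. = FALSE)
    }
    names(raw)[names(raw) == src] <- target
  }
  required <- c("country", "gnh", "lag_gnh", "d_ihs_cases",
                "residential_mobility", "decr_next", "incr_next", "month",
                "spring", "summer", "fall")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0L) {
    stop("unmapped required column(s): ", paste(miss, collapse = ", "),
         "; candidates in the file: ", paste(names(raw), collapse = ", "),
         call. = FALSE)
  }
  panel <- tibble::as_tibble(raw)
  have_emotions <- all(emotion_names() %in% names(panel))
  if (!have_emotions && is.null(retained_emotions)) {
    retained_emotions <- character(0)
  }
  ladder <- run_model_ladder(panel, retained_emotions = retained_emotions,
                             spec_args = spec_args, bootstrap = bootstrap)
  out <- list(panel = panel, ladder = ladder)
  if (!is.null(reference)) {
    recomputed <- dplyr::bind_rows(lapply(names(ladder$fits), function(m) {
      td <- tidy_fit(ladder$fits[[m]])
      td$model <- m
      td
    }))
    out$comparison <- dplyr::left_join(
      tibble::as_tibble(reference), recomputed[, c("model", "term",
                                                   "estimate", "cluster_se")],
      by = c("model", "term"), suffix = c("_published", "_recomputed"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
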