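#' Webb six-point bootstrap weights
#'
#' The weight family designed for wild cluster bootstraps with few (< ~10)
#' clusters: the six points \eqn{\pm\sqrt{3/2}, \pm 1, \pm\sqrt{1/2}}, each
#' with probability 1/6. The family has mean 0 and variance 1 exactly.
#'
#' @param n Number of draws.
#' @return Numeric vector of `n` weights.
#' @export
webb_weights <- function(n) {
  sample(c(-sqrt(1.5), -1, -sqrt(0.5), sqrt(0.5), 1, sqrt(1.5)), n,
         replace = TRUE)
}

rademacher_weights <- function(n) {
  sample(c(-1, 1), n, replace = TRUE)
}

#' Specify a panel regression
#'
#' Describes one model of the dependent variable on an ordered set of
#' regressor columns with country-clustered errors, month/season calendar
#' controls, and bootstrap settings.
#'
#' @param dependent Name of the dependent column (default `"gnh"`).
#' @param regressors Character vector of regressor column names (the
#'   dependent must not be among them).
#' @param cluster Name of the clustering column (default `"country"`).
#' @param include_months,include_seasons Add month factor dummies /
#'   spring-summer-fall dummies.
#' @param B Bootstrap replications (>= 99).
#' @param weight_family `"webb"` or `"rademacher"`.
#' @param null_imposed Use the restricted (null-imposed) bootstrap-t
#'   (default) or the unrestricted variant.
#' @param seed Integer seed for the bootstrap draws.
#' @return A `regression_spec` list.
#' @export
regression_spec <- function(dependent = "gnh", regressors,
                            cluster = "country",
                            include_months = TRUE, include_seasons = TRUE,
                            B = 999L, weight_family = c("webb", "rademacher"),
                            null_imposed = TRUE, seed = 1L) {
  weight_family <- match.arg(weight_family)
  if (dependent %in% regressors) {
    stop("dependent variable cannot be a regressor", call. = FALSE)
  }
  if (B < 99L) warning("B < 99 bootstrap replications is unreliable")
  structure(list(dependent = dependent, regressors = regressors,
                 cluster = cluster, include_months = include_months,
                 include_seasons = include_seasons, B = as.integer(B),
                 weight_family = weight_family, null_imposed = null_imposed,
                 seed = as.integer(seed)),
            class = "regression_spec")
}

# Build y, X, cluster from a panel + spec, complete cases only.
build_design <- function(panel, spec) {
  cols <- c(spec$dependent, spec$regressors, spec$cluster)
  if (spec$include_months) cols <- c(cols, "month")
  if (spec$include_seasons) cols <- c(cols, "spring", "summer", "fall")
  miss <- setdiff(cols, names(panel))
  if (length(miss) > 0L) {
    stop("panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- panel[stats::complete.cases(panel[, cols, drop = FALSE]), cols,
               drop = FALSE]
  if (nrow(dat) == 0L) stop("no complete cases for this model", call. = FALSE)
  X <- matrix(1, nrow = nrow(dat), ncol = 1L,
              dimnames = list(NULL, "(Intercept)"))
  if (length(spec$regressors) > 0L) {
    X <- cbind(X, as.matrix(dat[, spec$regressors, drop = FALSE]))
  }
  # seasons before months: any month/season linear dependency then lands on
  # a month dummy, which fit_ols absorbs rather than errors on
  if (spec$include_seasons) {
    X <- cbind(X, as.matrix(dat[, c("spring", "summer", "fall")]))
  }
  if (spec$include_months) {
    mo <- factor(dat$month, levels = sort(unique(dat$month)))
    if (nlevels(mo) > 1L) {
      md <- stats::model.matrix(~ mo)[, -1L, drop = FALSE]
      colnames(md) <- paste0("month_", levels(mo)[-1L])
      X <- cbind(X, md)
    }
  }
  list(y = dat[[spec$dependent]], X = X,
       cluster = as.character(dat[[spec$cluster]]))
}

#' Fit a panel model by OLS
#'
#' Ordinary least squares on the complete-case rows for the model, with
#' cluster-robust (CRVE) standard errors using the small-sample factor
#' \eqn{G/(G-1) \times (n-1)/(n-k)}. A rank-deficient design is an error
#' naming the aliased columns rather than silently dropping them.
#'
#' @param panel Panel tibble from [assemble_panel()] (or any data frame with
#'   the spec's columns).
#' @param spec A [regression_spec()].
#' @return A `gnh_fit` object: list with `coefficients`, `se_cluster`,
#'   `t_cluster`, `adj_r_squared`, `r_squared`, `n_obs`, `n_clusters`,
#'   `residuals`, `fitted`, plus internals used by the bootstrap.
#' @export
fit_ols <- function(panel, spec) {
  d <- build_design(panel, spec)
  y <- d$y; X <- d$X; g <- d$cluster
  n <- nrow(X); k <- ncol(X)
  qr_x <- qr(X)
  dropped <- character(0)
  if (qr_x$rank < k) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
    # month dummies are redundant by construction when pooled with
    # hemisphere-aware seasons (spring + fall spans six month indicators);
    # aliased month dummies are absorbed, anything else is misconfiguration
    if (all(grepl("^month_", aliased))) {
      dropped <- aliased
      X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
      k <- ncol(X)
      qr_x <- qr(X)
    }
    if (qr_x$rank < k) {
      aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)
  vc <- crve(X, resid, g, qr_x = qr_x)
  se <- stats::setNames(sqrt(diag(vc)), colnames(X))
  structure(list(coefficients = beta, se_cluster = se,
                 t_cluster = beta / se, r_squared = r2,
                 adj_r_squared = adj_r2, n_obs = n, k = k,
                 n_clusters = length(unique(g)), residuals = resid,
                 fitted = fitted, y = y, X = X, cluster = g, spec = spec,
                 dropped_aliased = dropped),
            class = "gnh_fit")
}

#' @export
print.gnh_fit <- function(x, ...) {
  cat("<gnh_fit> OLS, n =", x$n_obs, "| clusters =", x$n_clusters,
      "| adj R2 =", round(x$adj_r_squared, 3), "\n")
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    cluster_se = round(x$se_cluster, 4))
  if (!is.null(x$p_boot)) tab$boot_p <- round(x$p_boot[rownames(tab)], 4)
  print(tab)
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param fit A `gnh_fit`.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `cluster_se`, `t_value`, and `boot_p` when bootstrap p-values have been
#'   attached.
#' @export
tidy_fit <- function(fit) {
  out <- tibble::tibble(term = names(fit$coefficients),
                        estimate = unname(fit$coefficients),
                        cluster_se = unname(fit$se_cluster),
                        t_value = unname(fit$t_cluster))
  if (!is.null(fit$p_boot)) out$boot_p <- unname(fit$p_boot[out$term])
  out
}

# Cluster-robust variance with small-sample correction.
crve <- function(X, resid, cluster, qr_x = qr(X)) {
  n <- nrow(X); k <- ncol(X); G <- length(unique(cluster))
  Xu <- rowsum(X * resid, cluster)          # G x k score sums
  meat <- crossprod(Xu)
  bread <- chol2inv(qr.R(qr_x))             # (X'X)^-1
  cf <- G / (G - 1) * (n - 1) / (n - k)
  cf * bread %*% meat %*% bread
}

#' Wild cluster bootstrap p-value for one coefficient
#'
#' Restricted (null-imposed) wild cluster bootstrap-t: the model is refit
#' under `H0: beta_j = 0`, cluster-level wild weights (Webb six-point by
#' default) perturb the restricted residuals, the full model is refit on
#' each bootstrap sample, and the bootstrap t-statistics (using CRVE with
#' the same small-sample factor as the original) are compared with the
#' observed one. The p-value uses the `(1 + m) / (B + 1)` convention, so it
#' is never exactly zero. Set `null_imposed = FALSE` in the spec for the
#' unrestricted variant, which recenters bootstrap estimates at the original
#' ones.
#'
#' @param fit A `gnh_fit` from [fit_ols()].
#' @param coefficient Name of the coefficient to test.
#' @param B,weight_family,seed Override the corresponding spec fields.
#' @return Scalar p-value in `(0, 1]`.
#' @export
wild_cluster_bootstrap_p <- function(fit, coefficient, B = NULL,
                                     weight_family = NULL, seed = NULL) {
  spec <- fit$spec
  if (!is.null(B)) spec$B <- as.integer(B)
  if (!is.null(weight_family)) spec$weight_family <- weight_family
  if (!is.null(seed)) set.seed(seed)
  wcb_p_engine(fit, coefficient, spec)
}

#' Attach bootstrap p-values for all coefficients
#'
#' Runs [wild_cluster_bootstrap_p()] for every coefficient (one independent
#' weight stream each, drawn from the spec's seed so results are
#' reproducible bit-for-bit) and stores them in the fit.
#'
#' @param fit A `gnh_fit`.
#' @param terms Coefficients to test (default: all).
#' @param B,seed Optional overrides of the spec.
#' @return The fit with element `p_boot` (named numeric vector) filled in.
#' @export
add_bootstrap_p <- function(fit, terms = NULL, B = NULL, seed = NULL) {
  spec <- fit$spec
  if (!is.null(B)) spec$B <- as.integer(B)
  if (is.null(terms)) terms <- names(fit$coefficients)
  set.seed(if (is.null(seed)) spec$seed else seed)
  p <- vapply(terms, function(tm) wcb_p_engine(fit, tm, spec), numeric(1))
  fit$p_boot <- p
  fit
}

# Core bootstrap engine; uses the current RNG state (caller seeds).
wcb_p_engine <- function(fit, coefficient, spec) {
  X <- fit$X; y <- fit$y; g <- fit$cluster
  n <- nrow(X); k <- ncol(X)
  G <- fit$n_clusters
  if (G < 2L) stop("need at least 2 clusters", call. = FALSE)
  j <- match(coefficient, colnames(X))
  if (is.na(j)) stop("unknown coefficient: ", coefficient, call. = FALSE)
  B <- spec$B
  draw <- switch(spec$weight_family, webb = webb_weights,
                 rademacher = rademacher_weights)

  t_obs <- fit$t_cluster[j]

  if (spec$null_imposed) {
    Xr <- X[, -j, drop = FALSE]
    qr_r <- qr(Xr)
    beta_r <- qr.coef(qr_r, y)
    base_fit <- drop(Xr %*% beta_r)
    base_res <- y - base_fit
  } else {
    base_fit <- fit$fitted
    base_res <- fit$residuals
  }

  qr_x <- qr(X)
  XtX_inv <- chol2inv(qr.R(qr_x))
  A <- XtX_inv %*% t(X)                       # k x n projector to beta
  a <- X %*% XtX_inv[, j]                     # n, for var of beta_j
  cf <- G / (G - 1) * (n - 1) / (n - k)

  gid <- match(g, unique(g))
  W <- matrix(draw(G * B), nrow = G)          # cluster weights, G x B
  Ystar <- base_fit + base_res * W[gid, , drop = FALSE]
  Bhat <- A %*% Ystar                         # k x B
  U <- Ystar - X %*% Bhat
  S <- rowsum(as.vector(a) * U, gid)          # G x B cluster scores
  var_j <- cf * colSums(S^2)
  center <- if (spec$null_imposed) 0 else fit$coefficients[j]
  t_star <- (Bhat[j, ] - center) / sqrt(var_j)
  (1 + sum(abs(t_star) >= abs(t_obs))) / (B + 1)
}

#' Backward step-wise emotion selection
#'
#' Starting from the model containing all eight emotions, repeatedly drops
#' the emotion with the largest wild-cluster-bootstrap p-value at or above
#' the threshold and refits, stopping when every remaining emotion has
#' `p < threshold`. With `single_pass = TRUE` all emotions at or above the
#' threshold in the initial fit are dropped at once instead.
#'
#' @param panel Panel tibble.
#' @param base_regressors Regressors kept in every model (e.g. lag GNH,
#'   cases, mobility, stringency dummies).
#' @param emotions Candidate emotion columns (default all 8).
#' @param threshold Retention threshold on the bootstrap p-value
#'   (default 0.4).
#' @param spec_args Named list of extra arguments to [regression_spec()]
#'   (e.g. `B`, `seed`, `include_months`).
#' @param single_pass Drop simultaneously instead of one-at-a-time.
#' @return List with `retained` (character), `dropped` (ordered character),
#'   `drop_log` (tibble of step, emotion, p), and `fit` (final model with
#'   bootstrap p-values).
#' @export
stepwise_emotion_selection <- function(panel, base_regressors,
                                       emotions = emotion_names(),
                                       threshold = 0.4,
                                       spec_args = list(),
                                       single_pass = FALSE) {
  current <- emotions
  dropped <- character(0)
  log_step <- integer(0); log_emotion <- character(0); log_p <- numeric(0)
  step <- 0L
  repeat {
    step <- step + 1L
    spec <- do.call(regression_spec,
                    c(list(regressors = c(base_regressors, current)),
                      spec_args))
    fit <- fit_ols(panel, spec)
    fit <- add_bootstrap_p(fit, terms = current)
    p <- fit$p_boot[current]
    if (length(current) == 0L || all(p < threshold)) {
      return(list(retained = current, dropped = dropped,
                  drop_log = tibble::tibble(step = log_step,
                                            emotion = log_emotion,
                                            p = log_p),
                  fit = fit))
    }
    if (single_pass) {
      out <- current[p >= threshold]
      log_step <- c(log_step, rep(step, length(out)))
      log_emotion <- c(log_emotion, out)
      log_p <- c(log_p, unname(p[out]))
      dropped <- c(dropped, out)
      current <- setdiff(current, out)
      single_pass <- FALSE  # refit once after the mass drop to report
      if (length(current) == 0L) next
    } else {
      worst <- current[which.max(p)]
      log_step <- c(log_step, step)
      log_emotion <- c(log_emotion, worst)
      log_p <- c(log_p, unname(p[worst]))
      dropped <- c(dropped, worst)
      current <- setdiff(current, worst)
    }
  }
}

#' Run the step-wise model ladder
#'
#' Reproduces the printed model sequence: (1) baseline lag + calendar
#' controls; (2) + change in IHS cases; (3) + residential mobility; (4) +
#' next-week stringency dummies; (5) combined; (6) combined + all eight
#' emotions; (7) combined + retained emotions + economic fear; (8) ... +
#' institutional trust; (9) ... + loneliness; each fit on its own
#' complete-case rows, so N is model-specific.
#'
#' @param panel Panel tibble.
#' @param retained_emotions Emotions entering models 7-9; default the result
#'   of [stepwise_emotion_selection()] run on the combined model, or supply
#'   a character vector to skip the selection.
#' @param spec_args Extra [regression_spec()] arguments (e.g. `B`, `seed`).
#' @param bootstrap Attach bootstrap p-values to every model (slower).
#' @return List with `fits` (named list of `gnh_fit`), `summary` (tibble of
#'   model, N, clusters, adjusted R2) and `retained_emotions`.
#' @export
run_model_ladder <- function(panel, retained_emotions = NULL,
                             spec_args = list(), bootstrap = FALSE) {
  base <- c("lag_gnh")
  covs <- c("d_ihs_cases", "residential_mobility", "decr_next", "incr_next")
  combined <- c(base, covs)
  defs <- list(
    m1_baseline = base,
    m2_cases = c(base, "d_ihs_cases"),
    m3_mobility = c(base, "d_ihs_cases", "residential_mobility"),
    m4_stringency = c(base, "d_ihs_cases", "decr_next", "incr_next"),
    m5_combined = combined,
    m6_emotions = c(combined, emotion_names())
  )
  if (is.null(retained_emotions)) {
    retained_emotions <- if (all(emotion_names() %in% names(panel))) {
      stepwise_emotion_selection(panel, combined,
                                 spec_args = spec_args)$retained
    } else {
      character(0)
    }
  }
  defs$m7_econ_fear <- c(combined, retained_emotions, "econ_fear")
  defs$m8_inst_trust <- c(combined, retained_emotions, "inst_trust")
  defs$m9_loneliness <- c(combined, retained_emotions, "loneliness_sad")

  # a deposited panel may lack the emotion or context columns; fit what exists
  defs <- defs[vapply(defs, function(r) all(r %in% names(panel)), TRUE)]

  fits <- lapply(defs, function(reg) {
    spec <- do.call(regression_spec, c(list(regressors = reg), spec_args))
    f <- fit_ols(panel, spec)
    if (bootstrap) f <- add_bootstrap_p(f) else f
  })
  summary <- tibble::tibble(
    model = names(fits),
    n_obs = unname(vapply(fits, `[[`, 0L, "n_obs")),
    n_clusters = unname(vapply(fits, `[[`, 0L, "n_clusters")),
    adj_r_squared = unname(vapply(fits, `[[`, 0, "adj_r_squared"))
  )
  list(fits = fits, summary = summary, retained_emotions = retained_emotions)
}
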