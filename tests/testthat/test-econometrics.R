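make_cluster_data <- function(seed, G = 10, n_g = 20, beta = 0) {
  set.seed(seed)
  cl <- rep(sprintf("c%02d", seq_len(G)), each = n_g)
  x <- rep(rnorm(G), each = n_g) + rnorm(G * n_g)
  e <- rep(rnorm(G, 0, 1), each = n_g) + rnorm(G * n_g)
  data.frame(y = 1 + beta * x + e, x = x, country = cl)
}

plain_spec <- function(regressors = "x", ...) {
  regression_spec(dependent = "y", regressors = regressors,
                  include_months = FALSE, include_seasons = FALSE, ...)
}

test_that("OLS reproduces an exact linear law", {
  dat <- data.frame(y = 2 + 3 * (1:10), x = 1:10, country = rep(c("a", "b"), 5))
  fit <- fit_ols(dat, plain_spec())
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_obs, 10L)
})

test_that("OLS equals the brute-force normal-equation solve", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:100, 1)
    dat <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                      country = sample(letters[1:4], n, replace = TRUE))
    fit <- fit_ols(dat, plain_spec(c("x1", "x2")))
    X <- cbind(1, dat$x1, dat$x2)
    expect_equal(unname(fit$coefficients), ols_normal_equations(X, dat$y),
                 tolerance = 1e-10)
  }
})

test_that("rank deficiency raises an error naming the collinear column", {
  dat <- make_cluster_data(1)
  dat$x_dup <- dat$x
  expect_error(fit_ols(dat, plain_spec(c("x", "x_dup"))),
               "rank deficient.*x_dup")
})

test_that("cluster-robust variance matches the sandwich oracle", {
  skip_if_not_installed("sandwich")
  dat <- make_cluster_data(4)
  fit <- fit_ols(dat, plain_spec())
  lmfit <- lm(y ~ x, data = dat)
  # same estimator up to the documented small-sample factor
  v_ours <- fit$se_cluster["x"]^2
  v_raw <- sandwich::vcovCL(lmfit, cluster = dat$country, type = "HC0",
                            cadjust = FALSE)["x", "x"]
  G <- fit$n_clusters; n <- fit$n_obs; k <- fit$k
  expect_equal(unname(v_ours), v_raw * G / (G - 1) * (n - 1) / (n - k),
               tolerance = 1e-10)
})

test_that("Webb weights have mean zero and unit variance exactly", {
  w <- c(-sqrt(3 / 2), -1, -sqrt(1 / 2), sqrt(1 / 2), 1, sqrt(3 / 2))
  expect_equal(mean(w), 0)
  expect_equal(mean(w^2), 1)
  set.seed(1)
  draws <- webb_weights(6000)
  expect_true(all(round(abs(draws), 10) %in% round(w[4:6], 10)))
})

test_that("bootstrap p-values are reproducible and detect a strong effect", {
  dat <- make_cluster_data(7, beta = 2)
  fit <- fit_ols(dat, plain_spec(B = 399, seed = 42))
  p1 <- wild_cluster_bootstrap_p(fit, "x", seed = 42)
  p2 <- wild_cluster_bootstrap_p(fit, "x", seed = 42)
  expect_identical(p1, p2)
  expect_lt(p1, 0.05)
  expect_gt(p1, 0)
  # null regressor: p should be unremarkable
  dat0 <- make_cluster_data(8, beta = 0)
  fit0 <- fit_ols(dat0, plain_spec(B = 399))
  p0 <- wild_cluster_bootstrap_p(fit0, "x", seed = 1)
  expect_gte(p0, 1 / 400)

  # unrestricted variant runs and broadly agrees on a strong effect
  spec_u <- plain_spec(B = 399, null_imposed = FALSE, seed = 42)
  fit_u <- fit_ols(dat, spec_u)
  expect_lt(wild_cluster_bootstrap_p(fit_u, "x", seed = 42), 0.05)
})

test_that("bootstrap guards its preconditions", {
  dat <- make_cluster_data(9)
  dat$country <- "only_one"
  fit <- fit_ols(dat, plain_spec())
  expect_error(wild_cluster_bootstrap_p(fit, "x"), "2 clusters")
  fit2 <- fit_ols(make_cluster_data(9), plain_spec())
  expect_error(wild_cluster_bootstrap_p(fit2, "nope"), "unknown coefficient")
  expect_warning(plain_spec(B = 50), "unreliable")
})

test_that("a vacuous threshold retains all emotions", {
  gp <- gen_panel(panel_scenario(seed = 3))
  sel <- stepwise_emotion_selection(gp$panel, combined_regressors(),
                                    threshold = 1.0,
                                    spec_args = list(B = 99, seed = 1))
  expect_setequal(sel$retained, emotion_names())
  expect_equal(nrow(sel$drop_log), 0L)
})

test_that("null-emotion retention is governed by the p-value threshold", {
  # all emotions pure noise: retention should sit well between the extremes
  # near the threshold, and a tighter threshold must retain fewer
  ret4 <- ret1 <- numeric(0)
  for (s in 1:25) {
    gp <- gen_panel(panel_scenario(seed = s + 500))
    s4 <- stepwise_emotion_selection(gp$panel, combined_regressors(),
                                     threshold = 0.4,
                                     spec_args = list(B = 99, seed = s))
    s1 <- stepwise_emotion_selection(gp$panel, combined_regressors(),
                                     threshold = 0.1,
                                     spec_args = list(B = 99, seed = s))
    ret4 <- c(ret4, length(s4$retained))
    ret1 <- c(ret1, length(s1$retained))
  }
  expect_gt(mean(ret4) / 8, 0.2)
  expect_lt(mean(ret1) / 8, mean(ret4) / 8)
})

test_that("the model ladder reports model-specific complete-case sizes", {
  gp <- gen_panel(panel_scenario(seed = 21))
  panel <- gp$panel
  ladder <- run_model_ladder(panel, retained_emotions = c("disgust", "trust"),
                             spec_args = list(B = 99, seed = 1))
  s <- ladder$summary
  # fully observed regressors: N identical across nested models up to the
  # rows consumed by the stringency dummies' final week
  expect_equal(s$n_obs[s$model == "m1_baseline"],
               s$n_obs[s$model == "m2_cases"])
  expect_equal(s$n_obs[s$model == "m5_combined"],
               s$n_obs[s$model == "m4_stringency"])

  # mobility starting 5 weeks late costs 5 rows per country in models using it
  panel2 <- panel
  first5 <- panel2$week %in% sort(unique(panel2$week))[1:5]
  panel2$residential_mobility[first5] <- NA
  l2 <- run_model_ladder(panel2, retained_emotions = character(0),
                         spec_args = list(B = 99, seed = 1))
  G <- length(unique(panel$country))
  # baseline unaffected; mobility model loses 5 weeks x G minus the rows it
  # already lost to the lag (week 1 overlaps both rules)
  expect_equal(l2$summary$n_obs[l2$summary$model == "m1_baseline"],
               s$n_obs[s$model == "m1_baseline"])
  expect_equal(
    s$n_obs[s$model == "m3_mobility"] -
      l2$summary$n_obs[l2$summary$model == "m3_mobility"],
    4L * G)

  # dropping context coverage for one country reduces clusters there only
  panel3 <- panel
  panel3$econ_fear[panel3$country == panel3$country[1]] <- NA
  l3 <- run_model_ladder(panel3, retained_emotions = character(0),
                         spec_args = list(B = 99, seed = 1))
  expect_equal(l3$summary$n_clusters[l3$summary$model == "m7_econ_fear"],
               G - 1L)
  expect_equal(l3$summary$n_clusters[l3$summary$model == "m5_combined"], G)
})
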