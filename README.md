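# gnhpanel

Social-media text arrives hourly; well-being surveys arrive twice a year.
`gnhpanel` is an R toolkit for researchers who want to bridge that gap: it
turns raw tweet streams into daily national well-being indices and then asks,
in a small multi-country panel, what moved them — epidemic severity,
containment policy, mobility, emotions — with inference that is honest about
having only a handful of country clusters.

## What it computes

**Gross National Happiness (GNH).** Each cleaned tweet is classified
positive / neutral / negative by summing lexicon polarities over its tokens
(coded 0 / 2 / 4 respectively). For every hour the positive–negative balance
is scaled onto 0–10:

```
GNH_hour = 5 * (1 + (N_pos − N_neg) / (N_pos + N_neg))
```

and the daily index is the mean over the hours of the local calendar day.
An all-positive hour scores 10, an all-negative hour 0, a balanced (or
all-neutral) hour 5.

**Emotions and context series.** Tweets are scored on the eight Plutchik
emotions (anger, fear, anticipation, trust, surprise, sadness, joy, disgust)
by summing word intensities (0–10 scale, clipped at 10) and averaging per
day. Three context series score a specific emotion on keyword-filtered
subsets: *economic fear* (fear on economy tweets), *institutional trust*
(trust on tweets about national institutions), and *loneliness* (sadness on
loneliness tweets).

**The weekly panel model.** Daily series are averaged over ISO weeks and
merged with epidemic covariates into a country–week panel for the dynamic
regression

```
GNH_it = α + ρ GNH_it−1 + β1 ΔIHS(Cases)_it + β2 Distancing_it
       + β3 Decr.Policies_it+1 + β4 Incr.Policies_it+1
       + β5 Emotions_it + β6 EconFear_it + β7 GenTrust_it
       + β8 InstTrust_it + β9 Loneliness_it + γ X_it + ε_it
```

where `IHS(x) = ln(x + √(x²+1))` is the inverse hyperbolic sine of weekly
new cases per million (log-like but defined at zero), the policy dummies
flag next-week changes of the 0–100 stringency index, and `X` holds month
and hemisphere-aware season dummies. Estimation is OLS; p-values come from a
restricted **wild cluster bootstrap** with Webb six-point weights
(±√(3/2), ±1, ±√(1/2)), the recommended scheme when there are ten or fewer
clusters. A backward step-wise routine retains the emotions whose bootstrap
p-value stays below 0.4, and a model ladder reproduces the step-wise
specification sequence.

Everything is testable offline: `gen_lexicons()`, `gen_tweet_stream()` and
`gen_panel()` generate lexicons, tweet streams with planted sentiment
mixtures, and panels drawn from the regression model itself with known
coefficients and cluster-correlated errors.

## Worked example

```r
library(gnhpanel)

# synthetic lexicons + a 2-country stream whose mood sours after two weeks
lex <- gen_lexicons(seed = 1, vocab_size = 120)
sc  <- stream_scenario(countries = c("FR", "NZ"), start_date = "2020-03-02",
                       n_days = 28, tweets_per_day = 400,
                       p_pos = c(rep(0.45, 14), rep(0.35, 14)),
                       p_neg = c(rep(0.25, 14), rep(0.35, 14)), seed = 1)
daily <- build_daily_series(gen_tweet_stream(sc, lex),
                            lex$sentiment, lex$emotion)
daily[1:4, c("country", "date", "n_tweets", "n_pos", "n_neg", "gnh",
             "trust", "econ_fear")]
#>   country date       n_tweets n_pos n_neg   gnh trust econ_fear
#> 1 FR      2020-03-02      400   188    95  6.75  1.07      1.05
#> 2 FR      2020-03-03      400   176   111  6.05  1.24      1
#> 3 FR      2020-03-04      400   182    83  7.05  1.03      2.17
#> 4 FR      2020-03-05      400   174    98  6.45  1.10      1.41
```

The planted first-fortnight mixture (45% positive, 25% negative) implies
`5(1 + 0.2/0.7) ≈ 6.43`; the pipeline recovers 6.47, and the soured schedule
(equal shares, implied 5) yields 5.13 in the second fortnight.

```r
# a panel drawn from the model itself, then refitted with bootstrap p-values
gp   <- gen_panel(panel_scenario(seed = 1))
spec <- regression_spec(regressors = c("lag_gnh", "d_ihs_cases",
                                       "residential_mobility",
                                       "decr_next", "incr_next"),
                        B = 999, seed = 42)
fit  <- add_bootstrap_p(fit_ols(gp$panel, spec), terms = spec$regressors)
tidy_fit(fit)[2:6, ]
#>   term                 estimate cluster_se t_value boot_p
#> 1 lag_gnh               0.981      0.00536 183.     0.001
#> 2 d_ihs_cases          -0.00709    0.0184   -0.385  0.722
#> 3 residential_mobility  0.00674    0.00216   3.12   0.012
#> 4 decr_next            -0.0800     0.0386   -2.07   0.063
#> 5 incr_next            -0.00456    0.0197   -0.231  0.822
```

One draw of a 10-country, 52-week panel is noisy — the mobility and lag
coefficients land near their planted values (0.004, 0.922) while the case
coefficient is indistinguishable from zero at this sample size; averaged
over hundreds of seeds the covariate coefficients are recovered with under
10% bias (see the test suite).

Small fixture lexicons for experimentation ship under
`inst/extdata/` (`sentiment_fixture.tsv`, `emotion_fixture.tsv`); they are
synthetic stand-ins, not excerpts of any published lexicon.

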