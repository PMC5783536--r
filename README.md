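# ziglm

Two-part zero-inflated gamma (ZIG) regression for semicontinuous outcomes,
built around the motivating case of **leisure-time physical activity
(LTPA)**: weekly activity minutes that mix a large point mass at exactly
zero (people who do no leisure activity) with a right-skewed continuous
positive part. The package is for epidemiologists and biostatisticians who
want adjusted effects on *both* the decision to be active and the time
spent active, in the outcome's own units, instead of discarding the
continuous information by categorising it.

## The model

For weekly minutes $Y_i \ge 0$ with activity indicator
$X_i = \mathbf{1}(Y_i>0)$:

- **Zero process**: $X_i \sim \mathrm{Bernoulli}(p_i)$,
  $\operatorname{logit}(p_i) = x_i'\alpha$ — effects reported as odds
  ratios of doing any activity.
- **Duration**: $Y_i \mid X_i{=}1 \sim \mathrm{Gamma}$ with mean
  $\mu_i = w_i'\beta$ (identity link) and variance $\mu_i^2\nu^2$ — each
  $\beta_j$ is directly an adjusted mean difference in minutes/week.

Zeros can only come from the Bernoulli hurdle, so the likelihood factors,

$$L(p,\mu,\nu)=\prod_{Y_i=0}(1-p_i)\prod_{Y_i>0}p_i\prod_{Y_i>0}f(y_i\mid\mu_i,\nu),$$

and the two parts are fitted separately; `fit_zig()` returns both with the
total factored log-likelihood. The identity-link gamma MLE (with joint
maximum-likelihood dispersion and positivity-guarded Fisher scoring) is
implemented in the package. A baseline-category **multinomial comparator**
on the none / &lt;150 / ≥150 minutes-per-week categorisation is included,
and `compare_models()` aligns the two — deliberately without AIC/BIC, which
are not comparable across different response variables.

Because no individual-level cohort data are deposited, the package also
ships a **synthetic cohort generator** emulating the ELSA-Brasil baseline
(adults 35–74: 54.4% women, mean age 52, 36.8% graduate education, mean
per-capita income US$6,505, 43% doing no LTPA, 237 min/week among the
active) plus Monte-Carlo **recovery experiments** (`run_recovery()`,
`calibration_check()`) that validate the estimators against known truth.

## Worked example

```r
library(ziglm)

cfg <- calibrate_config(sim_config(n = 14823, seed = 1))
sim <- simulate_zig(cfg)          # synthetic cohort, known truth
mean(sim$weekly_minutes == 0)     # 0.428 — the zero spike
fit <- fit_zig(sim)
fit
```

```
<ziglm two-part zero-inflated gamma fit>
  n = 14823  ( zeros: 6350 , positive: 8473 , dropped: 0 )
  total logLik = -64057.91688 = logistic -9697.8497 + gamma -54360.067

Zero process (odds ratios):
  term           OR conf.low conf.high
1 intercept   0.244    0.192     0.311
2 male        1.77     1.65      1.89
3 high_school 1.21     1.08      1.35
4 college     1.71     1.51      1.94
5 graduate    2.21     1.98      2.46
6 age_decades 1.14     1.10      1.19
7 income_k    1.05     1.04      1.06

Duration among the active (mean differences, minutes/week):
  term        delta_minutes conf.low conf.high significant
1 intercept           86.6     50.0     123.   TRUE
2 male                26.0     15.6      36.5  TRUE
3 high_school         28.2     11.0      45.4  TRUE
4 college             40.2     20.6      59.8  TRUE
5 graduate            26.4      9.84     42.9  TRUE
6 age_decades          9.42     3.10     15.7  TRUE
7 income_k             7.91     6.72      9.10 TRUE
```

Reading it: men have 1.77 times the adjusted odds of doing any leisure
activity and, among the active, spend on average 26 minutes/week more than
women (simulated truth: odds ratio 1.70, 28.78 minutes). Each US$1,000 of
income adds 5% to the odds and ~8 minutes/week. The unconditional
expectation for a covariate profile multiplies the two parts:

```r
profile <- tibble::tibble(
  gender = "male", age_years = 50, education = "graduate", income_usd = 10000
)
predict_mean_time(fit, newdata = profile)
#   p_active mean_minutes_active mean_minutes
#      0.751                265.         199.
```

`fit_multinomial_activity(sim)` fits the comparator;
`compare_models(fit, mn)` tabulates both side by side;
`plot_activity_histogram(sim)` and `autoplot(fit)` draw the outcome's
zero-inflated shape and the coefficient forest. See the vignette
(`vignettes/zig-two-part-model.Rmd`) for the model, fitting algorithm and
generator design in detail.

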