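---
title: "Modelling semicontinuous activity time with a two-part zero-inflated gamma model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling semicontinuous activity time with a two-part zero-inflated gamma model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ziglm)
library(dplyr)
```

## The problem

Weekly minutes of leisure-time physical activity (LTPA) are a
*semicontinuous* outcome: a large point mass at exactly zero (people who do
no leisure activity at all) next to a continuous, strongly right-skewed
positive part. Neither a normal linear model nor a single GLM describes this
shape well, and the common workaround — categorising the outcome at
guideline thresholds and fitting logistic or multinomial models — throws
away the continuous information.

`ziglm` models the outcome in its original units with a **two-part
("hurdle") zero-inflated gamma (ZIG) model** and, for comparison, fits the
conventional multinomial model on the three-level categorisation
(none / below 150 / at or above 150 minutes per week, the adult-health
guideline cut-off, with the boundary value in the upper class).

## The model

Let $Y_i \ge 0$ be participant $i$'s weekly LTPA minutes and $X_i =
\mathbf{1}(Y_i > 0)$ the activity indicator. The two parts are:

* **Zero process** — $X_i \sim \mathrm{Bernoulli}(p_i)$ with
  $\operatorname{logit}(p_i) = x_i'\alpha$ (logistic regression).
* **Duration** — given $X_i = 1$, $Y_i$ follows a gamma distribution with
  mean $\mu_i = w_i'\beta$ (identity link) and variance $\mu_i^2\nu^2$,
  where $\nu$ is the coefficient of variation (gamma shape $1/\nu^2$, scale
  $\mu_i\nu^2$).

Because the gamma density is strictly positive, zeros can come only from
the Bernoulli part and the likelihood factors,

$$
L(p, \mu, \nu) \;=\; \prod_{Y_i = 0} (1 - p_i)\;
\prod_{Y_i > 0} p_i\; \prod_{Y_i > 0} f(y_i \mid \mu_i, \nu),
$$

with no parameter shared between the factors. The two parts are therefore
fitted **separately**, and the sum of their maximised log-likelihoods is the
joint maximum — an identity `fit_zig()` exposes as `total_loglik` and that
the test suite checks to $10^{-9}$ relative, alongside agreement with a
generic joint optimiser.

The identity link is *not* the canonical gamma link. The canonical inverse
link gives coefficients that are hard to read; with the identity link,
$\beta_j$ is directly the adjusted difference in mean minutes/week per unit
of covariate $j$. The price is a constraint: every fitted mean $w_i'\beta$
must stay strictly positive.

The covariates in the two parts need not coincide
(`fit_zig(data, spec, gamma_spec = ...)`); by default both use the same
design.

### Design and units

`design_spec()` fixes the column order
(`intercept, male, high_school, college, graduate, age_decades, income_k`)
so coefficient vectors are comparable across runs. Reference categories are
*female* and *basic education*; age enters in decades and annual per-capita
income in US$1,000, so odds ratios and mean differences read "per 10 years"
and "per US$1,000". Analyses are complete-case: rows missing any modelled
variable are dropped and counted (`n_dropped`), mirroring cohort practice.

### Fitting the gamma part

A design decision worth spelling out: under the mean/CV parameterisation the
score for $\beta$,
$k \, W'\!\left((y-\mu)/\mu^2\right)$ with $k = 1/\nu^2$, does not involve
the shape. The joint MLE therefore *profiles exactly*: we run Fisher scoring
for $\beta$ — starting from the least-squares solution, inflating the
intercept if needed to enter the feasible region, and step-halving any
update that would make a fitted mean non-positive or worsen the likelihood —
and then solve the one-dimensional shape equation
$\log k - \psi(k) = \overline{d - \log d - 1}$, $d_i = y_i/\hat\mu_i$, by
bracketed root-finding. This is numerically equivalent to a joint
$(\beta, \log\nu)$ optimisation with an infeasibility barrier, but each step
is a weighted least-squares solve, which is faster and has no tuning
constants; the equivalence is asserted against `optim()` in the tests.
Dispersion is full maximum likelihood (not a moment estimator), consistent
with writing out the complete likelihood above. If all durations are equal
the shape equation's right side is zero and the fitter returns the
no-dispersion limit $\hat\nu \to 0$ (capped at shape $10^{12}$).

Convergence: relative change in the likelihood monitor below $10^{-10}$,
at most 200 iterations; an optimum pushed onto the positivity boundary is
reported as an error with diagnostics, never silently accepted. Standard
errors for $\beta$ come from the inverse *observed* information at
$(\hat\beta, \hat\nu)$; all intervals are Wald, symmetric on the scale of
the coefficient (hence symmetric on the log scale for odds ratios).

### The logistic part and the multinomial comparator

The zero process is fitted by iteratively reweighted least squares
(Newton–Raphson for the canonical logit link) with tolerance $10^{-10}$ and
at most 100 iterations, via `stats::glm.fit` behind the `fit_logistic()`
surface. Rank-deficient designs are rejected with the collinear columns
named, and (quasi-)complete separation — a diverging coefficient with the
likelihood still improving — is an error naming the separating column.

The comparator (`fit_multinomial()`, reference category *none*) is a
baseline-category logit fitted by `nnet::multinom` with a tightened
tolerance; its covariance is the inverse observed information. A
two-category outcome reduces it exactly to the binary logistic model, which
the tests use as an oracle. `compare_models()` lays the two models'
odds-ratio tables side by side together with the gamma mean differences and
deliberately reports **no AIC/BIC**: the models do not describe the same
response variable, so their likelihoods are not comparable.

## The synthetic cohort generator

No individual-level cohort data are deposited, so the package ships a
generator (`simulate_covariates()`, `simulate_zig()`) that emulates the
ELSA-Brasil baseline structure — a Brazilian multicentre cohort of civil
servants aged 35–74 — and draws outcomes from the generative ZIG process
with known truth. Defaults:

* **Gender**: Bernoulli, P(female) = 0.544.
* **Age**: normal(52, 9.1) truncated to [35, 74] by inverse-CDF (the
  truncation shifts the realised mean to ≈ 52.5 and trims the SD slightly).
* **Education**: categorical with shares 12.7 / 34.6 / 15.9 / 36.9 % for
  basic / high school / college / graduate.
* **Income**: log-normal with mean US$6,505 and `sdlog = 0.75`, a
  right-skew typical of income data; the group means this implies span the
  range seen across education strata in comparable cohorts.
* **Effects** (`elsa_effects()`): zero-process odds ratios 1.70 (men),
  1.28 / 1.72 / 2.32 (education), 1.12 (age, per decade), 1.05 (income, per
  US$1,000); duration effects 28.78, 19.93 / 25.81 / 14.45, 6.20 and 7.58
  minutes/week on the same terms.
* **Dispersion**: $\nu = 1.1$, giving positive durations whose SD slightly
  exceeds their mean — the degree of right-skew (with a long tail past
  1,000 minutes/week) that matches the published marginal picture.

Published tables report no intercepts, so `calibrate_config()` derives them
at run time: the logistic intercept by root-finding so the marginal zero
fraction over a large simulated covariate panel equals 43%, and the gamma
intercept in closed form (the mean is linear in it, averaged with
activity-probability weights) so the mean among the active equals 237
minutes/week. Calibration uses a panel of 200,000 covariate draws by
default; `calibration_check()` verifies the achieved marginals with
Monte-Carlo standard errors.

Covariates are generated **independently** — the cohort's joint covariate
distribution is not published — with an optional `dependence` hook (off by
default) for users who want, say, income rising with education. This is the
main respect in which passing tests do *not* certify behaviour on real
data: real covariates are correlated, measurement of activity by
questionnaire is noisy and over-reports, and the cohort has survey
structure the generator ignores. What the simulations do establish is that
the estimators recover the truth of the generative model they claim to fit,
with honest uncertainty.

## Recovery experiments

`run_recovery()` repeats simulate → refit over replicates (replicate $r$
uses seed `seed + r`, so reports are bit-for-bit reproducible), recording
per-parameter bias, empirical SE and Wald coverage; failures are logged,
never dropped. Default desk-scale experiment sizes — 50 cohort-sized
(n = 14,823) replicates for the headline effects, 200 replicates of
n = 5,000 for coverage, and 40/40/15 replicates at n = 1,000/10,000/50,000
for the consistency check — keep the full suite in the tens of seconds on
one CPU while leaving Monte-Carlo error well below the effect sizes of
interest.

```{r recovery, eval = FALSE}
cfg <- calibrate_config(sim_config(n = 14823, seed = 1))
rec <- run_recovery(cfg, replicates = 50)
rec$summary
autoplot(rec)
```

## Worked example

```{r example}
cfg <- calibrate_config(sim_config(n = 14823, seed = 1))
sim <- simulate_zig(cfg)
mean(sim$weekly_minutes == 0) # ~0.43
fit <- fit_zig(sim)
glance(fit)
odds_ratios(fit$logistic)
mean_differences(fit$gamma)

mn <- fit_multinomial_activity(sim)
compare_models(fit, mn)

# expected weekly minutes for a 50-year-old graduate man on US$10,000/year
profile <- tibble::tibble(
  gender = "male", age_years = 50, education = "graduate", income_usd = 10000
)
predict_mean_time(fit, newdata = profile)
```

## Known limitations

* Zeros are structural: a person with a positive latent propensity but zero
  recorded minutes is not representable; the gamma never produces zeros.
* `predict_mean_time()` is a point prediction; no delta-method standard
  errors are attached.
* No survey weights, clustering, regularisation or interaction terms; no
  ordinal (proportional-odds) alternative to the multinomial comparator.
* The outcome construction helper (`weekly_minutes()`) is the plain
  days × minutes product; it does not parse questionnaire sub-domains
  (walking / moderate / vigorous) or their aggregation, which the package
  consumes already totalled.
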