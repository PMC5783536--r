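test_that("covariate marginals match their targets within Monte-Carlo error", {
  cfg <- sim_config(n = 10000, seed = 101)
  cov <- simulate_covariates(cfg)
  m <- elsa_marginals()

  p_f <- mean(cov$gender == "female")
  se_f <- sqrt(m$p_female * (1 - m$p_female) / cfg$n)
  expect_lt(abs(p_f - m$p_female), 3 * se_f)

  expect_true(all(cov$age_years >= 35 & cov$age_years <= 74))

  p_grad <- mean(cov$education == "graduate")
  se_g <- sqrt(0.3685 * (1 - 0.3685) / cfg$n)
  expect_lt(abs(p_grad - m$education_probs[["graduate"]]), 3 * se_g)

  se_inc <- sd(cov$income_usd) / sqrt(cfg$n)
  expect_lt(abs(mean(cov$income_usd) - m$income_mean), 3 * se_inc)
  # right-skewed income: mean well above the median
  expect_gt(mean(cov$income_usd), stats::median(cov$income_usd))
})

test_that("a single record respects the age truncation bounds", {
  cov <- simulate_covariates(sim_config(n = 1, seed = 77))
  expect_equal(nrow(cov), 1)
  expect_true(cov$age_years >= 35 && cov$age_years <= 74)
})

test_that("the same seed reproduces records exactly", {
  cfg <- small_config(n = 200, seed = 13)
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  expect_identical(
    simulate_zig(cfg)$weekly_minutes,
    simulate_zig(cfg)$weekly_minutes
  )
})

test_that("invalid education proportions are rejected", {
  m <- elsa_marginals()
  m$education_probs <- c(basic = 0.5, high_school = 0.2, college = 0.2, graduate = 0.2)
  expect_error(sim_config(marginals = m), "sum to 1")
  expect_error(sim_config(nu = -1), "positive")
  expect_error(sim_config(n = 0), "at least 1")
})

test_that("degenerate Bernoulli configs give all-zero or all-positive outcomes", {
  p <- length(.subset2(sim_config(n = 5, seed = 1), "alpha"))
  alpha_never <- c(-30, rep(0, p - 1))
  beta_flat <- c(237, rep(0, p - 1))
  cfg <- sim_config(n = 300, seed = 21, alpha = alpha_never, beta = beta_flat, nu = 1)
  expect_true(all(simulate_zig(cfg)$weekly_minutes == 0))

  cfg$alpha[1] <- 30
  y <- simulate_zig(cfg)$weekly_minutes
  expect_true(all(y > 0)) # gamma support is strictly positive
})

test_that("intercept-only truths reproduce the cohort's marginal zero share and positive mean", {
  p <- length(.subset2(sim_config(n = 5, seed = 1), "alpha"))
  cfg <- sim_config(
    n = 20000, seed = 31,
    alpha = c(qlogis(0.57), rep(0, p - 1)),
    beta = c(237, rep(0, p - 1)), nu = 1.1
  )
  y <- simulate_zig(cfg)$weekly_minutes
  zero_frac <- mean(y == 0)
  expect_lt(abs(zero_frac - 0.43), 3 * sqrt(0.43 * 0.57 / cfg$n))
  pos <- y[y > 0]
  expect_lt(abs(mean(pos) - 237), 3 * 237 * 1.1 / sqrt(length(pos)))
})

test_that("positives converge to the gamma mean and variance at fixed covariates", {
  p <- length(.subset2(sim_config(n = 5, seed = 1), "alpha"))
  nu <- 0.8
  cfg <- sim_config(
    n = 40000, seed = 41,
    alpha = c(30, rep(0, p - 1)), # everyone active
    beta = c(200, rep(0, p - 1)), nu = nu
  )
  y <- simulate_zig(cfg)$weekly_minutes
  expect_lt(abs(mean(y) - 200) / 200, 0.02)
  expect_lt(abs(var(y) - 200^2 * nu^2) / (200^2 * nu^2), 0.06)
  # right-skew with excess zeros under the calibrated defaults
  cal <- small_config(n = 20000, seed = 43)
  yy <- simulate_zig(cal)$weekly_minutes
  expect_gt(mean(yy == 0), 0.3)
  pos <- yy[yy > 0]
  skew <- mean((pos - mean(pos))^3) / sd(pos)^3
  expect_gt(skew, 1)
})

test_that("a non-positive gamma mean aborts with the offending profile", {
  p <- length(.subset2(sim_config(n = 5, seed = 1), "alpha"))
  beta_bad <- c(10, rep(0, p - 1))
  names_beta <- names(.subset2(sim_config(n = 5, seed = 1), "beta"))
  beta_bad <- stats::setNames(beta_bad, names_beta)
  beta_bad[["age_decades"]] <- -10 # ages 3.5-7.4 decades force w'beta < 0
  cfg <- sim_config(
    n = 100, seed = 51,
    alpha = rep(0, p), beta = beta_bad, nu = 1
  )
  expect_error(simulate_zig(cfg), "Non-positive gamma mean")
})

test_that("calibration hits the marginal targets and fills only NA intercepts", {
  cfg <- small_config(n = 5000, seed = 61)
  expect_false(any(is.na(cfg$alpha)))
  expect_false(any(is.na(cfg$beta)))
  check <- calibration_check(cfg, n = 60000)
  expect_lt(abs(check$zero_fraction - 0.43), 4 * check$zero_fraction_se + 0.005)
  expect_lt(abs(check$positive_mean - 237), 4 * check$positive_mean_se + 2)

  # an explicitly supplied intercept is left untouched
  cfg2 <- sim_config(n = 100, seed = 62)
  cfg2$alpha[1] <- -1
  cfg2 <- calibrate_config(cfg2, n_calib = 20000)
  expect_equal(unname(cfg2$alpha[1]), -1)
})

test_that("the optional covariate dependence hook is applied", {
  hook <- function(df) {
    df$income_usd <- df$income_usd * ifelse(df$education == "graduate", 2, 1)
    df
  }
  cfg_dep <- sim_config(n = 4000, seed = 71, dependence = hook)
  cfg_ind <- sim_config(n = 4000, seed = 71)
  dep <- simulate_covariates(cfg_dep)
  ind <- simulate_covariates(cfg_ind)
  ratio <- mean(dep$income_usd[dep$education == "graduate"]) /
    mean(ind$income_usd[ind$education == "graduate"])
  expect_gt(ratio, 1.8)
})
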