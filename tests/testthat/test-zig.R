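test_that("the six-point worked example recovers both closed forms", {
  x <- matrix(1, 6, 1, dimnames = list(NULL, "intercept"))
  y <- c(0, 0, 0, 100, 200, 300)
  fit <- fit_zig(x, y = y)
  expect_equal(unname(plogis(fit$logistic$coefficients)), 0.5, tolerance = 1e-9)
  expect_equal(unname(fit$gamma$coefficients), 200, tolerance = 1e-9)
  expect_equal(fit$n_zero, 3)
  expect_equal(fit$n_positive, 3)
  # generic optimisers agree part by part
  o_l <- oracle_optim(0, oracle_nll_logistic, x = x, y = as.numeric(y > 0))
  o_g <- oracle_optim(c(150, 0), oracle_nll_gamma, w = x[y > 0, , drop = FALSE], y = y[y > 0])
  expect_equal(unname(fit$logistic$coefficients), unname(o_l$par), tolerance = 1e-6)
  expect_equal(unname(fit$gamma$coefficients), o_g$par[1], tolerance = 1e-4)
  # unconditional mean prediction is the product of the two parts
  pred <- predict_mean_time(fit, x = matrix(1, 1, 1, dimnames = list(NULL, "intercept")))
  expect_equal(pred$mean_minutes, 100, tolerance = 1e-8)
})

test_that("the factored likelihood identity holds to 1e-9 relative", {
  for (seed in c(501, 502)) {
    cfg <- small_config(n = 3000, seed = seed)
    sim <- simulate_zig(cfg)
    fit <- fit_zig(sim)
    des <- build_design(sim, cfg$spec)
    y <- des$data$weekly_minutes
    ll <- zig_loglik(
      fit$logistic$coefficients, fit$gamma$coefficients, fit$gamma$nu,
      des$x, des$x, y
    )
    expect_equal(fit$total_loglik, ll, tolerance = 1e-9)
    expect_equal(fit$total_loglik, fit$logistic$loglik + fit$gamma$loglik,
      tolerance = 1e-12
    )
    expect_equal(fit$n, fit$n_zero + fit$n_positive)
  }
})

test_that("separately maximised parts are the joint optimum", {
  set.seed(503)
  n <- 180
  x <- cbind(intercept = 1, d = rbinom(n, 1, 0.5))
  alpha <- c(0.3, 0.6)
  beta <- c(150, 40)
  nu <- 0.9
  active <- rbinom(n, 1, plogis(drop(x %*% alpha))) == 1
  y <- numeric(n)
  y[active] <- rgamma(sum(active), 1 / nu^2, scale = drop(x[active, ] %*% beta) * nu^2)
  fit <- fit_zig(x, y = y)

  nll_joint <- function(par) {
    a <- par[1:2]
    b <- par[3:4]
    lnu <- par[5]
    -tryCatch(
      zig_loglik(a, b, exp(lnu), x, x, y),
      error = function(e) -1e10
    )
  }
  start <- c(0, 0, mean(y[y > 0]), 0, 0)
  o <- oracle_optim(start, nll_joint)
  fitted_par <- c(fit$logistic$coefficients, fit$gamma$coefficients, log(fit$gamma$nu))
  expect_lt(max(abs(fitted_par - o$par) / pmax(abs(o$par), 1)), 1e-4)
  expect_gte(-nll_joint(fitted_par), -o$value - 1e-6)

  # the fitted point is a local maximum: no perturbation improves it
  ll_hat <- -nll_joint(fitted_par)
  for (j in seq_along(fitted_par)) {
    for (eps in c(-1e-3, 1e-3)) {
      par <- fitted_par
      par[j] <- par[j] * (1 + eps) + eps * (par[j] == 0)
      expect_lte(-nll_joint(par), ll_hat + 1e-8)
    }
  }
})

test_that("zig_loglik reduces to the pure gamma likelihood when nothing is zero", {
  set.seed(505)
  n <- 60
  w <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  y <- rgamma(n, 2, scale = 100)
  big_alpha <- 40 # p identically ~1
  ll <- zig_loglik(big_alpha, 210, 0.7, w, w, y)
  expect_equal(ll, sum(dgamma(y, 1 / 0.49, scale = 210 * 0.49, log = TRUE)),
    tolerance = 1e-9
  )
  expect_error(
    zig_loglik(0, -5, 0.7, w, w, y),
    "Non-positive gamma mean"
  )
})

test_that("all-zero and all-positive outcomes are rejected", {
  x <- matrix(1, 10, 1, dimnames = list(NULL, "intercept"))
  expect_error(fit_zig(x, y = rep(0, 10)), "No positive outcomes")
  expect_error(fit_zig(x, y = rep(10, 10)), "No zeros")
})

test_that("the gamma part sees exactly the positive subset", {
  x <- matrix(1, 8, 1, dimnames = list(NULL, "intercept"))
  y <- c(0, 5, 0, 10, 0, 15, 0, 20)
  fit <- fit_zig(x, y = y)
  expect_equal(fit$gamma$n_positive, 4)
  expect_equal(fit$logistic$n, 8)
  expect_equal(unname(fit$gamma$coefficients), mean(c(5, 10, 15, 20)), tolerance = 1e-9)
})

test_that("the two parts may use different designs", {
  cfg <- small_config(n = 2500, seed = 507)
  sim <- simulate_zig(cfg)
  fit <- fit_zig(sim,
    spec = design_spec(c("gender", "education", "age", "income")),
    gamma_spec = design_spec(c("gender", "age"))
  )
  expect_equal(length(fit$logistic$coefficients), 7)
  expect_equal(length(fit$gamma$coefficients), 3)
  expect_true(fit$logistic$converged && fit$gamma$converged)
})

test_that("predicted mean time is monotone in each part", {
  cfg <- small_config(n = 3000, seed = 509)
  fit <- fit_zig(simulate_zig(cfg))
  x_row <- matrix(c(1, 1, 0, 0, 1, 5, 6.5), 1, dimnames = list(NULL, names(cfg$alpha)))
  base <- predict_mean_time(fit, x = x_row)
  # raising the activity propensity at fixed duration design raises the mean
  x_up <- x_row
  x_up[1, "income_k"] <- 12
  up_p <- predict_mean_time(fit, x = x_up, w = x_row)
  expect_gt(up_p$mean_minutes, base$mean_minutes)
  expect_gt(up_p$p_active, base$p_active)
  # raising the duration design at fixed propensity does the same
  up_mu <- predict_mean_time(fit, x = x_row, w = x_up)
  expect_gt(up_mu$mean_minutes_active, base$mean_minutes_active)
  expect_gt(up_mu$mean_minutes, base$mean_minutes)
})

test_that("model comparison aligns terms, checks rows and reports no information criteria", {
  cfg <- small_config(n = 2500, seed = 511)
  sim <- simulate_zig(cfg)
  zig <- fit_zig(sim)
  mn <- fit_multinomial_activity(sim)
  cmp <- compare_models(zig, mn)
  expect_setequal(
    unique(cmp$or_table$component),
    c("multinomial_low", "multinomial_high", "zig_logistic")
  )
  expect_setequal(unique(cmp$or_table$term), names(cfg$alpha))
  expect_equal(nrow(cmp$gamma_table), length(cfg$beta))
  flat <- c(names(unlist(cmp)), unlist(lapply(cmp, names)))
  expect_false(any(grepl("aic|bic", tolower(flat))))
  expect_true(any(grepl("AIC/BIC are not reported", cmp$footnotes)))

  other <- fit_multinomial_activity(simulate_zig(small_config(n = 2400, seed = 512)))
  expect_error(compare_models(zig, other), "Row-set mismatch")

  dir <- withr::local_tempdir()
  export_tables(cmp, zig, dir)
  expect_true(file.exists(file.path(dir, "odds_ratios.csv")))
  log <- readLines(file.path(dir, "run_log.txt"))
  expect_true(any(grepl("^n_zero:", log)))
})

test_that("tidy and glance return the documented tibbles", {
  cfg <- small_config(n = 1500, seed = 513)
  fit <- fit_zig(simulate_zig(cfg))
  td <- tidy(fit)
  expect_setequal(unique(td$component), c("logistic", "gamma"))
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$total_logLik, gl$logistic_logLik + gl$gamma_logLik)
  expect_true(gl$converged)
})
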