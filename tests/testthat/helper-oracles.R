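# Independent oracle implementations used to cross-check the fitters.
# These deliberately avoid the package's own code paths: likelihoods are
# written out from the densities and maximised with stats::optim.

oracle_nll_logistic <- function(par, x, y) {
  -sum(stats::dbinom(y, 1, stats::plogis(drop(x %*% par)), log = TRUE))
}

# joint (beta, log nu) gamma likelihood, mean w'beta, variance (w'beta)^2 nu^2
oracle_nll_gamma <- function(par, w, y) {
  p <- ncol(w)
  beta <- par[seq_len(p)]
  nu <- exp(par[p + 1])
  mu <- drop(w %*% beta)
  if (any(mu <= 0)) {
    return(1e10)
  }
  k <- 1 / nu^2
  -sum(stats::dgamma(y, shape = k, scale = mu * nu^2, log = TRUE))
}

# baseline-category multinomial likelihood; par is a (K-1) x p matrix
# flattened row-wise, categories ordered as levels(y)[-1]
oracle_nll_multinomial <- function(par, x, y) {
  k1 <- nlevels(y) - 1
  p <- ncol(x)
  b <- matrix(par, nrow = k1, byrow = TRUE)
  eta <- x %*% t(b) # n x (K-1)
  denom <- 1 + rowSums(exp(eta))
  ll <- -log(denom) # reference category contribution
  for (j in seq_len(k1)) {
    sel <- y == levels(y)[j + 1]
    ll[sel] <- ll[sel] + eta[sel, j]
  }
  -sum(ll)
}

oracle_optim <- function(par, fn, ..., polish = TRUE) {
  o <- stats::optim(par, fn, ...,
    method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-15)
  )
  if (polish && length(par) > 1) {
    o <- stats::optim(o$par, fn, ...,
      method = "Nelder-Mead",
      control = list(maxit = 10000, reltol = 1e-15)
    )
  }
  o
}

# small deterministic participant table used across data-model tests
make_records <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d"),
    gender = c("female", "male", "Male", "female"),
    age_years = c(50, 35, 60, 42),
    education = c("basic", "graduate", "high_school", "college"),
    income_usd = c(5000, 12000, 3000, NA),
    weekly_minutes = c(0, 90, 300, 150)
  )
}

# quick calibrated config for small simulation tests (modest panel size keeps
# the calibration cheap; targets are the cohort's 43% zeros / 237 min mean)
small_config <- function(n, seed, ...) {
  calibrate_config(sim_config(n = n, seed = seed, ...), n_calib = 30000)
}
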