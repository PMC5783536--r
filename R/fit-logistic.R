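# Logistic regression for the zero process of the two-part model:
# logit(p_i) = x_i'alpha, with p_i the probability that participant i does
# any leisure-time physical activity. Fitting is iteratively reweighted least
# squares (Newton-Raphson for the canonical logit link) via stats::glm, with
# rank and separation diagnostics layered on top; the covariance is the
# inverse observed information at the optimum.

#' Fit the activity (zero-process) logistic model
#'
#' Maximum-likelihood binary logistic regression of an activity indicator on
#' a design matrix. The design must be full column rank and both classes must
#' be present; (quasi-)complete separation is reported as an error naming the
#' most suspect column, never as a silent huge estimate.
#'
#' @param x A [build_design()] object or numeric design matrix (intercept
#'   column included).
#' @param y Binary 0/1 vector (1 = any activity).
#' @return Object of class `ziglm_logistic`: coefficients, covariance
#'   (inverse observed information), log-likelihood, n, convergence flag and
#'   iteration count.
#' @export
fit_logistic <- function(x, y) {
  xm <- .as_design_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(xm)) abort("`y` length must match the design rows.")
  if (any(is.na(y)) || !all(y %in% c(0, 1))) abort("`y` must be a 0/1 vector without missing values.")
  if (all(y == 0) || all(y == 1)) abort("Both classes must be present in `y`.")
  .check_full_rank(xm)

  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm.fit(xm, y,
      family = binomial(),
      control = list(epsilon = 1e-10, maxit = 100)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  alpha <- fit$coefficients
  if (sep_warned && max(abs(alpha)) > 8) {
    worst <- names(alpha)[which.max(abs(alpha))]
    abort(paste0(
      "(Quasi-)complete separation detected: the coefficient for `", worst,
      "` diverges while the likelihood still improves. Refit without that column."
    ))
  }

  p <- fit$fitted.values
  info <- crossprod(xm * sqrt(p * (1 - p)))
  covariance <- chol2inv(chol(info))
  dimnames(covariance) <- list(names(alpha), names(alpha))
  loglik <- sum(y * log(p) + (1 - y) * log1p(-p))

  structure(
    list(
      coefficients = alpha, covariance = covariance,
      loglik = loglik, n = length(y),
      converged = fit$converged, iterations = fit$iter,
      fitted = p, x = xm, y = y
    ),
    class = "ziglm_logistic"
  )
}

.wald_table <- function(est, se, level, exponentiate) {
  z <- qnorm(1 - (1 - level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  if (exponentiate) {
    tibble::tibble(
      term = names(est), estimate = exp(unname(est)),
      conf.low = exp(unname(lo)), conf.high = exp(unname(hi))
    )
  } else {
    tibble::tibble(
      term = names(est), estimate = unname(est),
      conf.low = unname(lo), conf.high = unname(hi)
    )
  }
}

#' Odds ratios with Wald confidence intervals
#'
#' Exponentiated logistic coefficients with symmetric-on-log-scale Wald
#' intervals: `exp(alpha_j +/- z * SE_j)`.
#'
#' @param fit A [fit_logistic()] result.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `term`, `OR`, `conf.low`, `conf.high`.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ziglm_logistic"))
  if (!fit$converged) abort("Logistic fit did not converge; no odds ratios reported.")
  se <- sqrt(diag(fit$covariance))
  out <- .wald_table(fit$coefficients, se, level, exponentiate = TRUE)
  names(out)[names(out) == "estimate"] <- "OR"
  out
}

#' @export
print.ziglm_logistic <- function(x, ...) {
  cat("<ziglm logistic fit>  n =", x$n,
      " logLik =", format(x$loglik, digits = 8),
      " iterations =", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ziglm_logistic <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  se <- sqrt(diag(x$covariance))
  out <- .wald_table(x$coefficients, se, conf.level, exponentiate)
  tibble::add_column(out,
    std.error = unname(se), .after = "estimate"
  )
}

#' @exportS3Method generics::glance
glance.ziglm_logistic <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n,
    converged = x$converged, iterations = x$iterations
  )
}
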