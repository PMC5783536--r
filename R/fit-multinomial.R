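# Comparator multinomial logistic (baseline-category logit) model on the
# three-level outcome none / low (< 150 min/week) / high (>= 150 min/week),
# with physical inactivity ("none") as the reference category. Fitting is
# delegated to nnet::multinom with a tight tolerance; the covariance is the
# inverse observed information from its Hessian.

#' Fit the three-category multinomial comparator model
#'
#' Baseline-category multinomial logistic regression of the activity
#' category on the design, reference category `none`. Coefficients are a
#' 2-by-p matrix (rows `low`, `high`), each row the log odds of that category
#' versus inactivity.
#'
#' @param x A [build_design()] object or numeric design matrix.
#' @param y3 Factor (or character) of outcome categories. Characters are
#'   mapped onto the canonical `none` / `low` / `high` levels. Every declared
#'   level of a factor must be observed (an empty category is an error); the
#'   reference is `none` when present, otherwise the first level.
#' @return Object of class `ziglm_multinomial`: `coefficients` ((K-1) x p,
#'   one row per non-reference category), `covariance` ((K-1)p x (K-1)p),
#'   `loglik`, `n`, `reference`, `converged`, `fitted` (n x K probability
#'   matrix).
#' @export
fit_multinomial <- function(x, y3) {
  xm <- .as_design_matrix(x)
  if (!is.factor(y3)) y3 <- factor(y3, levels = .category_levels)
  if (any(is.na(y3))) abort("`y3` contains missing or unknown categories.")
  empty <- setdiff(levels(y3), unique(as.character(y3)))
  if (length(empty) > 0) {
    abort(paste0("Empty outcome category: ", paste(empty, collapse = ", "), "."))
  }
  if (nlevels(y3) < 2) abort("`y3` must have at least two categories.")
  if (length(y3) != nrow(xm)) abort("`y3` length must match the design rows.")
  .check_full_rank(xm)

  reference <- if ("none" %in% levels(y3)) "none" else levels(y3)[1]
  y3 <- stats::relevel(y3, ref = reference)
  other <- levels(y3)[-1]

  capture.output(fit <- withCallingHandlers(
    nnet::multinom(y3 ~ xm - 1, Hess = TRUE, maxit = 500, reltol = 1e-14, trace = FALSE),
    warning = function(w) invokeRestart("muffleWarning")
  ))
  coefs <- coef(fit)
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1)
  dimnames(coefs) <- list(other, colnames(xm))
  if (max(abs(coefs)) > 15) {
    abort("(Quasi-)complete separation detected in the multinomial fit: a coefficient diverges.")
  }
  if (fit$convergence != 0) abort("Multinomial fit did not converge.")

  covariance <- vcov(fit) # inverse observed information (nnet Hessian)
  # nnet orders parameters category-major, design-column-minor
  par_names <- paste(rep(other, each = ncol(xm)), colnames(xm), sep = ":")
  dimnames(covariance) <- list(par_names, par_names)

  probs <- fit$fitted.values
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1)
  if (ncol(probs) == 1) probs <- cbind(1 - probs[, 1], probs[, 1])
  colnames(probs) <- levels(y3)
  structure(
    list(
      coefficients = coefs, covariance = covariance,
      loglik = as.numeric(logLik(fit)), n = length(y3),
      reference = reference, converged = TRUE,
      fitted = probs, x = xm, y3 = y3
    ),
    class = "ziglm_multinomial"
  )
}

#' Category-specific odds ratios from the multinomial model
#'
#' For each non-reference category (`low`, `high`) the exponentiated
#' coefficients are adjusted odds ratios of being in that category versus
#' doing no physical activity, with Wald intervals.
#'
#' @param fit A [fit_multinomial()] result.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `category`, `term`, `OR`, `conf.low`, `conf.high`.
#' @export
odds_ratios_multinomial <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ziglm_multinomial"))
  if (!fit$converged) abort("Multinomial fit did not converge; no odds ratios reported.")
  se_all <- sqrt(diag(fit$covariance))
  purrr::map_dfr(rownames(fit$coefficients), function(cat) {
    est <- stats::setNames(fit$coefficients[cat, ], colnames(fit$coefficients))
    se <- se_all[paste(cat, names(est), sep = ":")]
    out <- .wald_table(est, stats::setNames(se, names(est)), level, exponentiate = TRUE)
    names(out)[names(out) == "estimate"] <- "OR"
    tibble::add_column(out, category = cat, .before = "term")
  })
}

#' @export
print.ziglm_multinomial <- function(x, ...) {
  cat("<ziglm multinomial fit>  n =", x$n,
      " reference =", x$reference,
      " logLik =", format(x$loglik, digits = 8), "\n")
  print(odds_ratios_multinomial(x), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ziglm_multinomial <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  se_all <- sqrt(diag(x$covariance))
  purrr::map_dfr(rownames(x$coefficients), function(cat) {
    est <- stats::setNames(x$coefficients[cat, ], colnames(x$coefficients))
    se <- stats::setNames(se_all[paste(cat, names(est), sep = ":")], names(est))
    out <- .wald_table(est, se, conf.level, exponentiate)
    out <- tibble::add_column(out, std.error = unname(se), .after = "estimate")
    tibble::add_column(out, y.level = cat, .before = "term")
  })
}

#' @exportS3Method generics::glance
glance.ziglm_multinomial <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n,
    reference = x$reference, converged = x$converged
  )
}
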