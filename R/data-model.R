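# Participant records, covariate recoding and design-matrix construction.
#
# One row of data is a participant: gender, age in years, one of four ordered
# education levels, annual per-capita family income in US$, and the outcome —
# total weekly minutes of leisure-time physical activity (LTPA), with exact 0
# meaning no activity at all.

.gender_levels <- c("female", "male")
.education_levels <- c("basic", "high_school", "college", "graduate")
.category_levels <- c("none", "low", "high")

#' Weekly leisure-time activity minutes from days and duration
#'
#' Converts questionnaire answers — how many days per week an activity was
#' done and for how many minutes per day — to total weekly minutes, the
#' semicontinuous outcome modelled throughout the package.
#'
#' @param days_per_week Integer-valued vector, 0 to 7.
#' @param minutes_per_day Non-negative numeric vector, minutes per session.
#' @return Numeric vector of minutes per week (`days_per_week *
#'   minutes_per_day`).
#' @examples
#' weekly_minutes(3, 30)   # 90
#' weekly_minutes(0, 45)   # 0: no active days means no weekly activity
#' @export
weekly_minutes <- function(days_per_week, minutes_per_day) {
  if (any(is.na(days_per_week)) || any(is.na(minutes_per_day))) {
    abort("`days_per_week` and `minutes_per_day` must not contain missing values.")
  }
  if (any(days_per_week < 0) || any(days_per_week > 7)) {
    abort("`days_per_week` must lie in 0..7.")
  }
  if (any(days_per_week != round(days_per_week))) {
    abort("`days_per_week` must be whole numbers of days.")
  }
  if (any(minutes_per_day < 0)) {
    abort("`minutes_per_day` must be non-negative.")
  }
  as.numeric(days_per_week) * as.numeric(minutes_per_day)
}

#' Three-level activity category for the multinomial comparator
#'
#' Categorises weekly minutes as `none` (exactly 0), `low` (positive but
#' below 150 minutes/week) or `high` (at or above the 150 minutes/week
#' guideline threshold, boundary inclusive).
#'
#' @param y_minutes Non-negative numeric vector of weekly minutes.
#' @return Factor with levels `none`, `low`, `high` (reference first).
#' @examples
#' categorize_activity(c(0, 149.9, 150))
#' @export
categorize_activity <- function(y_minutes) {
  if (any(is.na(y_minutes))) abort("`y_minutes` must not contain missing values.")
  if (any(y_minutes < 0)) abort("`y_minutes` must be non-negative.")
  factor(
    ifelse(y_minutes == 0, "none", ifelse(y_minutes < 150, "low", "high")),
    levels = .category_levels
  )
}

#' Covariate-to-design mapping used by every model component
#'
#' Declares how raw covariates become design-matrix columns: reference levels
#' (female, basic education) are dropped, age is rescaled to decades and
#' income to US$1,000 units, so fitted coefficients read "per 10 years" and
#' "per US$1,000".
#'
#' @param terms Character vector of covariates, in column order. Any subset of
#'   `c("gender", "education", "age", "income")`.
#' @return An object of class `ziglm_design_spec`.
#' @export
design_spec <- function(terms = c("gender", "education", "age", "income")) {
  known <- c("gender", "education", "age", "income")
  bad <- setdiff(terms, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown design terms: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      terms = terms,
      reference_levels = c(gender = "female", education = "basic"),
      scalings = c(age = 10, income = 1000)
    ),
    class = "ziglm_design_spec"
  )
}

#' @export
print.ziglm_design_spec <- function(x, ...) {
  cat("<ziglm design spec>\n")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat("  references: gender = female, education = basic\n")
  cat("  scalings: age / 10 (decades), income / 1000 (US$1,000)\n")
  invisible(x)
}

.canon_category <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    abort(paste0(
      "Unknown ", what, " value(s): ",
      paste(unique(x[bad]), collapse = ", "),
      ". Expected one of: ", paste(levels, collapse = ", "), "."
    ))
  }
  factor(x, levels = levels)
}

.design_columns <- function(spec) {
  cols <- "intercept"
  for (term in spec$terms) {
    cols <- c(cols, switch(term,
      gender = "male",
      education = c("high_school", "college", "graduate"),
      age = "age_decades",
      income = "income_k"
    ))
  }
  cols
}

#' Build the model design matrix from participant records
#'
#' Applies the recoding declared in a [design_spec()]: intercept column of
#' ones, dummy columns for male and for each non-reference education level,
#' age in decades and income in US$1,000. Rows with a missing value on any
#' used term are dropped (complete-case analysis) and counted.
#'
#' @param data Data frame with columns `gender`, `age_years`, `education`,
#'   `income_usd` as needed by `spec` (case-insensitive category spellings).
#' @param spec A [design_spec()].
#' @return Object of class `ziglm_design`: list with `x` (the n-by-p numeric
#'   matrix), `columns`, `n`, `n_dropped`, `kept` (logical row filter on the
#'   input) and `data` (the kept rows, categories canonicalised).
#' @examples
#' d <- tibble::tibble(
#'   gender = c("male", "Female"), age_years = c(35, 50),
#'   education = c("graduate", "basic"), income_usd = c(12000, 5000)
#' )
#' build_design(d, design_spec())$x
#' @export
build_design <- function(data, spec = design_spec()) {
  stopifnot(inherits(spec, "ziglm_design_spec"))
  data <- tibble::as_tibble(data)

  needed <- c(
    gender = "gender", education = "education",
    age = "age_years", income = "income_usd"
  )[spec$terms]
  missing_cols <- setdiff(unname(needed), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }

  if ("gender" %in% spec$terms) {
    data$gender <- .canon_category(data$gender, .gender_levels, "gender")
  }
  if ("education" %in% spec$terms) {
    data$education <- .canon_category(data$education, .education_levels, "education")
  }

  kept <- stats::complete.cases(data[, unname(needed), drop = FALSE])
  used <- data[kept, , drop = FALSE]
  n <- nrow(used)

  cols <- .design_columns(spec)
  x <- matrix(0, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  x[, "intercept"] <- 1
  for (term in spec$terms) {
    switch(term,
      gender = {
        x[, "male"] <- as.numeric(used$gender == "male")
      },
      education = {
        for (lev in c("high_school", "college", "graduate")) {
          x[, lev] <- as.numeric(used$education == lev)
        }
      },
      age = {
        x[, "age_decades"] <- used$age_years / spec$scalings[["age"]]
      },
      income = {
        if (any(used$income_usd < 0)) abort("`income_usd` must be non-negative.")
        x[, "income_k"] <- used$income_usd / spec$scalings[["income"]]
      }
    )
  }

  structure(
    list(
      x = x, columns = cols, n = n, n_dropped = sum(!kept),
      kept = kept, data = used, spec = spec
    ),
    class = "ziglm_design"
  )
}

#' @export
print.ziglm_design <- function(x, ...) {
  cat("<ziglm design matrix>\n")
  cat("  n =", x$n, "rows (", x$n_dropped, "dropped as incomplete )\n")
  cat("  columns:", paste(x$columns, collapse = ", "), "\n")
  invisible(x)
}

# Accept either a ziglm_design or a bare numeric matrix in the fitters.
.as_design_matrix <- function(x) {
  if (inherits(x, "ziglm_design")) {
    return(x$x)
  }
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("Design must be numeric.")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

.check_full_rank <- function(x, what = "design") {
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(paste0(
      "The ", what, " matrix is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Read participant records from CSV
#'
#' Reads the flat per-participant table: columns `id`, `gender`, `age_years`,
#' `education`, `income_usd`, `weekly_minutes`; UTF-8, `.` decimal separator,
#' empty cells as missing. Category spellings are case-insensitive and are
#' canonicalised to lower-case.
#'
#' @param path Path to a CSV file.
#' @return A tibble of participant records.
#' @export
read_activity_csv <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      gender = readr::col_character(),
      age_years = readr::col_double(),
      education = readr::col_character(),
      income_usd = readr::col_double(),
      weekly_minutes = readr::col_double()
    ),
    na = c("", "NA")
  )
  required <- c("id", "gender", "age_years", "education", "income_usd", "weekly_minutes")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("CSV is missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data$gender <- .canon_category(data$gender, .gender_levels, "gender")
  data$education <- .canon_category(data$education, .education_levels, "education")
  if (any(data$weekly_minutes < 0, na.rm = TRUE)) {
    abort("`weekly_minutes` must be non-negative.")
  }
  data
}

#' Write participant records (and simulation metadata) to CSV
#'
#' Writes the same CSV dialect [read_activity_csv()] reads. When `data` came
#' from [simulate_zig()] its generator metadata (true parameters, seed) is
#' written to a plain-text key-value sidecar file.
#'
#' @param data Tibble of participant records.
#' @param path Output CSV path.
#' @param metadata_path Optional path for the sidecar; defaults to
#'   `<path>.meta.txt` when `data` carries simulation metadata.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(data, path, metadata_path = NULL) {
  readr::write_csv(data, path)
  meta <- attr(data, "ziglm_meta")
  if (!is.null(meta)) {
    metadata_path <- metadata_path %||% paste0(path, ".meta.txt")
    lines <- unlist(lapply(names(meta), function(k) {
      v <- meta[[k]]
      paste0(k, ": ", paste(format(v, digits = 10), collapse = " "))
    }))
    writeLines(lines, metadata_path)
  }
  invisible(path)
}
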