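#' Univariate linear fit of an outcome on a single predictor
#'
#' Ordinary least squares of `outcome ~ predictor` with the bivariate
#' Pearson correlation, standardized slope and two-sided p-value (t
#' distribution with n - 2 degrees of freedom). Rows with missing values
#' in either variable are dropped listwise.
#'
#' @param data Data frame holding the variables.
#' @param outcome,predictor Column names (strings).
#' @return A one-row tibble: `outcome`, `term`, `beta`, `se`, `std_beta`,
#'   `t`, `p`, `r`, `r2`, `df_resid`, `n`.
#' @export
univariate_fit <- function(data, outcome, predictor) {
  df <- regression_frame(data, c(outcome, predictor))
  y <- df[[outcome]]
  x <- df[[predictor]]
  n <- length(y)
  if (n < 3) stop("at least 3 complete observations are required", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop(sprintf("predictor `%s` is constant", predictor), call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)["x"])
  se <- sm$coefficients["x", "Std. Error"]
  tval <- sm$coefficients["x", "t value"]
  p <- sm$coefficients["x", "Pr(>|t|)"]
  r <- stats::cor(x, y)
  tibble::tibble(
    outcome = outcome, term = predictor,
    beta = beta, se = se,
    std_beta = beta * stats::sd(x) / stats::sd(y),
    t = tval, p = p,
    r = r, r2 = r^2,
    df_resid = fit$df.residual, n = n
  )
}

#' Covariate-adjusted multiple linear regression
#'
#' Fits `outcome ~ predictors + covariates` by OLS (intercept always
#' included, never reported) and returns one row per non-intercept term
#' with the unstandardized coefficient, its standard error, the
#' standardized coefficient `beta * sd(term) / sd(outcome)` (sample SDs,
#' n - 1 denominator), the t statistic and two-sided p-value, and the
#' model R^2. Rows with any missing value are dropped listwise; a
#' rank-deficient design is an error naming the collinear terms.
#'
#' @param data Data frame holding the variables.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param covariates Character vector of adjustment covariates; default
#'   sex and years of education.
#' @return A tibble with one row per term: `outcome`, `term`, `beta`,
#'   `se`, `std_beta`, `t`, `p`, `r2`, `df_resid`, `n`.
#' @export
multiple_regression <- function(data, outcome, predictors,
                                covariates = c("sex", "education")) {
  terms <- unique(c(predictors, covariates))
  df <- regression_frame(data, c(outcome, terms))
  n <- nrow(df)
  if (n <= length(terms) + 1) {
    stop("too few complete observations for the number of model terms", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(df[terms]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop("rank-deficient design; collinear terms: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(terms, response = outcome)
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  rows <- setdiff(rownames(co), "(Intercept)")
  sdy <- stats::sd(df[[outcome]])
  purrr::map_dfr(rows, function(tm) {
    tibble::tibble(
      outcome = outcome, term = tm,
      beta = co[tm, "Estimate"], se = co[tm, "Std. Error"],
      std_beta = co[tm, "Estimate"] * stats::sd(df[[tm]]) / sdy,
      t = co[tm, "t value"], p = co[tm, "Pr(>|t|)"],
      r2 = sm$r.squared, df_resid = fit$df.residual, n = n
    )
  })
}

# Listwise-complete numeric frame over the named columns, with a message
# when rows are dropped.
regression_frame <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("variables not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- data[cols]
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    message(sprintf("dropped %d incomplete row(s) (listwise deletion)", sum(!keep)))
  }
  df <- df[keep, , drop = FALSE]
  for (cl in cols) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("variable `%s` must be numeric", cl), call. = FALSE)
    }
  }
  df
}

#' Bonferroni-corrected per-test threshold
#'
#' Divides the family-wise alpha level by the number of tests. With the
#' analysis family of four resting-state networks plus three global
#' connectivity measures (m = 7) and alpha = 0.05, the threshold is
#' 0.05 / 7, reported as 0.007 when rounded to three decimals in output
#' tables.
#'
#' @param alpha Family-wise error level, in (0, 1).
#' @param m Number of tests (>= 1).
#' @return The per-test threshold `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("`m` must be a positive count", call. = FALSE)
  }
  alpha / m
}
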