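#' Specify a parallel-mediator mediation model
#'
#' Defines the exposure, the mediators operating in parallel (all entered
#' jointly in the outcome equation, so each indirect effect is estimated
#' adjusting for the others), the outcome and optional covariates.
#'
#' @param exposure Exposure variable name (e.g. `"age"`).
#' @param mediators Character vector of mediator names.
#' @param outcome Outcome variable name.
#' @param covariates Character vector of covariates entered in every
#'   equation (default none).
#' @param a_paths_adjust If `TRUE`, each mediator's a-path equation also
#'   adjusts for the other mediators (an alternative reading of
#'   "each mediator was a covariate for the others"); the default
#'   standard parallel model regresses each mediator on the exposure
#'   (+ covariates) only. Note the effect-decomposition identity
#'   `total = direct + sum(indirect)` is exact only in the default mode.
#' @return A `mediation_model` list.
#' @export
mediation_model <- function(exposure, mediators, outcome,
                            covariates = character(),
                            a_paths_adjust = FALSE) {
  stopifnot(is.character(exposure), length(exposure) == 1,
            is.character(mediators), length(mediators) >= 1,
            is.character(outcome), length(outcome) == 1)
  if (exposure %in% mediators) {
    stop("the exposure cannot also be a mediator", call. = FALSE)
  }
  if (outcome %in% c(mediators, exposure)) {
    stop("the outcome cannot also be the exposure or a mediator", call. = FALSE)
  }
  structure(list(exposure = exposure, mediators = mediators,
                 outcome = outcome, covariates = covariates,
                 a_paths_adjust = a_paths_adjust),
            class = "mediation_model")
}

# Closed-form OLS coefficients (single solve; X assumed full rank).
ols_coef <- function(X, Y) {
  solve(crossprod(X), crossprod(X, Y))
}

# Point estimates of all mediation effects on a numeric matrix V whose
# columns are (exposure, mediators..., outcome, covariates...). Returns a
# named vector: total, direct, indirect_<m>..., and the a/b paths.
mediation_point <- function(V, model) {
  x <- V[, model$exposure]
  M <- V[, model$mediators, drop = FALSE]
  y <- V[, model$outcome]
  Z <- if (length(model$covariates)) V[, model$covariates, drop = FALSE] else NULL
  base <- if (is.null(Z)) cbind(1, x) else cbind(1, x, Z)

  total <- unname(ols_coef(base, y)[2, 1])

  if (model$a_paths_adjust && length(model$mediators) > 1) {
    a <- vapply(seq_along(model$mediators), function(j) {
      others <- M[, -j, drop = FALSE]
      Xa <- cbind(base, others)
      unname(ols_coef(Xa, M[, j])[2, 1])
    }, numeric(1))
  } else {
    a <- ols_coef(base, M)[2, , drop = TRUE]
  }

  Xy <- cbind(base, M)
  cy <- ols_coef(Xy, y)
  direct <- unname(cy[2, 1])
  b <- cy[seq(ncol(base) + 1, ncol(Xy)), 1]
  indirect <- unname(a) * unname(b)

  c(total = total, direct = direct,
    stats::setNames(indirect, paste0("indirect_", model$mediators)),
    total_indirect = sum(indirect),
    stats::setNames(unname(a), paste0("a_", model$mediators)),
    stats::setNames(unname(b), paste0("b_", model$mediators)))
}

mediation_frame <- function(data, model) {
  vars <- c(model$exposure, model$mediators, model$outcome, model$covariates)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    stop("missing model variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- regression_frame(data, vars)
  if (nrow(df) <= length(vars) + 2) {
    stop("too few complete observations for the mediation model", call. = FALSE)
  }
  V <- as.matrix(df)
  qr_rank <- qr(cbind(1, V))$rank
  if (qr_rank < ncol(V) + 1) {
    stop("rank-deficient mediation design (collinear variables)", call. = FALSE)
  }
  V
}

effects_table <- function(est, model, sds) {
  eff <- c("total", "direct", paste0("indirect_", model$mediators), "total_indirect")
  mediator <- c(NA_character_, NA_character_, model$mediators, NA_character_)
  scale_xy <- sds[model$exposure] / sds[model$outcome]
  tibble::tibble(
    effect = c("total", "direct", rep("indirect", length(model$mediators)),
               "total_indirect"),
    mediator = mediator,
    estimate = unname(est[eff]),
    std_estimate = unname(est[eff]) * scale_xy
  )
}

#' Fit mediation path models (point estimates)
#'
#' Estimates all paths of a parallel-mediator model by OLS: each a-path
#' from regressing the mediator on the exposure (+ covariates); the
#' b-paths and the direct effect c' from regressing the outcome on the
#' exposure and all mediators jointly (+ covariates); the total effect c
#' from regressing the outcome on the exposure (+ covariates). Each
#' indirect effect is `a_j * b_j`, and for the standard parallel model
#' the decomposition `total = direct + sum(indirect)` is an exact OLS
#' identity. Standardized effects are the unstandardized effects scaled
#' by `sd(exposure) / sd(outcome)` (and the paths by the corresponding
#' variable SDs).
#'
#' @param data Data frame holding all model variables.
#' @param model A [mediation_model()].
#' @return A `mediation_fit` object; its `effects` tibble has columns
#'   `effect`, `mediator`, `estimate`, `std_estimate`, and `paths` holds
#'   the per-mediator a/b coefficients.
#' @export
fit_paths <- function(data, model) {
  stopifnot(inherits(model, "mediation_model"))
  V <- mediation_frame(data, model)
  n <- nrow(V)
  n_terms <- 1 + length(model$mediators) + length(model$covariates)
  if (n <= n_terms + 2) {
    stop("too few complete observations for the mediation model", call. = FALSE)
  }
  est <- mediation_point(V, model)
  sds <- apply(V, 2, stats::sd)
  paths <- tibble::tibble(
    mediator = model$mediators,
    a = unname(est[paste0("a_", model$mediators)]),
    b = unname(est[paste0("b_", model$mediators)]),
    a_std = unname(est[paste0("a_", model$mediators)]) *
      sds[model$exposure] / sds[model$mediators],
    b_std = unname(est[paste0("b_", model$mediators)]) *
      sds[model$mediators] / sds[model$outcome]
  )
  structure(list(
    effects = effects_table(est, model, sds),
    paths = paths,
    model = model, n = n, n_boot = 0L
  ), class = "mediation_fit")
}

#' Bootstrap inference for mediation effects
#'
#' Non-parametric case resampling of subjects with replacement: the full
#' path model is refitted on each resample, giving bootstrap standard
#' errors, percentile (default) or bias-corrected confidence intervals,
#' and a two-sided bootstrap p-value
#' `2 * min(fraction of resampled estimates <= 0, >= 0)` for every
#' effect. Resamples with a constant exposure are redrawn (and counted
#' in a message). Deterministic given `seed`.
#'
#' @param data Data frame holding all model variables (n >= 10).
#' @param model A [mediation_model()].
#' @param n_boot Number of bootstrap iterations (default 10000; fewer
#'   than 100 triggers a warning).
#' @param seed Integer seed.
#' @param ci_level Confidence level (default 0.95).
#' @param ci_type `"percentile"` (default) or `"bc"` (bias-corrected).
#' @return A `mediation_fit` whose `effects` tibble gains `se`,
#'   `ci_low`, `ci_high` and `p` columns; the bootstrap draws are kept in
#'   `$boot` (iterations x effects).
#' @export
bootstrap_mediation <- function(data, model, n_boot = 10000, seed = 1,
                                ci_level = 0.95,
                                ci_type = c("percentile", "bc")) {
  ci_type <- match.arg(ci_type)
  if (n_boot < 100) {
    warning("fewer than 100 bootstrap iterations give unstable intervals",
            call. = FALSE)
  }
  fit <- fit_paths(data, model)
  V <- mediation_frame(data, model)
  n <- nrow(V)
  if (n < 10) stop("at least 10 observations are required", call. = FALSE)

  eff_names <- c("total", "direct", paste0("indirect_", model$mediators),
                 "total_indirect")
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(eff_names),
                 dimnames = list(NULL, eff_names))
  x_col <- model$exposure
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Vb <- V[idx, , drop = FALSE]
      if (stats::sd(Vb[, x_col]) > 0) break
      redraws <- redraws + 1L
      if (redraws > 1000L) stop("exposure degenerate in repeated resamples",
                                call. = FALSE)
    }
    est_b <- tryCatch(mediation_point(Vb, model), error = function(e) NULL)
    if (is.null(est_b)) {
      boot[b, ] <- NA_real_
    } else {
      boot[b, ] <- est_b[eff_names]
    }
  }
  if (redraws > 0) message(sprintf("redrew %d degenerate resample(s)", redraws))
  ok <- stats::complete.cases(boot)
  bmat <- boot[ok, , drop = FALSE]

  alpha <- 1 - ci_level
  point <- stats::setNames(fit$effects$estimate, eff_names)
  ci <- vapply(eff_names, function(e) {
    v <- bmat[, e]
    if (ci_type == "percentile") {
      stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    } else {
      z0 <- stats::qnorm(mean(v < point[e]))
      zc <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
      stats::quantile(v, stats::pnorm(2 * z0 + zc), names = FALSE, type = 7)
    }
  }, numeric(2))
  pvals <- vapply(eff_names, function(e) {
    v <- bmat[, e]
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  }, numeric(1))

  fit$effects$se <- unname(apply(bmat, 2, stats::sd))
  fit$effects$ci_low <- unname(ci[1, ])
  fit$effects$ci_high <- unname(ci[2, ])
  fit$effects$p <- unname(pvals)
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- seed
  fit$ci_level <- ci_level
  fit$ci_type <- ci_type
  fit$boot <- boot
  fit
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Parallel-mediator mediation fit: %s -> {%s} -> %s (n = %d%s)\n",
              x$model$exposure, paste(x$model$mediators, collapse = ", "),
              x$model$outcome, x$n,
              if (x$n_boot > 0) sprintf(", %d bootstrap draws", x$n_boot) else ""))
  print(x$effects)
  invisible(x)
}

#' Tidy a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return The effects tibble (one row per total/direct/indirect effect,
#'   with bootstrap columns when present).
#' @export
tidy.mediation_fit <- function(x, ...) x$effects

#' Glance at a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the sample size, bootstrap count and the
#'   total/direct/total-indirect estimates.
#' @export
glance.mediation_fit <- function(x, ...) {
  est <- stats::setNames(x$effects$estimate, make.unique(x$effects$effect))
  tibble::tibble(
    n = x$n, n_boot = x$n_boot,
    n_mediators = length(x$model$mediators),
    total = unname(est["total"]),
    direct = unname(est["direct"]),
    total_indirect = unname(x$effects$estimate[x$effects$effect == "total_indirect"])
  )
}
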