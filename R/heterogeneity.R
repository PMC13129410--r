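# Derived summaries: multilevel I2, prediction intervals, marginal R2, and
# the small-study-effects (funnel-asymmetry) meta-regression.

#' Typical sampling variance
#'
#' The "typical" within-effect variance used by multilevel I2:
#' `vbar = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))` with `w = 1/v`. Uses the
#' diagonal variances only (off-diagonal sampling covariances are ignored by
#' convention). Always lies within `[min(v), max(v)]`.
#'
#' @param v Per-effect sampling variances (k >= 2, all > 0).
#' @export
typical_sampling_variance <- function(v) {
  if (any(v <= 0)) stop("all sampling variances must be > 0")
  if (length(v) < 2) stop("need at least 2 effects")
  w <- 1 / v
  (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Multilevel I-squared decomposition
#'
#' Relative heterogeneity per random level and in total:
#' `I2_level = 100 * sigma2_level / (sum(sigma2) + vbar)`; the level shares
#' sum exactly to `I2_total`. In the homogeneous two-level case this reduces
#' to the classical `I2 = 100 * tau2 / (tau2 + vbar)`.
#'
#' @param fit A converged `badge_fit`.
#' @param vbar Typical sampling variance; computed from the fit's variances
#'   by default.
#' @return List with `i2_by_level` (named percent vector), `i2_total`,
#'   `sigma2_total` and `vbar`.
#' @export
i2_multilevel <- function(fit, vbar = NULL) {
  stopifnot(inherits(fit, "badge_fit"))
  if (is.null(vbar)) vbar <- typical_sampling_variance(fit$v)
  s2 <- fit$sigma2[!is.na(fit$sigma2)]
  tot <- sum(s2)
  i2 <- 100 * s2 / (tot + vbar)
  list(i2_by_level = i2, i2_total = 100 * tot / (tot + vbar),
       sigma2_total = tot, vbar = vbar)
}

#' Prediction interval for a new effect
#'
#' `beta +/- crit * sqrt(se^2 + sum(sigma2))`: the likely range for the true
#' effect in a new study, widening with total heterogeneity. Requires an
#' intercept-only fit. Always contains the confidence interval.
#'
#' @param fit An intercept-only `badge_fit`.
#' @param level Coverage level.
#' @return Numeric `c(lower, upper)`.
#' @export
prediction_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "badge_fit"))
  if (ncol(fit$X) != 1 || any(fit$X != 1)) {
    stop("prediction intervals are defined for the intercept-only model")
  }
  alpha <- 1 - level
  crit <- if (fit$inference == "z") stats::qnorm(1 - alpha / 2) else
    stats::qt(1 - alpha / 2, fit$k - 1)
  s2 <- sum(fit$sigma2, na.rm = TRUE)
  half <- crit * sqrt(fit$se[1]^2 + s2)
  unname(c(fit$beta[1] - half, fit$beta[1] + half))
}

#' Marginal R-squared of a meta-regression
#'
#' Percentage of total variance explained by the fixed-effect moderators:
#' `100 * var(X beta) / (var(X beta) + sum(sigma2))`, the mixed-model
#' marginal R2 on the meta-analytic scale.
#'
#' @param fit A `badge_fit` with at least one non-intercept fixed effect.
#' @return Percent in [0, 100].
#' @export
r2_marginal <- function(fit) {
  stopifnot(inherits(fit, "badge_fit"))
  if (ncol(fit$X) == 1 && all(fit$X == 1)) stop("no moderator")
  sf <- stats::var(drop(fit$X %*% fit$beta))
  100 * sf / (sf + sum(fit$sigma2, na.rm = TRUE))
}

#' Small-study-effects (funnel asymmetry) meta-regression
#'
#' Fits the full phylogenetic multilevel meta-regression with a precision
#' moderator. The slope measures funnel asymmetry; the intercept is the
#' meta-analytic mean extrapolated to infinite precision, i.e., the mean
#' adjusted for small-study effects. Moderator kinds:
#' \describe{
#'   \item{`inv_sqrt_n_eff`}{`sqrt(1/n_eff)` with effective sample size
#'     `n_eff = 4*n1*n2/(n1+n2)` for two-group effects and `n` otherwise
#'     (already computed by [convert_effects()]).}
#'   \item{`se_of_r`}{the effect's standard error `sqrt(v)`.}
#'   \item{`se_of_z`}{the standard error of Fisher's z, `1/sqrt(n_eff - 3)`.}
#' }
#'
#' @param dataset A [meta_dataset()] whose effects carry `n_eff` (for the
#'   sample-size kinds).
#' @param kind Moderator variant; the two SE variants are provided because
#'   published runs label the asymmetry slope either way, and the choice is
#'   recorded in the result.
#' @param level Confidence level.
#' @param ... Passed to [reml_fit()].
#' @return Object of class `small_study_result`: `slope`, `slope_ci`,
#'   `slope_p`, `adjusted_mean`, `adjusted_ci`, `adjusted_p`, `r2_marginal`,
#'   `kind` and the underlying `fit`.
#' @export
small_study_test <- function(dataset, kind = c("inv_sqrt_n_eff", "se_of_r", "se_of_z"),
                             level = 0.95, ...) {
  stopifnot(inherits(dataset, "meta_dataset"))
  kind <- match.arg(kind)
  eff <- dataset$effects
  mod <- switch(kind,
    inv_sqrt_n_eff = {
      if (is.null(eff$n_eff) || anyNA(eff$n_eff)) {
        stop("effects must carry a complete n_eff column for kind = 'inv_sqrt_n_eff'")
      }
      sqrt(1 / eff$n_eff)
    },
    se_of_r = sqrt(eff$v),
    se_of_z = {
      if (is.null(eff$n_eff) || anyNA(eff$n_eff)) {
        stop("effects must carry a complete n_eff column for kind = 'se_of_z'")
      }
      if (any(eff$n_eff <= 3)) stop("n_eff must exceed 3 for kind = 'se_of_z'")
      1 / sqrt(eff$n_eff - 3)
    })
  if (stats::var(mod) == 0) stop("precision moderator is constant")
  dataset$effects$.precision <- mod
  fit <- reml_fit(dataset, moderator = ".precision", ...)
  tab <- wald_inference(fit, level = level)
  structure(list(
    kind = kind,
    slope = tab$estimate[2], slope_ci = c(tab$ci_lb[2], tab$ci_ub[2]),
    slope_p = tab$pval[2],
    adjusted_mean = tab$estimate[1],
    adjusted_ci = c(tab$ci_lb[1], tab$ci_ub[1]),
    adjusted_p = tab$pval[1],
    r2_marginal = r2_marginal(fit),
    fit = fit
  ), class = "small_study_result")
}

#' @export
print.small_study_result <- function(x, digits = 3, ...) {
  cat("Small-study effects meta-regression (moderator:", x$kind, ")\n")
  cat(sprintf("  slope = %.*f, 95%% CI [%.*f, %.*f], p = %.4f\n",
              digits, x$slope, digits, x$slope_ci[1], digits, x$slope_ci[2],
              x$slope_p))
  cat(sprintf("  adjusted mean = %.*f, 95%% CI [%.*f, %.*f], p = %.4f\n",
              digits, x$adjusted_mean, digits, x$adjusted_ci[1], digits,
              x$adjusted_ci[2], x$adjusted_p))
  cat(sprintf("  R2_marginal = %.2f%%\n", x$r2_marginal))
  invisible(x)
}
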