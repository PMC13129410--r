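# Conversion of reported summary statistics to correlation-scale effect sizes.
#
# All effects end up on the r scale ("r" covering both Pearson r and the
# biserial r_bis). Biserial estimates may legitimately exceed |1| in finite
# samples and are propagated unclipped.

ORIGINS <- c("pearson_r", "means_sd_n", "t_value", "F_value", "chi2_value")
DIRECTIONS <- c("positive", "negative", "unknown")

#' Standardized mean difference between a dark and a light group
#'
#' Computes Cohen-type d from group means, standard deviations and sample
#' sizes. Two variants are provided: `"fixed"` uses the correctly bracketed
#' pooled standard deviation; `"buggy"` reproduces a parentheses-missing
#' denominator in which only the dark-group sum of squares is divided by the
#' pooled degrees of freedom, i.e. `sqrt((nL-1)*sdL^2 + (nD-1)*sdD^2/(nL+nD-2))`.
#' The buggy denominator is never smaller than the correct one, so the buggy
#' |d| is systematically shrunk; the variant exists to audit datasets built
#' with the erroneous code.
#'
#' @param mean_dark,mean_light Group means (trait units).
#' @param sd_dark,sd_light Group standard deviations, both > 0.
#' @param n_dark,n_light Group sample sizes, both >= 2.
#' @param variant `"fixed"` (correct pooling) or `"buggy"`.
#' @return Numeric standardized difference d (dark minus light).
#' @examples
#' std_mean_diff(2.40, 0.80, 10, 2.25, 0.75, 10)
#' std_mean_diff(2.40, 0.80, 10, 2.25, 0.75, 10, variant = "buggy")
#' @export
std_mean_diff <- function(mean_dark, sd_dark, n_dark, mean_light, sd_light,
                          n_light, variant = c("fixed", "buggy")) {
  variant <- match.arg(variant)
  stopifnot(sd_dark > 0, sd_light > 0, n_dark >= 2, n_light >= 2,
            n_dark + n_light >= 4)
  ss <- (n_light - 1) * sd_light^2 + (n_dark - 1) * sd_dark^2
  if (any(ss == 0)) stop("degenerate groups: zero pooled variance")
  denom <- if (variant == "fixed") {
    sqrt(ss / (n_light + n_dark - 2))
  } else {
    sqrt((n_light - 1) * sd_light^2 +
           (n_dark - 1) * sd_dark^2 / (n_light + n_dark - 2))
  }
  (mean_dark - mean_light) / denom
}

#' Biserial correlation from two-group summary statistics
#'
#' Converts group means/SDs/ns to the biserial correlation via the chain
#' d -> point-biserial -> biserial: `r_pb = d / sqrt(d^2 + h)` followed by
#' `r_bis = r_pb * sqrt(p*q) / dnorm(qnorm(p))`, with `p = n_dark / n` the
#' dark-group proportion. By default `h = 1/(p*q)` (the asymptotic
#' denominator); with `small_sample = TRUE`, `h = m/n_dark + m/n_light`
#' (`m = n - 2`), the small-sample denominator used by
#' `metafor::escalc(measure = "RBIS")`, which this option reproduces exactly.
#'
#' The sampling variance is Soper's large-sample variance of the biserial
#' correlation (the same convention as `escalc(measure = "RBIS")`):
#' `v = (p*q/phi^2 - (3/2 + (1 - p*z/phi)*(1 + q*z/phi))*rt^2 + rt^4) / (n-1)`
#' with `z = qnorm(p, lower.tail = FALSE)`, `phi = dnorm(z)` and `rt` the
#' estimate truncated to [-1, 1] for the variance computation only.
#'
#' @inheritParams std_mean_diff
#' @param small_sample Use the small-sample point-biserial denominator.
#' @return List with elements `r` (biserial, may exceed |1|), `v` (sampling
#'   variance) and `d` (the intermediate standardized difference).
#' @export
rbis_from_groups <- function(mean_dark, sd_dark, n_dark, mean_light, sd_light,
                             n_light, variant = c("fixed", "buggy"),
                             small_sample = FALSE) {
  variant <- match.arg(variant)
  n <- n_dark + n_light
  p <- n_dark / n
  if (p <= 0 || p >= 1) stop("one empty group")
  q <- 1 - p
  d <- std_mean_diff(mean_dark, sd_dark, n_dark, mean_light, sd_light,
                     n_light, variant = variant)
  h <- if (small_sample) (n - 2) / n_dark + (n - 2) / n_light else 1 / (p * q)
  r_pb <- d / sqrt(d^2 + h)
  z <- stats::qnorm(p, lower.tail = FALSE)
  fz <- stats::dnorm(z)
  r <- sqrt(p * q) / fz * r_pb
  rt <- pmin(1, pmax(-1, r))
  v <- (p * q / fz^2 -
          (3 / 2 + (1 - p * z / fz) * (1 + q * z / fz)) * rt^2 + rt^4) / (n - 1)
  list(r = r, v = v, d = d)
}

#' Correlation from a t statistic
#'
#' `r = t / sqrt(t^2 + df)`; the sign of t is carried. The sampling variance
#' is the large-sample `(1 - r^2)^2 / (n - 1)` with `n = df + 2` unless
#' `n_total` is supplied.
#'
#' @param t t statistic.
#' @param df Degrees of freedom (>= 1).
#' @param n_total Optional total sample size overriding `df + 2`.
#' @return List with `r` and `v`.
#' @export
r_from_t <- function(t, df, n_total = NULL) {
  stopifnot(df >= 1)
  r <- t / sqrt(t^2 + df)
  n <- if (is.null(n_total)) df + 2 else n_total
  list(r = r, v = sampling_variance_r(r, n))
}

#' Cramer's V from a chi-squared statistic
#'
#' `V = sqrt(chi2 / (n * (min(rows, cols) - 1)))`, the association measure for
#' an r x c contingency table; for a 2x2 table V equals |phi|. V is inherently
#' unsigned, so a direction must subsequently be attached with
#' [assign_sign()]. The variance is reported on the r scale as
#' `(1 - V^2)^2 / (n - 1)`.
#'
#' @param chi2 Chi-squared statistic (>= 0).
#' @param n Total sample size (>= 4).
#' @param rows,cols Contingency-table dimensions, both >= 2.
#' @return List with `V` (in [0, 1]) and `v`.
#' @export
cramers_v <- function(chi2, n, rows = 2, cols = 2) {
  if (any(chi2 < 0)) stop("chi-squared statistic must be nonnegative")
  stopifnot(n >= 4, rows >= 2, cols >= 2)
  V <- sqrt(chi2 / (n * (min(rows, cols) - 1)))
  list(V = V, v = sampling_variance_r(V, n))
}

#' Eta-squared (and its correlation magnitude) from an omnibus F
#'
#' `eta2 = F*df1 / (F*df1 + df2)`, the proportion of variance attributable to
#' the factor, valid for omnibus (multi-df) F tests. The correlation-scale
#' magnitude is `sqrt(eta2)`; for `df1 = 1` this equals |r| from `t = sqrt(F)`
#' with `df = df2`. Unsigned: attach a direction with [assign_sign()].
#' Variance convention: `(1 - eta2)^2 / (n - 1)` on the r scale with
#' `n = df1 + df2 + 1` unless `n_total` is given.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param n_total Optional total sample size.
#' @return List with `eta2`, `r_magnitude` and `v`.
#' @export
eta_squared_from_f <- function(f, df1, df2, n_total = NULL) {
  if (any(f < 0)) stop("F statistic must be nonnegative")
  stopifnot(df1 >= 1, df2 >= 1)
  eta2 <- f * df1 / (f * df1 + df2)
  n <- if (is.null(n_total)) df1 + df2 + 1 else n_total
  list(eta2 = eta2, r_magnitude = sqrt(eta2),
       v = sampling_variance_r(sqrt(eta2), n))
}

#' Large-sample sampling variance of a correlation
#'
#' `v = (1 - r^2)^2 / (n - 1)`. For biserial estimates beyond |1| this
#' formula would degenerate, so there Soper's biserial variance is used
#' instead (balanced-group form, matching [rbis_from_groups()] at p = 0.5).
#' Sample correlations of exactly |1| (e.g., a perfect-association 2x2
#' table) would get zero variance and infinite weight; the variance is
#' therefore floored at its |r| = 0.99 value.
#'
#' @param r Correlation-scale effect size.
#' @param n Sample size (>= 3).
#' @export
sampling_variance_r <- function(r, n) {
  if (any(n < 3)) stop("insufficient sample size")
  v <- pmax((1 - r^2)^2, (1 - 0.99^2)^2) / (n - 1)
  over <- abs(r) > 1
  if (any(over)) {
    # Soper's variance with p = q = 0.5 (z = 0, phi = dnorm(0)); |r| capped at
    # 1 inside the polynomial, as in the escalc convention
    fz <- stats::dnorm(0)
    rt <- pmin(1, pmax(-1, r))
    v[over] <- ((0.25 / fz^2 - (3 / 2 + 1) * rt^2 + rt^4) / (n - 1))[over]
  }
  v
}

#' Attach a reported direction to an unsigned effect-size magnitude
#'
#' Inherently unsigned statistics (F, chi-squared) carry no direction and are
#' easily mis-recorded as positive by default; the direction must come from
#' the primary study. Records whose direction is unknown are kept but flagged
#' (`sign_source = "flagged_unknown"`) and are excluded from model fits unless
#' explicitly retained. Reversed-scale traits (e.g., latency, where larger
#' values mean less aggression) are handled by flipping the direction before
#' signing.
#'
#' @param magnitude Nonnegative effect-size magnitude.
#' @param direction One of `"positive"`, `"negative"`, `"unknown"`.
#' @param scale_reversed Flip the direction before signing?
#' @return List with `r` (signed, or the bare magnitude when unknown) and
#'   `sign_source` (`"assigned_from_direction"` or `"flagged_unknown"`).
#' @export
assign_sign <- function(magnitude, direction = c("positive", "negative", "unknown"),
                        scale_reversed = FALSE) {
  direction <- match.arg(direction)
  stopifnot(magnitude >= 0)
  if (direction == "unknown") {
    return(list(r = magnitude, sign_source = "flagged_unknown"))
  }
  if (isTRUE(scale_reversed)) {
    direction <- if (direction == "positive") "negative" else "positive"
  }
  list(r = if (direction == "positive") magnitude else -magnitude,
       sign_source = "assigned_from_direction")
}

#' Guard against Fisher Z-transforming a mixed-origin dataset
#'
#' The Fisher Z-transformation is appropriate for Pearson correlations but not
#' for biserial correlations, which require a different transformation; a
#' dataset mixing both must therefore stay on the raw r scale. Requesting
#' `"fisher_z"` on a dataset that contains both `pearson_r` and `means_sd_n`
#' origins is a hard error. Homogeneous Pearson datasets may be transformed
#' (`z = atanh(r)`, `v_z = 1/(n - 3)`) for sensitivity analyses.
#'
#' @param effects Data frame of converted effects with columns `origin`, `r`,
#'   `v` and (for the transform) `n_total`.
#' @param scale `"raw_r"` (no-op) or `"fisher_z"`.
#' @return The validated (possibly transformed) data frame, with a
#'   `scale_tag` column recording the scale.
#' @export
fisher_z_guard <- function(effects, scale = c("raw_r", "fisher_z")) {
  scale <- match.arg(scale)
  if (scale == "raw_r") {
    effects$scale_tag <- "raw_r"
    return(effects)
  }
  org <- unique(effects$origin)
  if (all(c("pearson_r", "means_sd_n") %in% org)) {
    stop("incompatible transformation: Fisher Z requested for a dataset ",
         "mixing Pearson r with biserial (means-SD-n) effects")
  }
  if (any(abs(effects$r) >= 1)) {
    stop("incompatible transformation: |r| >= 1 cannot be Z-transformed")
  }
  if (is.null(effects$n_total) || anyNA(effects$n_total)) {
    stop("Fisher Z requires a complete n_total column")
  }
  effects$r <- atanh(effects$r)
  effects$v <- 1 / (effects$n_total - 3)
  effects$scale_tag <- "fisher_z"
  effects
}

#' Tabulate the sign distribution of effects by statistical origin
#'
#' A steep gradient in the percentage of positive effects from inherently
#' signed origins (r, means-SD-n, t) to inherently unsigned ones (F,
#' chi-squared) is a red flag for default-positive sign assignment during
#' extraction. A warning is raised when any unsigned-statistic origin exceeds
#' the minimum signed origin by more than `margin` percentage points.
#'
#' @param effects Data frame with columns `origin` and `r`.
#' @param margin Warning threshold in percentage points.
#' @return Data frame (origin, k, pct_positive) with attribute
#'   `gradient_warning`.
#' @export
sign_distribution_audit <- function(effects, margin = 25) {
  eff <- effects[!is.na(effects$r), , drop = FALSE]
  tab <- do.call(rbind, lapply(intersect(ORIGINS, unique(eff$origin)), function(o) {
    ri <- eff$r[eff$origin == o]
    data.frame(origin = o, k = length(ri),
               pct_positive = 100 * mean(ri > 0))
  }))
  signed <- tab$pct_positive[tab$origin %in% c("pearson_r", "means_sd_n", "t_value")]
  unsigned <- tab$pct_positive[tab$origin %in% c("F_value", "chi2_value")]
  warn <- length(signed) > 0 && length(unsigned) > 0 &&
    max(unsigned) - min(signed) > margin
  if (warn) {
    warning(sprintf(
      "sign gradient: unsigned-statistic origins reach %.1f%% positive vs %.1f%% for signed origins",
      max(unsigned), min(signed)))
  }
  attr(tab, "gradient_warning") <- warn
  tab
}

#' Convert an extraction table to correlation-scale effect sizes
#'
#' Applies the origin-appropriate conversion to every row of an effect-size
#' extraction table (see [read_effects_csv()] for the column dialect) and
#' appends `r`, `v`, `sign_source`, `scale_tag`, the effective sample size
#' `n_eff` used by small-study tests (`4*n1*n2/(n1+n2)` for two-group
#' designs, `n_total` otherwise) and an `excluded` flag. Rows with an unknown
#' direction for an unsigned statistic are flagged and excluded unless
#' `keep_unsigned = TRUE`, which retains them at +magnitude (the
#' legacy-comparison behavior).
#'
#' @param data Extraction data frame.
#' @param variant Biserial pooling variant, `"fixed"` or `"buggy"`.
#' @param small_sample Passed to [rbis_from_groups()].
#' @param keep_unsigned Retain unknown-direction effects at +magnitude.
#' @return The input with conversion columns appended.
#' @export
convert_effects <- function(data, variant = c("fixed", "buggy"),
                            small_sample = FALSE, keep_unsigned = FALSE) {
  variant <- match.arg(variant)
  stopifnot(all(c("effect_id", "study_id", "species", "origin") %in% names(data)))
  bad <- setdiff(unique(data$origin), ORIGINS)
  if (length(bad)) stop("unknown origin(s): ", paste(bad, collapse = ", "))
  n <- nrow(data)
  r <- v <- n_eff <- rep(NA_real_, n)
  sign_source <- rep(NA_character_, n)
  excluded <- rep(FALSE, n)
  rev_flag <- if (is.null(data$scale_reversed)) rep(FALSE, n) else
    data$scale_reversed %in% c(TRUE, "TRUE", "true", "1", 1)

  for (i in seq_len(n)) {
    o <- data$origin[i]
    if (o == "pearson_r") {
      ri <- data$stat_value[i]
      if (rev_flag[i]) ri <- -ri
      r[i] <- ri
      v[i] <- sampling_variance_r(ri, data$n_total[i])
      sign_source[i] <- "inherent"
      n_eff[i] <- data$n_total[i]
    } else if (o == "means_sd_n") {
      est <- rbis_from_groups(data$mean_dark[i], data$sd_dark[i], data$n_dark[i],
                              data$mean_light[i], data$sd_light[i], data$n_light[i],
                              variant = variant, small_sample = small_sample)
      r[i] <- if (rev_flag[i]) -est$r else est$r
      v[i] <- est$v
      sign_source[i] <- "inherent"
      n_eff[i] <- 4 * data$n_dark[i] * data$n_light[i] /
        (data$n_dark[i] + data$n_light[i])
    } else if (o == "t_value") {
      nt <- if (!is.null(data$n_total) && !is.na(data$n_total[i])) data$n_total[i] else NULL
      est <- r_from_t(data$stat_value[i], data$df1[i], n_total = nt)
      r[i] <- if (rev_flag[i]) -est$r else est$r
      v[i] <- est$v
      sign_source[i] <- "inherent"
      n_eff[i] <- if (is.null(nt)) data$df1[i] + 2 else nt
    } else {
      mag <- if (o == "F_value") {
        est <- eta_squared_from_f(data$stat_value[i], data$df1[i], data$df2[i],
                                  n_total = data$n_total[i])
        est$r_magnitude
      } else {
        est <- cramers_v(data$stat_value[i], data$n_total[i],
                         data$rows[i], data$cols[i])
        est$V
      }
      dir <- as.character(data$direction[i])
      if (is.na(dir) || !nzchar(dir)) dir <- "unknown"
      sg <- assign_sign(mag, dir, scale_reversed = rev_flag[i])
      r[i] <- sg$r
      v[i] <- est$v
      sign_source[i] <- sg$sign_source
      n_eff[i] <- data$n_total[i]
      if (sg$sign_source == "flagged_unknown" && !keep_unsigned) excluded[i] <- TRUE
    }
  }
  data$r <- r
  data$v <- v
  data$sign_source <- sign_source
  data$scale_tag <- "raw_r"
  data$n_eff <- n_eff
  data$excluded <- excluded
  data
}
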