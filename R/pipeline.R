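# Orchestration: read data and tree, convert, audit, fit, summarize, write.

#' Read an effect-size extraction table
#'
#' CSV dialect: one row per effect with columns `effect_id, study_id,
#' species, origin, stat_value, df1, df2, rows, cols, mean_dark, sd_dark,
#' n_dark, mean_light, sd_light, n_light, n_total, direction,
#' scale_reversed`. Fields that do not apply to a row's origin are left
#' empty (read as NA), never zero.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_effects_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

# stable config fingerprint without external digest dependencies (djb2)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full re-analysis pipeline
#'
#' Stages: convert raw statistics to r-scale effects; audit the sign
#' distribution by origin; apply the requested scale (with the Fisher-Z
#' mixing guard); build the dataset with its phylogenetic correlation and
#' within-study sampling VCV; fit the intercept-only phylogenetic multilevel
#' model with Wald inference, Cochran's Q, multilevel I2 and the prediction
#' interval; run the small-study-effects meta-regression; optionally fit a
#' moderator model. Any stage error aborts with the stage name prefixed.
#'
#' @param data Raw extraction table (data frame) or path to its CSV.
#' @param tree Optional `phylo`, Newick string or path.
#' @param rho Within-study sampling correlation.
#' @param scale `"raw_r"` or `"fisher_z"` (guarded).
#' @param moderator Optional moderator column name (e.g., `"origin"`).
#' @param small_study Precision-moderator kind for [small_study_test()];
#'   `"ess"` is shorthand for `"inv_sqrt_n_eff"`, `"se"` for `"se_of_r"`.
#' @param inference `"z"` (default) or `"t"`.
#' @param variant Biserial pooling variant (audit use: `"buggy"`).
#' @param keep_unsigned Retain unknown-direction effects at +magnitude.
#' @param seed Optional integer seed recorded in the report (the pipeline
#'   itself is deterministic; the seed also feeds any downstream simulation).
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `coefficients.csv`, `effects.csv` and `log.txt`.
#' @param level Confidence level used throughout.
#' @return Report list (class `badge_report`).
#' @export
run_pipeline <- function(data, tree = NULL, rho = 0.5,
                         scale = c("raw_r", "fisher_z"), moderator = NULL,
                         small_study = c("ess", "se", "inv_sqrt_n_eff",
                                         "se_of_r", "se_of_z"),
                         inference = c("z", "t"),
                         variant = c("fixed", "buggy"),
                         keep_unsigned = FALSE, seed = NULL, out_dir = NULL,
                         level = 0.95) {
  scale <- match.arg(scale)
  small_study <- match.arg(small_study)
  small_study <- switch(small_study, ess = "inv_sqrt_n_eff", se = "se_of_r",
                        small_study)
  inference <- match.arg(inference)
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  cfg <- list(rho = rho, scale = scale, moderator = moderator,
              small_study = small_study, inference = inference,
              variant = variant, keep_unsigned = keep_unsigned, seed = seed,
              level = level)

  if (is.character(data)) data <- stage("read", read_effects_csv(data))
  converted <- stage("convert",
                     convert_effects(data, variant = variant,
                                     keep_unsigned = keep_unsigned))
  audit <- stage("audit", suppressWarnings(sign_distribution_audit(converted)))
  usable <- converted[!converted$excluded, , drop = FALSE]
  usable <- stage("scale", fisher_z_guard(usable, scale = scale))
  ds <- stage("dataset", meta_dataset(usable, tree = tree, rho = rho))

  fit <- stage("fit", reml_fit(ds, inference = inference))
  wald <- wald_inference(fit, level = level)
  q <- stage("heterogeneity", cochran_q(ds))
  i2 <- i2_multilevel(fit)
  pi_ <- prediction_interval(fit, level = level)
  ss <- stage("small_study", small_study_test(ds, kind = small_study,
                                              inference = inference))
  mod_report <- NULL
  if (!is.null(moderator)) {
    mod_report <- stage("moderator",
                        if (identical(moderator, "origin")) {
                          effect_size_origin_report(ds, inference = inference,
                                                    level = level)
                        } else {
                          meta_regression(ds, moderator, level = level,
                                          inference = inference)
                        })
  }

  report <- structure(list(
    config = c(cfg, list(package_version = as.character(utils::packageVersion("badgemeta")),
                         config_hash = .config_hash(cfg))),
    k = fit$k, n_studies = fit$n_studies, n_species = fit$n_species,
    estimate = unname(fit$beta[1]), se = unname(fit$se[1]),
    ci = c(wald$ci_lb[1], wald$ci_ub[1]), pval = wald$pval[1],
    sigma2 = fit$sigma2, sigma2_total = i2$sigma2_total,
    i2_total = i2$i2_total, i2_by_level = i2$i2_by_level,
    prediction_interval = pi_,
    Q = q$Q, Q_df = q$df, Q_pval = q$pval,
    small_study = ss[c("kind", "slope", "slope_ci", "slope_p",
                       "adjusted_mean", "adjusted_ci", "adjusted_p",
                       "r2_marginal")],
    audit = audit,
    moderator = mod_report,
    excluded = converted[converted$excluded,
                         c("effect_id", "study_id", "origin"), drop = FALSE],
    fit = fit
  ), class = "badge_report")

  if (!is.null(out_dir)) write_report(report, usable, out_dir)
  report
}

#' @export
print.badge_report <- function(x, digits = 3, ...) {
  cat("badge-of-status re-analysis report\n")
  cat(sprintf("  k = %d effects, %d studies, %d species\n",
              x$k, x$n_studies, x$n_species))
  cat(sprintf("  pooled r = %.*f, %d%% CI [%.*f, %.*f], p = %.4f\n",
              digits, x$estimate, round(100 * x$config$level),
              digits, x$ci[1], digits, x$ci[2], x$pval))
  cat(sprintf("  sigma2_total = %.*f, I2_total = %.1f%%, Q = %.0f (df %d, p %s)\n",
              digits, x$sigma2_total, x$i2_total, x$Q, x$Q_df,
              format.pval(x$Q_pval, digits = 2)))
  cat(sprintf("  %d%% PI [%.*f, %.*f]\n", round(100 * x$config$level),
              digits, x$prediction_interval[1], digits, x$prediction_interval[2]))
  cat(sprintf("  small-study slope (%s) = %.*f [%.*f, %.*f], adjusted mean = %.*f\n",
              x$small_study$kind, digits, x$small_study$slope,
              digits, x$small_study$slope_ci[1], digits, x$small_study$slope_ci[2],
              digits, x$small_study$adjusted_mean))
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' `report.json` (full precision), `coefficients.csv`, `effects.csv` and a
#' `log.txt` listing every excluded or flagged effect with its reason.
#'
#' @param report A `badge_report`.
#' @param effects The converted effects table used for fitting.
#' @param dir Output directory.
#' @export
write_report <- function(report, effects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- report[setdiff(names(report), "fit")]
  json$moderator <- if (!is.null(report$moderator)) {
    if (inherits(report$moderator, "origin_report")) {
      unclass(report$moderator)[c("table", "r2_marginal", "omnibus")]
    } else {
      list(coef_table = report$moderator$coef_table,
           r2_marginal = report$moderator$r2_marginal)
    }
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(wald_inference(report$fit),
                   file.path(dir, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(effects, file.path(dir, "effects.csv"), row.names = FALSE)
  lines <- c(sprintf("badgemeta %s  config %s  seed %s",
                     report$config$package_version, report$config$config_hash,
                     if (is.null(report$config$seed)) "none" else report$config$seed),
             if (nrow(report$excluded)) {
               sprintf("excluded %s (%s, %s): unknown sign",
                       report$excluded$effect_id, report$excluded$study_id,
                       report$excluded$origin)
             } else "no effects excluded")
  writeLines(lines, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Per-origin pooled estimates
#'
#' Fits the effect-size-origin meta-regression (cell-means parameterization)
#' and tabulates, per origin, the number of effects and studies, the percent
#' of positive effects, and the pooled estimate with its CI; plus the
#' omnibus moderator test and marginal R2. Large differences between origins
#' — especially unsigned-statistic origins pooling higher than directly
#' extracted correlations — indicate extraction-stage sign problems rather
#' than biology.
#'
#' @param dataset A [meta_dataset()] whose effects carry `origin`.
#' @param level Confidence level.
#' @param ... Passed to [reml_fit()].
#' @return Object of class `origin_report` with `table`, `omnibus`,
#'   `r2_marginal` and the underlying `meta_regression`.
#' @export
effect_size_origin_report <- function(dataset, level = 0.95, ...) {
  stopifnot(inherits(dataset, "meta_dataset"))
  eff <- dataset$effects
  if (is.null(eff$origin)) stop("effects must carry an origin column")
  if (length(unique(eff$origin)) < 2) {
    stop("origin report needs >= 2 origins; ",
         "only '", unique(eff$origin), "' present")
  }
  mr <- meta_regression(dataset, "origin", level = level, ...)
  tab <- mr$coef_table
  per <- do.call(rbind, lapply(tab$term, function(o) {
    sub <- eff[eff$origin == o, , drop = FALSE]
    data.frame(origin = o, k = nrow(sub),
               n_studies = length(unique(sub$study_id)),
               pct_positive = 100 * mean(sub$r > 0))
  }))
  table <- cbind(per, tab[match(per$origin, tab$term),
                          c("estimate", "ci_lb", "ci_ub", "pval")])
  rownames(table) <- NULL
  structure(list(table = table, omnibus = mr$omnibus,
                 r2_marginal = mr$r2_marginal, regression = mr),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, digits = 3, ...) {
  cat("Pooled effect by effect-size origin\n")
  tab <- x$table
  tab$pct_positive <- round(tab$pct_positive, 1)
  tab[c("estimate", "ci_lb", "ci_ub")] <-
    round(tab[c("estimate", "ci_lb", "ci_ub")], digits)
  print(tab)
  cat(sprintf("Omnibus chisq = %.2f (df %d, p = %.4f); R2_marginal = %.1f%%\n",
              x$omnibus$chisq, x$omnibus$df, x$omnibus$pval, x$r2_marginal))
  invisible(x)
}
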