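# Phylogenetic multilevel random-effects meta-analysis by REML.
#
# Marginal model: y = X beta + u_study + u_species + u_phylo + u_unit + e,
#   Sigma(sigma2) = M + s_study*S + s_species*G + s_phylo*ZAZ' + s_unit*I,
# where M is the block sampling VCV (rho within study), S and G are
# same-study / same-species indicator matrices, and A the phylogenetic
# correlation. The REML log-likelihood is evaluated by Cholesky
# factorization and maximized over log-variances with analytic scores.

LEVELS <- c("study", "species", "phylogeny", "unit")

#' Block sampling variance-covariance matrix
#'
#' Diagonal `v`; off-diagonal `rho * sqrt(v_i v_j)` for effects from the same
#' study, 0 otherwise. Positive definite by construction for `rho < 1`.
#'
#' @param v Per-effect sampling variances, all > 0.
#' @param study_ids Study label per effect.
#' @param rho Assumed correlation between sampling errors within a study.
#' @return k x k covariance matrix.
#' @export
build_sampling_vcv <- function(v, study_ids, rho = 0.5) {
  if (any(v <= 0)) stop("all sampling variances must be > 0")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  stopifnot(length(v) == length(study_ids))
  same <- outer(study_ids, study_ids, "==")
  M <- rho * sqrt(outer(v, v)) * same
  diag(M) <- v
  M
}

#' Assemble a meta-analytic dataset
#'
#' Bundles converted effects, the phylogenetic correlation matrix derived
#' from `tree`, and the within-study sampling VCV. Effects flagged
#' `excluded` (unknown sign) are dropped with a message. Species names are
#' matched to tree tips after normalization; unmatched species are an error.
#'
#' @param effects Data frame with at least `effect_id`, `study_id`,
#'   `species`, `r`, `v` (and optionally `n_eff`, `origin`, ...).
#' @param tree Optional `phylo` object or Newick path/string; Grafen branch
#'   lengths are applied when the tree has none.
#' @param rho Within-study sampling correlation for the VCV.
#' @return Object of class `meta_dataset`.
#' @export
meta_dataset <- function(effects, tree = NULL, rho = 0.5) {
  stopifnot(all(c("effect_id", "study_id", "species", "r", "v") %in% names(effects)))
  if (anyDuplicated(effects$effect_id)) stop("effect_id labels must be unique")
  if (!is.null(effects$excluded) && any(effects$excluded)) {
    message(sum(effects$excluded), " effect(s) excluded (unknown sign)")
    effects <- effects[!effects$excluded, , drop = FALSE]
  }
  effects <- effects[!is.na(effects$r) & !is.na(effects$v), , drop = FALSE]
  if (nrow(effects) < 2) stop("need at least 2 usable effects")
  if (any(effects$v <= 0)) stop("all sampling variances must be > 0")
  A <- NULL
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) tree <- read_phylogeny(tree)
    if (is.null(tree$edge.length)) tree <- grafen_lengths(tree)
    A <- phylo_correlation(tree, species = unique(effects$species))
  }
  M <- build_sampling_vcv(effects$v, effects$study_id, rho = rho)
  structure(list(effects = effects, A = A, M = M, rho = rho, tree = tree),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  e <- x$effects
  cat("meta_dataset:", nrow(e), "effects,",
      length(unique(e$study_id)), "studies,",
      length(unique(e$species)), "species;",
      if (is.null(x$A)) "no phylogeny" else "phylogenetic correlation attached",
      sprintf("(rho = %.2f)\n", x$rho))
  invisible(x)
}

# Random-effect design matrices (as k x k covariance contributions) for the
# requested levels. A NULL phylogenetic correlation drops that level.
.random_covs <- function(effects, A, random, phylo_corr = NULL) {
  k <- nrow(effects)
  Gs <- list()
  if ("study" %in% random) {
    Gs$study <- 1 * outer(effects$study_id, effects$study_id, "==")
  }
  if ("species" %in% random) {
    Gs$species <- 1 * outer(effects$species, effects$species, "==")
  }
  if ("phylogeny" %in% random) {
    Aeff <- if (!is.null(phylo_corr)) phylo_corr else A
    if (!is.null(Aeff)) {
      idx <- match(normalize_species(effects$species),
                   normalize_species(rownames(Aeff)))
      if (anyNA(idx)) stop("species missing from phylogenetic correlation: ",
                           paste(unique(effects$species[is.na(idx)]), collapse = ", "))
      Gs$phylogeny <- Aeff[idx, idx, drop = FALSE]
    }
  }
  if ("unit" %in% random) Gs$unit <- diag(k)
  Gs
}

# Single REML evaluation at a given vector of variance components.
# Returns log-likelihood, analytic score per component, GLS beta and its
# covariance. Cholesky with jitter escalation on factorization failure.
.reml_eval <- function(sigma2, y, X, M, Gs, grad = TRUE) {
  k <- length(y)
  p <- ncol(X)
  Sigma <- M
  for (j in seq_along(Gs)) Sigma <- Sigma + sigma2[j] * Gs[[j]]
  L <- NULL
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(chol(Sigma + diag(jit, k)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) return(NULL)
  W <- chol2inv(L)
  WX <- W %*% X
  XtWX <- crossprod(X, WX)
  Cx <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(Cx)) stop("rank-deficient fixed-effect design matrix")
  Ci <- chol2inv(Cx)
  beta <- drop(Ci %*% crossprod(WX, y))
  resid <- drop(y - X %*% beta)
  Py <- drop(W %*% resid)
  ll <- -0.5 * ((k - p) * log(2 * pi) + 2 * sum(log(diag(L))) +
                  2 * sum(log(diag(Cx))) + sum(resid * Py))
  out <- list(ll = ll, beta = beta, vcov_beta = Ci)
  if (grad && length(Gs)) {
    P <- W - WX %*% tcrossprod(Ci, WX)
    out$score <- vapply(seq_along(Gs), function(j) {
      -0.5 * (sum(P * Gs[[j]]) - drop(crossprod(Py, Gs[[j]] %*% Py)))
    }, numeric(1))
  }
  out
}

#' Fit a phylogenetic multilevel meta-analysis by REML
#'
#' Estimates the variance components of the random structure (study, species,
#' phylogeny, unit) and the fixed effects by restricted maximum likelihood,
#' with the within-study block sampling VCV of the dataset as the known
#' error covariance. Optimization is over log-variances (quasi-Newton
#' L-BFGS-B with analytic scores) from three deterministic starting points;
#' components converging to the boundary are reported as exactly 0.
#'
#' @param dataset A [meta_dataset()].
#' @param moderator Optional name of a column of `dataset$effects`.
#'   Categorical moderators are fitted without intercept (per-level means);
#'   numeric moderators with intercept. `NULL` fits the intercept-only model.
#' @param random Random levels to include. `"phylogeny"` is dropped
#'   automatically when the dataset has no tree.
#' @param sigma2_fixed Optional named numeric vector fixing selected
#'   components (e.g., `c(study = 0, species = 0, phylogeny = 0, unit = 0)`
#'   gives the fixed-effect/GLS limit).
#' @param phylo_corr Optional replacement phylogenetic correlation matrix
#'   (rows/cols named by species), e.g. an identity for sensitivity checks.
#' @param inference Reference distribution for Wald inference downstream:
#'   normal (`"z"`, default) or t with k - p degrees of freedom.
#' @return Object of class `badge_fit` with elements `beta`, `se`,
#'   `vcov_beta`, `sigma2` (named per level), `loglik_reml`, `converged`,
#'   `k`, `n_studies`, `n_species`, plus internal state for summaries.
#' @export
reml_fit <- function(dataset, moderator = NULL, random = LEVELS,
                     sigma2_fixed = NULL, phylo_corr = NULL,
                     inference = c("z", "t")) {
  stopifnot(inherits(dataset, "meta_dataset"))
  inference <- match.arg(inference)
  random <- match.arg(random, LEVELS, several.ok = TRUE)
  eff <- dataset$effects
  y <- eff$r

  if (is.null(moderator)) {
    X <- matrix(1, nrow(eff), 1, dimnames = list(NULL, "intercept"))
  } else {
    if (!moderator %in% names(eff)) stop("moderator not found: ", moderator)
    mo <- eff[[moderator]]
    keep <- !is.na(mo)
    if (!all(keep)) {
      message(sum(!keep), " effect(s) dropped: missing moderator value")
      eff <- eff[keep, , drop = FALSE]
      y <- y[keep]
      mo <- mo[keep]
      dataset$M <- dataset$M[keep, keep, drop = FALSE]
    }
    if (is.numeric(mo)) {
      if (stats::var(mo) == 0) stop("moderator is constant")
      X <- cbind(intercept = 1, mo)
      colnames(X)[2] <- moderator
    } else {
      mo <- factor(mo)
      if (nlevels(mo) < 2) stop("moderator has a single level")
      X <- stats::model.matrix(~ 0 + mo)
      colnames(X) <- levels(mo)
    }
  }
  M <- dataset$M
  if (nrow(M) != nrow(eff)) M <- build_sampling_vcv(eff$v, eff$study_id, dataset$rho)

  Gs <- .random_covs(eff, dataset$A, random, phylo_corr = phylo_corr)
  used_levels <- names(Gs)

  fixed <- rep(NA_real_, length(Gs))
  names(fixed) <- used_levels
  if (!is.null(sigma2_fixed)) {
    bad <- setdiff(names(sigma2_fixed), LEVELS)
    if (length(bad)) stop("unknown level(s) in sigma2_fixed: ", paste(bad, collapse = ", "))
    fixed[intersect(names(sigma2_fixed), used_levels)] <-
      sigma2_fixed[intersect(names(sigma2_fixed), used_levels)]
  }
  free <- which(is.na(fixed))

  lb <- log(1e-10)
  ub <- log(50)
  assemble <- function(theta) {
    s <- fixed
    s[free] <- exp(theta)
    s
  }

  if (length(free) == 0) {
    ev <- .reml_eval(fixed, y, X, M, Gs, grad = FALSE)
    if (is.null(ev)) stop("marginal covariance not positive definite")
    sigma2 <- fixed
    converged <- TRUE
    best <- list(value = -ev$ll)
  } else {
    negll <- function(theta) {
      ev <- .reml_eval(assemble(theta), y, X, M, Gs, grad = FALSE)
      if (is.null(ev) || !is.finite(ev$ll)) return(1e10)
      -ev$ll
    }
    neggr <- function(theta) {
      ev <- .reml_eval(assemble(theta), y, X, M, Gs, grad = TRUE)
      if (is.null(ev)) return(rep(0, length(theta)))
      -(ev$score[free] * exp(theta))
    }
    # deterministic multi-start: equal split of excess variance, a
    # unit-heavy split, and a near-boundary start
    s_tot <- max(stats::var(y) - mean(eff$v), 1e-3)
    starts <- list(rep(s_tot / length(free), length(free)),
                   ifelse(used_levels[free] == "unit", 0.8 * s_tot,
                          0.2 * s_tot / max(1, length(free) - 1)),
                   rep(1e-3, length(free)))
    fits <- lapply(starts, function(s0) {
      tryCatch(
        stats::optim(log(pmax(s0, 1e-8)), negll, neggr, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(factr = 1e3, pgtol = 1e-7, maxit = 500)),
        error = function(e) NULL)
    })
    fits <- Filter(function(f) !is.null(f) && is.finite(f$value) && f$value < 1e9, fits)
    if (!length(fits)) stop("REML optimization failed for all starts")
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    converged <- best$convergence == 0
    if (!converged) warning("REML optimizer did not report convergence")
    sigma2 <- assemble(best$par)
    sigma2[sigma2 < 1e-8] <- 0
  }

  ev <- .reml_eval(sigma2, y, X, M, Gs, grad = FALSE)
  if (is.null(ev)) stop("marginal covariance not positive definite at solution")
  se <- sqrt(diag(as.matrix(ev$vcov_beta)))
  names(se) <- colnames(X)
  beta <- ev$beta
  names(beta) <- colnames(X)

  sig_out <- rep(NA_real_, length(LEVELS))
  names(sig_out) <- LEVELS
  sig_out[used_levels] <- sigma2

  structure(list(
    beta = beta, se = se, vcov_beta = ev$vcov_beta, sigma2 = sig_out,
    loglik_reml = ev$ll, converged = converged,
    k = nrow(eff), n_studies = length(unique(eff$study_id)),
    n_species = length(unique(eff$species)),
    v = eff$v, y = y, X = X, moderator = moderator,
    inference = inference, random = used_levels
  ), class = "badge_fit")
}

#' @export
print.badge_fit <- function(x, digits = 3, ...) {
  cat("Phylogenetic multilevel meta-analysis (REML)\n")
  cat(sprintf("k = %d effects, %d studies, %d species; logLik = %.3f%s\n",
              x$k, x$n_studies, x$n_species, x$loglik_reml,
              if (x$converged) "" else " (NOT converged)"))
  cat("Variance components:\n")
  print(round(x$sigma2[!is.na(x$sigma2)], digits + 2))
  cat("Fixed effects:\n")
  print(round(wald_inference(x), digits))
  invisible(x)
}

#' Wald-type inference for fixed effects
#'
#' Estimates, standard errors, two-sided confidence intervals and p-values
#' from the normal reference (default) or, as a sensitivity option, a t
#' reference with k - p degrees of freedom.
#'
#' @param fit A `badge_fit`.
#' @param level Confidence level.
#' @param inference Override the fit's reference distribution.
#' @return Data frame with one row per coefficient.
#' @export
wald_inference <- function(fit, level = 0.95, inference = NULL) {
  stopifnot(inherits(fit, "badge_fit"), level > 0, level < 1)
  inference <- if (is.null(inference)) fit$inference else match.arg(inference, c("z", "t"))
  alpha <- 1 - level
  df <- fit$k - ncol(fit$X)
  crit <- if (inference == "z") stats::qnorm(1 - alpha / 2) else
    stats::qt(1 - alpha / 2, df)
  z <- fit$beta / fit$se
  pval <- if (inference == "z") 2 * stats::pnorm(-abs(z)) else
    2 * stats::pt(-abs(z), df)
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se),
             ci_lb = unname(fit$beta - crit * fit$se),
             ci_ub = unname(fit$beta + crit * fit$se),
             stat = unname(z), pval = unname(pval),
             row.names = NULL)
}

#' Cochran's Q test for residual heterogeneity
#'
#' Weighted least squares with weights 1/v (ignoring the off-diagonal
#' sampling covariances, as is conventional for Q);
#' `Q = sum(w_i * (y_i - x_i' beta_FE)^2)` on k - p degrees of freedom.
#'
#' @param dataset A [meta_dataset()].
#' @param moderator Optional moderator name (as in [reml_fit()]).
#' @return List with `Q`, `df` and `pval`.
#' @export
cochran_q <- function(dataset, moderator = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  eff <- dataset$effects
  y <- eff$r
  w <- 1 / eff$v
  X <- if (is.null(moderator)) {
    matrix(1, length(y), 1)
  } else {
    mo <- eff[[moderator]]
    if (is.numeric(mo)) cbind(1, mo) else stats::model.matrix(~ 0 + factor(mo))
  }
  if (length(y) <= ncol(X)) stop("k must exceed the number of fixed effects")
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  res <- drop(y - X %*% beta)
  Q <- sum(w * res^2)
  df <- length(y) - ncol(X)
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Uni-moderator phylogenetic multilevel meta-regression
#'
#' Fits [reml_fit()] with the named moderator. Categorical moderators yield
#' per-level pooled means with CIs (no-intercept parameterization); the
#' omnibus Wald chi-squared tests equality of the level means. Also reports
#' the marginal R-squared (percent of variance explained by the moderator).
#'
#' @inheritParams reml_fit
#' @param moderator Name of the moderator column (required).
#' @param level Confidence level for per-coefficient intervals.
#' @return Object of class `meta_regression`: the `badge_fit` plus
#'   `coef_table`, `omnibus` (chisq, df, pval) and `r2_marginal`.
#' @export
meta_regression <- function(dataset, moderator, level = 0.95, ...) {
  if (missing(moderator) || is.null(moderator)) stop("a moderator is required")
  fit <- reml_fit(dataset, moderator = moderator, ...)
  tab <- wald_inference(fit, level = level)
  p <- length(fit$beta)
  omnibus <- NULL
  if (!"intercept" %in% names(fit$beta) && p > 1) {
    # equality of coefficients: contrasts against the first level/term
    Cm <- cbind(-1, diag(p - 1))
    cb <- drop(Cm %*% fit$beta)
    Vc <- Cm %*% fit$vcov_beta %*% t(Cm)
    chisq <- drop(crossprod(cb, solve(Vc, cb)))
    omnibus <- list(chisq = chisq, df = p - 1,
                    pval = stats::pchisq(chisq, p - 1, lower.tail = FALSE))
  }
  structure(list(fit = fit, coef_table = tab, omnibus = omnibus,
                 r2_marginal = r2_marginal(fit)),
            class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$omnibus)) {
    cat(sprintf("Omnibus Wald: chisq = %.3f, df = %d, p = %.4f\n",
                x$omnibus$chisq, x$omnibus$df, x$omnibus$pval))
  }
  cat(sprintf("R2_marginal = %.1f%%\n", x$r2_marginal))
  invisible(x)
}
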