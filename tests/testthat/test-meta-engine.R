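test_that("sampling VCV: diagonal v, rho-scaled covariance within studies only", {
  expect_equal(build_sampling_vcv(0.2, "a"), matrix(0.2, 1, 1))
  M <- build_sampling_vcv(c(0.1, 0.4), c("s1", "s1"), rho = 0.5)
  expect_equal(M[1, 2], 0.5 * sqrt(0.04))
  expect_equal(M[1, 2], 0.1)
  M2 <- build_sampling_vcv(c(0.1, 0.4), c("s1", "s2"), rho = 0.5)
  expect_equal(M2[1, 2], 0)
  expect_error(build_sampling_vcv(c(0.1, 0.2), c("a", "b"), rho = 1), "rho")
  expect_error(build_sampling_vcv(c(0.1, 0), c("a", "b")), "> 0")
  # PSD by construction
  set.seed(2)
  v <- runif(30, 0.01, 0.3)
  st <- sample(letters[1:6], 30, replace = TRUE)
  ev <- eigen(build_sampling_vcv(v, st, 0.9), only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("with variance components fixed at zero, REML reduces to GLS / simple means", {
  # two independent equal-variance effects: intercept = arithmetic mean
  eff <- data.frame(effect_id = c("a", "b"), study_id = c("s1", "s2"),
                    species = c("x", "y"), r = c(0.1, 0.5), v = c(0.2, 0.2))
  ds <- meta_dataset(eff)
  zero <- c(study = 0, species = 0, phylogeny = 0, unit = 0)
  fit <- reml_fit(ds, sigma2_fixed = zero)
  expect_equal(unname(fit$beta), 0.3, tolerance = 1e-10)
  # general case: matches the GLS closed form under the sampling VCV alone
  sd_ <- small_dataset(seed = 21)
  ds2 <- sd_$dataset
  fit2 <- reml_fit(ds2, sigma2_fixed = zero)
  M <- ds2$M
  X <- matrix(1, nrow(ds2$effects), 1)
  y <- ds2$effects$r
  beta_gls <- solve(t(X) %*% solve(M) %*% X, t(X) %*% solve(M) %*% y)
  expect_equal(unname(fit2$beta), drop(beta_gls), tolerance = 1e-8)
})

test_that("optimized REML log-likelihood attains the grid-search oracle maximum", {
  set.seed(31)
  inst <- random_small_instance(k = 12, n_studies = 4)
  eff <- data.frame(effect_id = sprintf("e%d", 1:12), study_id = inst$study,
                    species = sprintf("sp%d", 1:12), r = inst$y, v = inst$v)
  ds <- meta_dataset(eff, rho = 0)  # the oracle instance has a diagonal VCV
  fit <- reml_fit(ds, random = c("study", "unit"))
  # dense grid + golden-section refinement over the two components
  grid <- expand.grid(s1 = seq(0, 0.4, by = 0.004), s2 = seq(0, 0.4, by = 0.004))
  ll <- apply(grid, 1, function(g)
    oracle_reml_ll(as.numeric(g), inst$y, inst$X, inst$M, inst$Gs))
  expect_gte(fit$loglik_reml, max(ll) - 1e-6)
})

test_that("fits agree with metafor::rma.mv on the full four-level phylogenetic model", {
  skip_if_not_installed("metafor")
  sd_ <- small_dataset(seed = 11, n_studies = 12, n_species = 8)
  ds <- sd_$dataset
  fit <- reml_fit(ds)
  eff <- ds$effects
  eff$phylo <- eff$species
  mf <- metafor::rma.mv(r ~ 1, V = ds$M,
                        random = list(~ 1 | study_id, ~ 1 | species,
                                      ~ 1 | phylo, ~ 1 | effect_id),
                        R = list(phylo = ds$A), data = eff)
  expect_equal(unname(fit$beta), unname(coef(mf)), tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(mf$se), tolerance = 1e-2)
  expect_equal(sum(fit$sigma2, na.rm = TRUE), sum(mf$sigma2), tolerance = 0.01)
  # log-likelihoods agree up to metafor's +log|X'X|/2 convention constant
  expect_equal(fit$loglik_reml + 0.5 * log(fit$k), as.numeric(logLik(mf)),
               tolerance = 1e-3)
})

test_that("REML estimates are invariant to effect reordering", {
  sd_ <- small_dataset(seed = 13)
  ds <- sd_$dataset
  fit <- reml_fit(ds)
  set.seed(1)
  perm <- sample(nrow(ds$effects))
  ds_p <- suppressMessages(meta_dataset(ds$effects[perm, ], tree = sd_$sim$tree))
  fit_p <- reml_fit(ds_p)
  expect_equal(unname(fit_p$beta), unname(fit$beta), tolerance = 1e-6)
  expect_equal(fit_p$sigma2, fit$sigma2, tolerance = 1e-4)
  expect_equal(fit_p$loglik_reml, fit$loglik_reml, tolerance = 1e-6)
})

test_that("with an identity phylogeny the species+phylogeny sum stays identifiable", {
  sd_ <- small_dataset(seed = 17, n_studies = 14, n_species = 9)
  ds <- sd_$dataset
  sp <- unique(ds$effects$species)
  ident <- diag(length(sp)); dimnames(ident) <- list(sp, sp)
  fit_id <- reml_fit(ds, phylo_corr = ident)
  fit_3 <- reml_fit(ds, random = c("study", "species", "unit"))
  # the species/phylogeny split is not identifiable, but the sum is
  expect_equal(fit_id$sigma2[["species"]] + fit_id$sigma2[["phylogeny"]],
               fit_3$sigma2[["species"]], tolerance = 1e-3)
  expect_equal(fit_id$loglik_reml, fit_3$loglik_reml, tolerance = 1e-6)
  expect_equal(unname(fit_id$beta), unname(fit_3$beta), tolerance = 1e-6)
})

test_that("Cochran's Q: hand example, zero case, and scale equivariance", {
  eff <- data.frame(effect_id = c("a", "b"), study_id = c("s1", "s2"),
                    species = c("x", "y"), r = c(0, 1), v = c(1, 1))
  q <- cochran_q(meta_dataset(eff))
  expect_equal(q$Q, 0.5)
  expect_equal(q$df, 1)
  # identical effects give Q = 0
  eff2 <- within(eff, r <- c(0.4, 0.4))
  expect_equal(cochran_q(meta_dataset(eff2))$Q, 0)
  # rescaling y and sqrt(v) jointly leaves Q unchanged
  sd_ <- small_dataset(seed = 23)
  ds <- sd_$dataset
  q1 <- cochran_q(ds)
  eff3 <- ds$effects
  eff3$r <- 3 * eff3$r
  eff3$v <- 9 * eff3$v
  q2 <- cochran_q(suppressMessages(meta_dataset(eff3)))
  expect_equal(q2$Q, q1$Q, tolerance = 1e-10)
})

test_that("Wald inference: normal reference, printed-CI self-consistency, level monotonicity", {
  fit <- structure(list(beta = c(intercept = 0), se = c(intercept = 1),
                        k = 50, X = matrix(1, 50, 1), inference = "z"),
                   class = "badge_fit")
  w <- wald_inference(fit)
  expect_equal(w$ci_lb, -qnorm(0.975), tolerance = 1e-10)
  expect_equal(w$ci_ub, qnorm(0.975), tolerance = 1e-10)
  expect_equal(w$pval, 1)
  # a mean of 0.218 with CI [0.078, 0.359] implies SE ~ 0.0717
  fit$beta <- c(intercept = 0.218); fit$se <- c(intercept = 0.0717)
  w2 <- wald_inference(fit)
  expect_lt(abs(w2$ci_lb - 0.078), 0.002)
  expect_lt(abs(w2$ci_ub - 0.359), 0.002)
  w50 <- wald_inference(fit, level = 0.5)
  expect_gt(w50$ci_lb, w2$ci_lb)
  expect_lt(w50$ci_ub, w2$ci_ub)
})

test_that("meta-regression recovers distinct per-level means and rejects constants", {
  set.seed(77)
  k <- 60
  origin <- rep(c("pearson_r", "chi2_value"), each = k / 2)
  mu <- ifelse(origin == "pearson_r", 0, 0.4)
  v <- runif(k, 0.01, 0.05)
  eff <- data.frame(effect_id = sprintf("e%d", 1:k),
                    study_id = sprintf("s%d", rep(1:20, 3)),
                    species = sprintf("sp%d", rep(1:10, 6)),
                    origin = origin,
                    r = rnorm(k, mu, sqrt(v + 0.01)), v = v)
  ds <- meta_dataset(eff)
  mr <- meta_regression(ds, "origin", random = c("study", "unit"))
  tab <- mr$coef_table
  est0 <- tab$estimate[tab$term == "pearson_r"]
  est4 <- tab$estimate[tab$term == "chi2_value"]
  se0 <- tab$se[tab$term == "pearson_r"]
  se4 <- tab$se[tab$term == "chi2_value"]
  expect_lt(abs(est0 - 0), 2.5 * se0)
  expect_lt(abs(est4 - 0.4), 2.5 * se4)
  expect_equal(mr$omnibus$df, 1)
  expect_lt(mr$omnibus$pval, 0.01)
  # constant moderator is an error
  eff$origin <- "pearson_r"
  expect_error(meta_regression(meta_dataset(eff), "origin"), "single level")
})
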