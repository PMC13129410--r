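test_that("standardized difference: correct pooling and the parentheses-missing variant", {
  # hand arithmetic: s_pooled = sqrt(0.60125) = 0.775403, d = 0.15/0.775403
  d_fixed <- std_mean_diff(2.40, 0.80, 10, 2.25, 0.75, 10, variant = "fixed")
  expect_equal(d_fixed, 0.15 / sqrt(0.60125), tolerance = 1e-10)
  expect_equal(d_fixed, 0.19345, tolerance = 1e-4)
  # buggy denominator: sqrt(9*0.5625 + 9*0.64/18) = sqrt(5.3825)
  d_buggy <- std_mean_diff(2.40, 0.80, 10, 2.25, 0.75, 10, variant = "buggy")
  expect_equal(d_buggy, 0.15 / sqrt(5.3825), tolerance = 1e-10)
  expect_equal(d_buggy, 0.06466, tolerance = 1e-4)
  expect_lt(abs(d_buggy), abs(d_fixed))
  # equal means give d = 0 under either variant
  expect_equal(std_mean_diff(3, 1, 8, 3, 2, 12), 0)
  expect_equal(std_mean_diff(3, 1, 8, 3, 2, 12, variant = "buggy"), 0)
  expect_error(std_mean_diff(1, 1, 1, 2, 1, 5), "n_dark")
})

test_that("the buggy denominator never shrinks: |d_buggy| <= |d_fixed| over random summaries", {
  set.seed(42)
  for (i in 1:1000) {
    nD <- sample(2:40, 1); nL <- sample(2:40, 1)
    sdD <- runif(1, 0.1, 3); sdL <- runif(1, 0.1, 3)
    mD <- rnorm(1, 0, 2); mL <- rnorm(1, 0, 2)
    f <- std_mean_diff(mD, sdD, nD, mL, sdL, nL, "fixed")
    b <- std_mean_diff(mD, sdD, nD, mL, sdL, nL, "buggy")
    expect_lte(abs(b), abs(f) + 1e-12)
  }
})

test_that("biserial conversion follows the d -> point-biserial -> biserial chain", {
  # frozen chain: r_pb = d/sqrt(d^2 + 4) = 0.096275, r_bis = r_pb * 0.5/dnorm(0)
  est <- rbis_from_groups(2.40, 0.80, 10, 2.25, 0.75, 10)
  expect_equal(est$r, 0.1206623, tolerance = 1e-6)
  expect_gt(est$v, 0)
  # zero mean difference maps to zero correlation
  expect_equal(rbis_from_groups(2, 1, 10, 2, 1, 10)$r, 0)
  # buggy variant shrinks the estimate
  expect_lt(abs(rbis_from_groups(2.40, 0.80, 10, 2.25, 0.75, 10,
                                 variant = "buggy")$r), abs(est$r))
})

test_that("small-sample biserial mode reproduces metafor::escalc(measure = 'RBIS') exactly", {
  skip_if_not_installed("metafor")
  grid <- expand.grid(m1 = c(2.4, 1.0), m2 = c(2.25, 1.4),
                      n1 = c(10, 25), n2 = c(10, 40))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    est <- rbis_from_groups(g$m1, 0.8, g$n1, g$m2, 0.75, g$n2,
                            small_sample = TRUE)
    ref <- metafor::escalc(measure = "RBIS", m1i = g$m1, m2i = g$m2,
                           sd1i = 0.8, sd2i = 0.75, n1i = g$n1, n2i = g$n2)
    expect_equal(est$r, as.numeric(ref$yi), tolerance = 1e-12)
    expect_equal(est$v, as.numeric(ref$vi), tolerance = 1e-12)
  }
})

test_that("biserial estimates are consistent for the population biserial correlation", {
  # two-group normal data with known latent correlation; at large n the
  # average biserial estimate approaches the population value
  set.seed(99)
  rho <- 0.35
  r_pb <- rho * dnorm(0) / 0.5
  d <- 2 * r_pb / sqrt(1 - r_pb^2)
  n <- 4000
  est <- replicate(60, {
    xD <- rnorm(n, d, 1); xL <- rnorm(n, 0, 1)
    rbis_from_groups(mean(xD), sd(xD), n, mean(xL), sd(xL), n)$r
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - rho), 3 * mc_se + 0.005)
})

test_that("t-to-r conversion preserves sign and matches the algebraic identity", {
  expect_equal(r_from_t(0, 12)$r, 0)
  expect_equal(r_from_t(2, 18)$r, 2 / sqrt(22), tolerance = 1e-10)
  expect_equal(r_from_t(-3, 25)$r, -0.51450, tolerance = 1e-4)
  # identity r^2 = t^2/(t^2 + df)
  r <- r_from_t(2.7, 31)$r
  expect_equal(r^2, 2.7^2 / (2.7^2 + 31), tolerance = 1e-12)
  expect_error(r_from_t(1, 0))
})

test_that("Cramer's V: direct formula, [0, 1] range, and the 2x2 phi identity", {
  expect_equal(cramers_v(0, 50)$V, 0)
  expect_equal(cramers_v(10, 40, 2, 2)$V, 0.5)
  expect_equal(cramers_v(12, 60, 3, 4)$V, sqrt(12 / 120), tolerance = 1e-12)
  expect_error(cramers_v(-1, 40))
  # for 2x2 tables chi2 = n * phi^2, so V = |phi|
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
    n <- sum(tab)
    phi <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
      sqrt(prod(rowSums(tab)) * prod(colSums(tab)) / n^2) / n
    V <- cramers_v(unname(chi), n)$V
    expect_gte(V, 0); expect_lte(V, 1)
    expect_equal(V, abs(phi), tolerance = 1e-8)
  }
})

test_that("eta-squared from F: omnibus formula and df1 = 1 equivalence with t", {
  expect_equal(eta_squared_from_f(0, 1, 20)$eta2, 0)
  e <- eta_squared_from_f(4, 1, 20)
  expect_equal(e$eta2, 1 / 6, tolerance = 1e-12)
  expect_equal(e$r_magnitude, 0.40825, tolerance = 1e-4)
  expect_equal(eta_squared_from_f(3, 2, 30)$eta2, 1 / 6, tolerance = 1e-12)
  # with df1 = 1, sqrt(eta2) equals |r| from t = sqrt(F)
  for (f in c(0.5, 1, 2.7, 6)) {
    for (df2 in c(8, 20, 55)) {
      expect_equal(eta_squared_from_f(f, 1, df2)$r_magnitude,
                   abs(r_from_t(sqrt(f), df2)$r), tolerance = 1e-12)
    }
  }
})

test_that("large-sample variance of r decreases in n and handles |r| > 1", {
  expect_equal(sampling_variance_r(0, 11), 0.1)
  expect_equal(sampling_variance_r(0.5, 21), 0.75^2 / 20)
  v <- sapply(c(5, 10, 50, 200), function(n) sampling_variance_r(0.3, n))
  expect_true(all(diff(v) < 0))
  expect_gt(sampling_variance_r(1.17, 20), 0)
  expect_error(sampling_variance_r(0.2, 2), "insufficient")
})

test_that("sign assignment respects direction, scale reversal and the unknown flag", {
  expect_equal(assign_sign(0.4, "negative")$r, -0.4)
  expect_equal(assign_sign(0.4, "positive")$r, 0.4)
  un <- assign_sign(0.4, "unknown")
  expect_equal(un$r, 0.4)
  expect_equal(un$sign_source, "flagged_unknown")
  # reversed-scale trait (e.g., latency): reversal applies before signing
  expect_equal(assign_sign(0.4, "positive", scale_reversed = TRUE)$r, -0.4)
  expect_equal(assign_sign(0.4, "negative", scale_reversed = TRUE)$r, 0.4)
})

test_that("Fisher Z guard blocks mixed-origin transformation but passes raw r", {
  mixed <- data.frame(origin = c("pearson_r", "means_sd_n"),
                      r = c(0.3, 0.5), v = c(0.02, 0.04), n_total = c(30, 20))
  expect_error(fisher_z_guard(mixed, "fisher_z"), "incompatible")
  out <- fisher_z_guard(mixed, "raw_r")
  expect_equal(out$r, mixed$r)
  expect_equal(out$scale_tag, rep("raw_r", 2))
  homog <- data.frame(origin = "pearson_r", r = c(0.3, -0.2),
                      v = c(0.02, 0.05), n_total = c(30, 43))
  z <- fisher_z_guard(homog, "fisher_z")
  expect_equal(z$r, atanh(c(0.3, -0.2)))
  expect_equal(z$v, 1 / (c(30, 43) - 3))
  expect_equal(z$scale_tag, rep("fisher_z", 2))
})

test_that("sign-distribution audit counts per origin and flags steep gradients", {
  eff <- data.frame(
    origin = c(rep("pearson_r", 4), rep("chi2_value", 2)),
    r = c(0.2, -0.1, -0.3, -0.4, 0.5, 0.6))
  expect_warning(tab <- sign_distribution_audit(eff), "sign gradient")
  expect_equal(tab$pct_positive[tab$origin == "pearson_r"], 25)
  expect_equal(tab$pct_positive[tab$origin == "chi2_value"], 100)
  expect_true(attr(tab, "gradient_warning"))
  # uniformly positive effects trigger no warning
  eff$r <- abs(eff$r)
  expect_no_warning(tab2 <- sign_distribution_audit(eff))
  expect_false(attr(tab2, "gradient_warning"))
  # empty origin classes are omitted
  expect_setequal(tab$origin, c("pearson_r", "chi2_value"))
})

test_that("convert_effects handles every origin and the exclusion policy", {
  conv <- convert_effects(tiny_extraction())
  expect_equal(conv$r[1], 0.30)                      # Pearson passes through
  expect_equal(conv$r[2], 0.1206623, tolerance = 1e-6)  # biserial
  expect_equal(conv$r[3], 2 / sqrt(22), tolerance = 1e-10)
  expect_equal(conv$r[4], sqrt(1 / 6), tolerance = 1e-10)   # F, positive
  expect_equal(conv$r[5], -0.5)                      # chi2, negative direction
  expect_true(all(conv$v > 0))
  # unknown-direction chi2 is flagged and excluded by default
  expect_equal(conv$sign_source[6], "flagged_unknown")
  expect_true(conv$excluded[6])
  expect_false(any(conv$excluded[1:5]))
  # keep_unsigned retains it at +magnitude
  kept <- convert_effects(tiny_extraction(), keep_unsigned = TRUE)
  expect_false(kept$excluded[6])
  expect_gt(kept$r[6], 0)
  # effective sample size: 4*n1*n2/(n1+n2) = 2n for balanced groups
  expect_equal(conv$n_eff[2], 20)
})
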