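# Fixture builders shared across test files. Everything is generated in code;
# sizes are kept small so the default run stays quick.

# a minimal extraction table covering every origin
tiny_extraction <- function() {
  data.frame(
    effect_id = sprintf("e%02d", 1:6),
    study_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
    species = c("sp_a", "sp_a", "sp_b", "sp_c", "sp_d", "sp_b"),
    origin = c("pearson_r", "means_sd_n", "t_value", "F_value", "chi2_value",
               "chi2_value"),
    stat_value = c(0.30, NA, 2.0, 4.0, 10.0, 6.0),
    df1 = c(NA, NA, 18, 1, NA, NA),
    df2 = c(NA, NA, NA, 20, NA, NA),
    rows = c(NA, NA, NA, NA, 2, 3),
    cols = c(NA, NA, NA, NA, 2, 4),
    mean_dark = c(NA, 2.40, NA, NA, NA, NA),
    sd_dark = c(NA, 0.80, NA, NA, NA, NA),
    n_dark = c(NA, 10, NA, NA, NA, NA),
    mean_light = c(NA, 2.25, NA, NA, NA, NA),
    sd_light = c(NA, 0.75, NA, NA, NA, NA),
    n_light = c(NA, 10, NA, NA, NA, NA),
    n_total = c(30, 20, 20, 22, 40, 60),
    direction = c("", "", "", "positive", "negative", ""),
    scale_reversed = FALSE,
    stringsAsFactors = FALSE
  )
}

# converted effects with a small tree, ready for meta_dataset()
small_dataset <- function(seed = 7, n_studies = 8, n_species = 5,
                          rho = 0.5) {
  cfg <- synthetic_config(n_studies = n_studies, n_species = n_species,
                          effects_per_study_range = c(1, 3),
                          tree_seed = seed, data_seed = seed + 1)
  sim <- simulate_meta_dataset(cfg)
  conv <- convert_effects(sim$data)
  ds <- suppressMessages(meta_dataset(conv, tree = sim$tree, rho = rho))
  list(dataset = ds, sim = sim)
}

# independent REML likelihood oracle: direct dense evaluation via solve() and
# determinant(), no Cholesky shortcuts shared with the package internals
oracle_reml_ll <- function(sigma2, y, X, M, Gs) {
  Sigma <- M
  for (j in seq_along(Gs)) Sigma <- Sigma + sigma2[j] * Gs[[j]]
  k <- length(y)
  p <- ncol(X)
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- drop(y - X %*% beta)
  ld1 <- determinant(Sigma, logarithm = TRUE)$modulus
  ld2 <- determinant(XtSiX, logarithm = TRUE)$modulus
  -0.5 * ((k - p) * log(2 * pi) + ld1 + ld2 + drop(t(r) %*% Si %*% r))
}

# random small instance for oracle comparisons: k effects in a handful of
# studies, study + unit variance components
random_small_instance <- function(k = 12, n_studies = 4) {
  study <- sort(sample(sprintf("s%d", seq_len(n_studies)), k, replace = TRUE))
  v <- runif(k, 0.02, 0.2)
  y <- rnorm(k, 0.2, 0.35)
  M <- diag(v)
  X <- matrix(1, k, 1)
  Gs <- list(study = 1 * outer(study, study, "=="), unit = diag(k))
  list(y = y, X = X, M = M, Gs = Gs, study = study, v = v)
}
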