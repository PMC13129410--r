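# Synthetic data with known truth: the two-group biserial comparison
# simulation, random ultrametric phylogenies, and complete meta-analytic
# datasets whose raw summary statistics exercise the full conversion
# pipeline end to end.

#' Simulate the buggy-versus-fixed biserial comparison
#'
#' Draws two normal groups per replicate (defaults: dark N(2.40, 0.80^2),
#' light N(2.25, 0.75^2), n = 10 per group — the group parameters and
#' first-quartile group size of the dataset under audit; 70 is the observed
#' maximum), computes the biserial correlation through both the corrected
#' and the parentheses-missing standardized-difference variants, and
#' summarizes the replicate distribution per variant. Because the buggy
#' denominator is inflated, the buggy variant shrinks every |d|, so its mean
#' and SD sit strictly below the fixed variant's.
#'
#' @param reps Number of replicates (>= 100; default 10000).
#' @param n_per_group Per-group sample size.
#' @param mean_dark,sd_dark,mean_light,sd_light Group parameters.
#' @param seed Optional integer seed.
#' @param small_sample Passed to [rbis_from_groups()].
#' @return Data frame with one row per variant (`variant`, `mean`, `sd`,
#'   `min`, `max`); the replicate-level values are attached as attribute
#'   `"r"` (a reps x 2 matrix).
#' @export
simulate_rbis_comparison <- function(reps = 10000, n_per_group = 10,
                                     mean_dark = 2.40, sd_dark = 0.80,
                                     mean_light = 2.25, sd_light = 0.75,
                                     seed = NULL, small_sample = FALSE) {
  stopifnot(reps >= 100, n_per_group >= 2, sd_dark > 0, sd_light > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_per_group
  xD <- matrix(stats::rnorm(reps * n, mean_dark, sd_dark), reps, n)
  xL <- matrix(stats::rnorm(reps * n, mean_light, sd_light), reps, n)
  mD <- rowMeans(xD)
  mL <- rowMeans(xL)
  sdD <- sqrt(rowSums((xD - mD)^2) / (n - 1))
  sdL <- sqrt(rowSums((xL - mL)^2) / (n - 1))
  out <- vapply(c("fixed", "buggy"), function(var) {
    r <- rbis_from_groups(mD, sdD, n, mL, sdL, n, variant = var,
                          small_sample = small_sample)$r
    r
  }, numeric(reps))
  summ <- data.frame(
    variant = colnames(out),
    mean = colMeans(out),
    sd = apply(out, 2, stats::sd),
    min = apply(out, 2, min),
    max = apply(out, 2, max),
    row.names = NULL
  )
  attr(summ, "r") <- out
  summ
}

#' Simulate a random ultrametric phylogeny
#'
#' Random rooted binary topology by sequential random joins of lineages,
#' then Grafen branch lengths (ultrametric, root height 1). Reproducible for
#' a given seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @param labels Tip labels; defaults to `sp_01, sp_02, ...`.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_species, seed = NULL, labels = NULL) {
  stopifnot(n_species >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) {
    labels <- sprintf("sp_%0*d", nchar(as.character(n_species)), seq_len(n_species))
  }
  stopifnot(length(labels) == n_species)
  groups <- as.list(labels)
  while (length(groups) > 1) {
    i <- sample.int(length(groups), 2)
    joined <- paste0("(", groups[[i[1]]], ",", groups[[i[2]]], ")")
    groups <- c(groups[-i], joined)
  }
  tree <- read_phylogeny(paste0(groups[[1]], ";"))
  grafen_lengths(tree)
}

#' Configuration for a synthetic meta-analytic dataset
#'
#' Defaults mirror the structure of the re-analyzed badge-of-status dataset:
#' 74 studies over 54 species, 1-4 effects per study (about 170 effects in
#' total), per-group sample sizes between 10 and 70, a grand mean of
#' r = 0.218, and variance components whose total (0.174) and relative
#' shares match the reported heterogeneity decomposition
#' (study 0.027, species 0.008, phylogeny 0.047, unit 0.091).
#'
#' @param n_studies,n_species Structure sizes.
#' @param effects_per_study_range Inclusive integer range.
#' @param mu_true Grand mean on the r scale.
#' @param sigma2_true Named per-level true variance components.
#' @param origin_mixture Probabilities over the five origins, in the order
#'   r, means-SD-n, t, F, chi-squared; must sum to 1.
#' @param n_per_group_range Per-group sample-size range.
#' @param tree_seed,data_seed Seeds for the topology and the data draws.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_studies = 74, n_species = 54,
                             effects_per_study_range = c(1, 4),
                             mu_true = 0.218,
                             sigma2_true = c(study = 0.027, species = 0.008,
                                             phylogeny = 0.047, unit = 0.091),
                             origin_mixture = c(pearson_r = 0.15, means_sd_n = 0.25,
                                                t_value = 0.25, F_value = 0.20,
                                                chi2_value = 0.15),
                             n_per_group_range = c(10, 70),
                             tree_seed = 1L, data_seed = 2L) {
  stopifnot(n_studies >= 1, n_species >= 2,
            length(effects_per_study_range) == 2,
            effects_per_study_range[1] >= 1,
            diff(effects_per_study_range) >= 0,
            all(sigma2_true >= 0),
            abs(sum(origin_mixture) - 1) < 1e-8,
            n_per_group_range[1] >= 4)
  stopifnot(identical(sort(names(sigma2_true)), sort(LEVELS)),
            identical(sort(names(origin_mixture)), sort(ORIGINS)))
  structure(as.list(environment()), class = "synthetic_config")
}

# Inverse mappings so each origin's converted effect is centred on the
# target correlation rho:
#  - means-SD-n rows are converted back with the biserial correction, so the
#    latent group difference must come from the biserial -> point-biserial ->
#    d chain (balanced groups, p = 0.5);
#  - t/F rows convert to the point-biserial scale, so d inverts that directly;
#  - 2x2 chi-squared rows yield the phi coefficient, which for a
#    sign-dichotomized bivariate normal is (2/pi) * asin(rho_latent), so the
#    latent correlation is sin(pi * rho / 2).
.d_from_rho_bis <- function(rho) {
  r_pb <- rho * stats::dnorm(0) / 0.5
  r_pb <- pmin(0.99, pmax(-0.99, r_pb))
  2 * r_pb / sqrt(1 - r_pb^2)
}
.d_from_rho_pb <- function(rho) 2 * rho / sqrt(1 - rho^2)
.latent_from_phi <- function(rho) sin(pi * pmin(0.99, pmax(-0.99, rho)) / 2)

#' Simulate a complete meta-analytic dataset with known truth
#'
#' Draws study, species, phylogenetic (multivariate normal under the tree's
#' correlation matrix) and unit-level effects with the configured variance
#' components, forms per-effect true correlations
#' `rho_i = mu + u_study + u_species + u_phylo + u_unit` (clamped to
#' [-0.97, 0.97]; clamping is counted in the truth record), then generates
#' origin-appropriate raw summary statistics: bivariate normal samples for
#' Pearson r, two-group normal layouts for means-SD-n, t and F (F as the
#' squared two-group t, df1 = 1), and sign-dichotomized 2x2 tables for
#' chi-squared. Each origin's latent parameters invert that origin's
#' conversion (biserial for means rows, point-biserial for t/F, the
#' dichotomized-normal phi for 2x2 tables), so every converted effect is
#' centred on its rho_i and the full conversion pipeline is exercised end to
#' end. Directions for the unsigned origins are reported from the sample
#' association, as a faithful extractor would.
#'
#' @param config A [synthetic_config()].
#' @return List with `data` (raw extraction table in the CSV dialect),
#'   `tree`, and `truth` (true parameters, per-effect true correlations,
#'   clamp count).
#' @export
simulate_meta_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  tree <- simulate_tree(cfg$n_species, seed = cfg$tree_seed)
  A <- phylo_correlation(tree)
  species <- rownames(A)

  set.seed(cfg$data_seed)
  k_per_study <- sample(seq(cfg$effects_per_study_range[1],
                            cfg$effects_per_study_range[2]),
                        cfg$n_studies, replace = TRUE)
  k <- sum(k_per_study)
  if (k < cfg$n_studies) stop("infeasible config: fewer effects than studies")
  study_id <- rep(sprintf("study_%03d", seq_len(cfg$n_studies)), k_per_study)
  # one species per study; every species is used when n_studies >= n_species
  sp_of_study <- if (cfg$n_studies >= cfg$n_species) {
    c(sample(species), sample(species, cfg$n_studies - cfg$n_species, replace = TRUE))
  } else {
    sample(species, cfg$n_studies)
  }
  sp <- rep(sp_of_study, k_per_study)

  s2 <- cfg$sigma2_true
  u_study <- stats::rnorm(cfg$n_studies, 0, sqrt(s2["study"]))
  u_species <- stats::rnorm(length(species), 0, sqrt(s2["species"]))
  names(u_species) <- species
  u_phylo <- drop(t(chol(A)) %*% stats::rnorm(length(species))) * sqrt(s2["phylogeny"])
  names(u_phylo) <- species
  u_unit <- stats::rnorm(k, 0, sqrt(s2["unit"]))

  rho <- cfg$mu_true + rep(u_study, k_per_study) + u_species[sp] +
    u_phylo[sp] + u_unit
  clamped <- sum(abs(rho) > 0.97)
  rho <- pmin(0.97, pmax(-0.97, rho))

  origin <- sample(names(cfg$origin_mixture), k, replace = TRUE,
                   prob = cfg$origin_mixture)
  ng <- sample(seq(cfg$n_per_group_range[1], cfg$n_per_group_range[2]),
               k, replace = TRUE)

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    rec <- list(effect_id = sprintf("es_%04d", i), study_id = study_id[i],
                species = sp[i], origin = origin[i],
                stat_value = NA_real_, df1 = NA_real_, df2 = NA_real_,
                rows = NA_real_, cols = NA_real_,
                mean_dark = NA_real_, sd_dark = NA_real_, n_dark = NA_real_,
                mean_light = NA_real_, sd_light = NA_real_, n_light = NA_real_,
                n_total = NA_real_, direction = "", scale_reversed = FALSE)
    if (origin[i] == "pearson_r") {
      n <- 2 * ng[i]
      x <- stats::rnorm(n)
      ysim <- rho[i] * x + sqrt(1 - rho[i]^2) * stats::rnorm(n)
      rec$stat_value <- stats::cor(x, ysim)
      rec$n_total <- n
    } else if (origin[i] %in% c("means_sd_n", "t_value", "F_value")) {
      d <- if (origin[i] == "means_sd_n") .d_from_rho_bis(rho[i]) else
        .d_from_rho_pb(rho[i])
      xD <- stats::rnorm(ng[i], d, 1)
      xL <- stats::rnorm(ng[i], 0, 1)
      if (origin[i] == "means_sd_n") {
        rec$mean_dark <- mean(xD); rec$sd_dark <- stats::sd(xD); rec$n_dark <- ng[i]
        rec$mean_light <- mean(xL); rec$sd_light <- stats::sd(xL); rec$n_light <- ng[i]
      } else {
        tt <- stats::t.test(xD, xL, var.equal = TRUE)$statistic
        rec$n_total <- 2 * ng[i]
        if (origin[i] == "t_value") {
          rec$stat_value <- unname(tt)
          rec$df1 <- 2 * ng[i] - 2
        } else {
          rec$stat_value <- unname(tt^2)
          rec$df1 <- 1
          rec$df2 <- 2 * ng[i] - 2
          rec$direction <- if (tt >= 0) "positive" else "negative"
        }
      }
    } else {
      # 2x2 table from sign-dichotomized bivariate normal draws
      n <- 2 * ng[i]
      rl <- .latent_from_phi(rho[i])
      x <- stats::rnorm(n)
      ysim <- rl * x + sqrt(1 - rl^2) * stats::rnorm(n)
      tab <- table(factor(x > 0, c(FALSE, TRUE)), factor(ysim > 0, c(FALSE, TRUE)))
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(chi$statistic)
      if (!is.finite(stat)) stat <- 0
      rec$stat_value <- stat
      rec$rows <- 2; rec$cols <- 2
      rec$n_total <- n
      lor <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
      rec$direction <- if (lor >= 1) "positive" else "negative"
    }
    rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  truth <- list(mu = cfg$mu_true, sigma2 = s2, rho = rho,
                clamped = clamped, config = cfg)
  list(data = data, tree = tree, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the extraction CSV, the Newick tree and a `truth.json` sidecar.
#'
#' @param sim Result of [simulate_meta_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(data = file.path(dir, "effects.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$data, paths["data"], row.names = FALSE)
  ape::write.tree(sim$tree, paths["tree"])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
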