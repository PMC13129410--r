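---
title: "Methods: effect-size conversion and phylogenetic multilevel meta-analysis in badgemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect-size conversion and phylogenetic multilevel meta-analysis in badgemeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badgemeta)
```

`badgemeta` implements a complete re-analysis workflow for comparative
meta-analyses of coloration-aggression associations (the badge-of-status
literature). This vignette documents the statistical model, the conversion
conventions, the numerical choices, and what the synthetic-data generator
does and does not emulate — i.e., the design decisions a maintainer or
reviewer would want spelled out.

## Effect-size conversion

All effects are analyzed on the correlation scale; "r" covers both Pearson
correlations and biserial correlations (`r_bis`), which are *not* Fisher
Z-transformed because the two families require different transformations and
cannot be mixed on the Z scale. `fisher_z_guard()` enforces this as a hard
error; a homogeneous Pearson dataset may still be Z-transformed for
sensitivity runs.

**Biserial from means/SDs/n.** The chain is d → point-biserial → biserial:
\[
d = \frac{\bar x_D - \bar x_L}{s_p},\qquad
s_p = \sqrt{\frac{(n_L-1)SD_L^2 + (n_D-1)SD_D^2}{n_L+n_D-2}},\qquad
r_{pb} = \frac{d}{\sqrt{d^2 + h}},\qquad
r_{bis} = r_{pb}\frac{\sqrt{pq}}{\varphi(\Phi^{-1}(p))},
\]
with \(p = n_D/(n_D+n_L)\). Two conventions for \(h\) exist in the
literature: the asymptotic \(h = 1/(pq)\) and the small-sample
\(h = m/n_D + m/n_L\) (\(m = n-2\)) used by `metafor::escalc(measure =
"RBIS")`. The default is the asymptotic form; `small_sample = TRUE`
reproduces `escalc()` bit-for-bit and is cross-checked against it in the
test suite. The sampling variance is Soper's large-sample biserial variance
in both modes (the paper trail for many published datasets does not state a
variance convention, so this one is declared here and documented in code).
Biserial estimates can legitimately exceed |1| in finite samples; they are
propagated unclipped, and downstream code never assumes |r| ≤ 1.

**The "buggy" variant.** `std_mean_diff(..., variant = "buggy")` reproduces
a parentheses-slip in which only the dark-group sum of squares is divided by
the pooled degrees of freedom:
\(s_{buggy} = \sqrt{(n_L-1)SD_L^2 + (n_D-1)SD_D^2/(n_L+n_D-2)}\). Since
\(s_{buggy} \ge s_p\) always (for \(n_L+n_D-2 > 1\)), the buggy |d| — and
hence the buggy biserial — is systematically deflated. The variant exists so
that datasets computed with the erroneous code can be audited and
reproduced; `simulate_rbis_comparison()` packages the two-group comparison
study (defaults: dark N(2.40, 0.80²) vs light N(2.25, 0.75²), n = 10 per
group, 10,000 replicates; 70 per group is the observed maximum group size
and is the standard alternative setting). The replicate count of the
original comparison is not published, so quantitative agreement is asserted
only up to Monte-Carlo tolerances; the ordering buggy < fixed (mean and SD)
is deterministic in direction and asserted strictly.

**t, F, chi-squared.** \(r = t/\sqrt{t^2+df}\) (sign carried);
\(\eta^2 = F\,df_1/(F\,df_1+df_2)\) with \(|r| = \sqrt{\eta^2}\), valid for
omnibus multi-df F; Cramér's \(V = \sqrt{\chi^2/(n(\min(r,c)-1))}\) for
r×c tables. F- and χ²-derived magnitudes are inherently unsigned:
`assign_sign()` attaches the reported direction, flips it first for
reversed-scale traits (e.g., latency, where larger values mean *less*
aggression), and flags unknown directions. Flagged effects are excluded
from fits by default — defaulting them to positive is a documented source
of inflated pooled effects — but `keep_unsigned = TRUE` retains them at
+magnitude to reproduce legacy behavior for comparison runs.
`sign_distribution_audit()` tabulates percent-positive per origin and warns
when unsigned origins exceed signed origins by more than 25 percentage
points (configurable), the signature of default-positive extraction.

**Variance conventions.** For t-, F- and V-derived effects the r-scale
large-sample variance \((1-r^2)^2/(n-1)\) is used. Sample correlations of
exactly |1| (a perfect-association 2×2 table does occur in small samples)
would receive zero variance and infinite weight; the variance is floored at
its |r| = 0.99 value. Effective sample sizes for precision moderators use
\(\tilde n = 4n_1n_2/(n_1+n_2)\) for two-group designs and n otherwise.

## Phylogenetic correlation

Trees are read from Newick (polytomies allowed, basal polytomies treated as
a rooted star; duplicate tips are an error). Grafen branch lengths set each
node's height to (descendant tips − 1), rescaled so the root is at height 1
— the exponent `power` defaults to 1, the cited method's own convention,
since published analyses in this literature rarely state it. The resulting
tree is ultrametric with unit depth, and the correlation between two species
is their shared root-to-MRCA depth. Species matching between data and tree
is case-insensitive with spaces and underscores equivalent; unmatched
species are a hard error, never a silent drop (silent drops change k).
Near-singular matrices can be ridged with an explicit `jitter` flag
(default 0).

## The multilevel REML model

With effects \(y\) and design matrix \(X\),
\[
\Sigma(\sigma^2) = M + \sigma^2_{study} S + \sigma^2_{species} G +
\sigma^2_{phylo} Z A Z^\top + \sigma^2_{unit} I ,
\]
where M is the within-study sampling VCV with
\(M_{ij} = \rho\sqrt{v_iv_j}\) for same-study pairs (ρ = 0.5 by default; M
is positive definite for ρ < 1), S and G are same-study and same-species
indicators, and A the phylogenetic correlation. The REML log-likelihood
\(-\tfrac12[(k-p)\log 2\pi + \log|\Sigma| + \log|X^\top\Sigma^{-1}X| +
r^\top\Sigma^{-1}r]\) is evaluated by Cholesky factorization with jitter
escalation (0 → 1e-10 → 1e-8 → 1e-6) on factorization failure, and
maximized over log-variances by L-BFGS-B with analytic scores
\(-\tfrac12[\mathrm{tr}(PG_j) - y^\top P G_j P y]\). Three deterministic
starting points are used (equal split of the excess variance, a unit-heavy
split, and a near-boundary start); deterministic starts rather than random
ones keep fits bit-reproducible without touching the user's RNG state.
Components converging below 1e-8 are reported as exactly 0 (boundary
estimates are common); convergence uses `factr = 1e3` and `pgtol = 1e-7`.
The likelihood omits the data-independent \(+\tfrac12\log|X^\top X|\)
constant some implementations add, which matters only when comparing
absolute log-likelihood values across software.

Inference is Wald-type with a normal reference by default; published
analyses in this area report z-style CIs and p-values without stating the
reference distribution, and the normal default reproduces the magnitude of
such intervals. A t reference with k − p degrees of freedom is available as
a sensitivity flag (`inference = "t"`), and is slightly more conservative at
small k. The species/phylogeny variance split is weakly identified when the
phylogenetic signal is modest — only their sum is reliably estimated (the
test suite asserts exactly this exchangeability with an identity A); totals
(Σσ², I²_total, prediction intervals) are therefore the primary summaries.

Missing moderator values are handled by listwise deletion with a logged
count, never imputation.

## Heterogeneity and small-study effects

The typical sampling variance is \(\bar v = (k-1)\sum w/((\sum w)^2 -
\sum w^2)\), \(w = 1/v\), computed from the diagonal variances only
(ignoring the VCV off-diagonals, the convention of the multilevel-I²
literature). Then \(I^2_{level} = 100\,\sigma^2_{level}/(\sum\sigma^2 +
\bar v)\); the level shares sum to the total exactly. The 95% prediction
interval is \(\hat\beta \pm z_{.975}\sqrt{SE^2 + \sum\sigma^2}\) (t
optionally), and always contains the CI. For meta-regressions,
\(R^2_{marginal} = 100\,\mathrm{var}(X\hat\beta)/(\mathrm{var}(X\hat\beta) +
\sum\sigma^2)\).

`small_study_test()` fits the full phylogenetic multilevel meta-regression
with a precision moderator; the slope measures funnel asymmetry and the
intercept is the bias-adjusted mean (the extrapolation to infinite
precision). Two moderator families are first-class because published runs
label the slope either way: `inv_sqrt_n_eff` (\(\sqrt{1/\tilde n}\)) and the
SE variants (`se_of_r`, `se_of_z`). The package endorses neither — the SE of
Zr in particular sits awkwardly beside the no-Z-mixing rule — so the choice
is explicit and recorded in the result.

## The synthetic-data generator

`synthetic_config()` defaults encode the structure of the re-analyzed
dataset: 74 studies, 54 species, 1–4 effects per study (~170 effects),
per-group sizes uniform on 10–70 (the dataset's first quartile and maximum),
grand mean 0.218, and variance components (study 0.027, species 0.008,
phylogeny 0.047, unit 0.091) whose total 0.174 and relative shares match the
reported heterogeneity decomposition. The origin mixture (15/25/25/20/15%
for r/means/t/F/χ²) approximates the dataset's composition.

Raw statistics are generated so that each origin's *conversion output* is
centred on that effect's true correlation: means rows invert the biserial
chain, t/F rows invert the point-biserial, and 2×2 tables invert the
dichotomized-bivariate-normal φ (latent correlation \(\sin(\pi\rho/2)\)).
True correlations are clamped to [−0.97, 0.97] before data generation (the
clamp count is recorded in the truth sidecar). F effects are generated from
two-group layouts only (df1 = 1) and χ² from 2×2 tables only; the
*converters* handle multi-df F and larger tables, but the generator does
not produce them.

What the generator deliberately does **not** emulate: extraction errors and
sign mistakes (directions are always reported faithfully from the sample),
publication selection (the bias tests inject small-n censoring explicitly),
multi-species studies (each synthetic study observes one species),
unbalanced group sizes, and real phylogenies (topologies are random
sequential joins). Passing recovery tests therefore demonstrates that the
*pipeline* is unbiased and calibrated under its own assumptions — not that
any real dataset is free of the extraction pathologies the audit tools are
designed to surface.

## Problem sizes and test calibration

The stochastic suites run at sizes chosen to keep the default test run
quick while preserving the study's structure: likelihood-oracle comparisons
use k ≤ 15 with two variance components against a two-stage grid search;
recovery runs 200 replicates at 24 studies / 16 species (~60 effects);
funnel-slope coverage runs 200 replicates at the full 74-study / 54-species
scale, where the z-reference coverage is nominal (at k ≈ 60 it dips a point
or two below — the usual small-k anticonservatism of Wald intervals with
estimated variance components). The biserial comparison study uses 20,000
replicates. Single-replicate pooled estimates can sit far from the grand
mean because one draw of the phylogenetic effects shifts every species
together; recovery is therefore asserted on medians across replicates.

## Known limitations

- Biserial effects beyond |1| are supported end-to-end, but their Soper
  variance is evaluated with the estimate truncated to |1|, so extreme
  estimates are modestly over-weighted.
- The species/phylogeny variance split is reported as estimated even where
  only the sum is identified; interpret the split cautiously.
- No trim-and-fill, selection models or p-curve: small-study effects are
  assessed only by precision-moderator meta-regression.
- The Fisher-Z guard blocks the Pearson/biserial mix specifically; datasets
  mixing other origins remain on the raw r scale by design.
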