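---
title: "Methods: correlation-aware MR and directional triangulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-aware MR and directional triangulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriangle)
```

## The problem

Plasma metabolites and proteins are attractive intermediates for cardiac
drug development: metabolites index the myocardial energy state, and
proteins are the units drugs act on. `mrtriangle` implements a two-sample
Mendelian randomisation (MR) workflow that screens metabolite effects on
cardiac outcomes genome-wide, screens protein effects on those metabolites
and on the outcomes with cis instruments, and then *triangulates*: a
protein is prioritised only when its effects on a metabolite and on an
outcome are directionally consistent with the metabolite's own effect on
that outcome. The surviving proteins are annotated with cardiac expression
and druggability, tested for pathway enrichment, and re-examined in
independent proteomic studies.

## The estimators

For an exposure with harmonised per-variant effects $\hat\beta_{Xj}$ and
outcome effects $\hat\beta_{Yj}$ with standard errors $\sigma_j$, and a
signed instrument-correlation (LD) matrix $R$, the generalised least
squares (GLS) implementation of the inverse-variance-weighted (IVW)
estimator solves

$$\hat\theta = (X^\top \Omega^{-1} X)^{-1} X^\top \Omega^{-1} y,
\qquad \Omega = D R D,\; D = \mathrm{diag}(\sigma_j),$$

with $X$ the column of exposure betas (IVW, regression through the origin)
or `[1, x]` (the Egger correction, whose free intercept absorbs
directional horizontal pleiotropy). Standard errors come from
$(X^\top\Omega^{-1}X)^{-1}$; heterogeneity is
$Q = r^\top\Omega^{-1}r$. Working in the whitened coordinates
$L^{-1}X$ (with $\Omega = L L^\top$) the fit is ordinary least squares, so
the hat-matrix diagonal is a proper leverage (entries in $[0,1]$, summing
to the number of parameters) and the squared whitened residuals decompose
$Q$ additively per variant. These two diagnostics drive pruning:

* leverage larger than `leverage_factor` (3) times the mean leverage, and
* outlier statistic (squared standardised residual) larger than
  `outlier_cut` = 10.83, the $\chi^2_1$ 0.999 quantile,

are removed as a union, the model refit, and the procedure iterated to
convergence (capped at 10 rounds). The statistics are recomputed from the
IVW fit each round; whether pruning should instead use the finally
selected model is genuinely open, and the IVW-based choice is the
deterministic one we document.

Model selection follows the heterogeneity-difference rule: the Egger model
is chosen iff $Q_\mathrm{IVW} - Q_\mathrm{Egger}$ exceeds the
$\chi^2_1$ upper-$\alpha$ quantile (3.841 at $\alpha = 0.05$; the
framework is usually cited without an explicit level, and 0.05 is our
fixed choice). The models are nested, so the difference is non-negative by
construction and a materially negative value raises an internal error
rather than being clipped.

Inference uses normal reference distributions, the convention for
summary-statistic MR, and 95% intervals use 1.96 verbatim rather than the
exact quantile so that printed odds-ratio intervals round-trip at two
decimals. Binary outcomes are reported as odds ratios by exponentiating
the slope and its Wald limits; continuous outcomes as mean differences.

## Instrument rules

* **Strength and frequency.** F statistic $(\hat\beta/\mathrm{se})^2 \ge
  24$ and minor allele frequency $\min(\mathrm{eaf}, 1-\mathrm{eaf}) \ge
  0.01$, both boundaries inclusive. The folding is the only coherent
  reading of "minor allele frequency" for an effect-allele frequency.
* **Cis window.** For protein exposures, variants within the gene body
  plus 200 kb on each side (closed interval, 1-based coordinates).
  "A 200-kb window surrounding the gene" is ambiguous between total width
  and per-side flank; we adopt the per-side reading used in drug-target MR
  practice and expose `flank` as a knob.
* **Clumping.** Greedy at $r^2 > 0.3$: repeatedly retain the remaining
  variant with the smallest exposure p-value (ties broken
  lexicographically on the variant id for determinism) and drop everything
  correlated above threshold with it.
* **Harmonisation.** Outcome records are aligned to the exposure allele
  coding; swapped alleles flip the outcome beta sign, palindromic (A/T,
  C/G) variants with folded frequency above 0.42 in either sample are
  dropped, and mismatched allele sets are dropped. The 0.42 cutoff is the
  standard two-sample default. The LD matrix is treated as aligned to the
  exposure coding (exposure data are pre-aligned to the LD reference, as
  in practice); if it is supplied in outcome coding,
  `harmonize(ld_coding = "outcome")` flips the sign of $r$ for flipped
  variants.
* **Pipeline order.** filter &rarr; cis window &rarr; harmonise &rarr;
  clump; whether the original analyses clumped before or after
  intersecting with the outcome study is unstated, and this order is our
  fixed, documented choice. Analyses reaching any stage with fewer than
  `min_variants` = 6 variants are *discarded*: no estimate is reported.

## Thresholds, triangles and downstream annotation

Stage thresholds are exact Bonferroni values $\alpha/(m_\mathrm{exposures}
\times m_\mathrm{outcomes})$; the one-significant-figure values (7e-5,
9e-7, 2e-5 for the 174x4, 1567x36 and 686x4 designs) are used for
*reporting only*, because filtering at the rounded value would be more
lenient than $\alpha/m$. A triangle (protein $P$, metabolite $M$, outcome
$D$) survives when all three edges pass their thresholds and
$\mathrm{sign}(\beta_{PM}) \cdot \mathrm{sign}(\beta_{MD}) =
\mathrm{sign}(\beta_{PD})$, with signs taken on the log-odds /
mean-difference scale (never the OR scale, where the null is 1, not 0).
Proteins reaching two or more distinct outcomes are flagged pleiotropic.
When a protein appears in several proteomic GWAS, the largest sample size
study is the primary source (ties broken lexicographically) and the rest
serve as replication: a protein-outcome association replicates nominally
with the same direction and $p < 0.05$, conservatively at $p <
0.05/n_\mathrm{tested}$.

Enrichment uses the Wald proportion comparison: with $\hat p_1$ the
proportion of prioritised proteins in a pathway and $\hat p_0$ the
proportion among all tested (background) proteins,
$z = (\hat p_1 - \hat p_0)/\sqrt{\hat p_0(1-\hat p_0)/n_1}$ against a
standard normal. The procedure's second step is described in the source
methodology as a "total number" while its third step tests a difference of
proportions; the background *proportion* is the only reading under which
that test is defined, and it is what we implement (prominently noted
here). The null-proportion standard error is the default; a pooled
variant sits behind `se_method = "pooled"`, and the test is two-sided by
default with a one-sided option. Cardiac expression uses abundance > 0 by
default (configurable minimum), and overexpression is a one-sided z of
the cardiac abundance against the mean and SD of the other 60 tissues —
a provisional screening statistic, since published analyses of this kind
defer the exact test to supplementary material.

## The synthetic-data generator

No individual-level data or external GWAS are bundled; every test runs on
simulated summary statistics with known truth. The generative model is

$$\hat\beta_{Xj} = b_j + e_j,\; e_j \sim N(0, 1/n_X), \qquad
\hat\beta_{Yj} = \theta b_j + \alpha_j + \epsilon_j,\;
\epsilon \sim N(0, \sigma_Y^2 R),$$

with $b_j \sim U(0.1, 0.3)$, $\sigma_Y^2 = 1/n_Y$, exposure and outcome
noise drawn independently (two-sample independence), and pleiotropy
$\alpha_j$ either absent, balanced ($N(0, \tau^2)$) or directional
($N(\mu, \tau^2)$). Exposure betas are treated as fixed at their true
values plus estimation noise, and the outcome-noise covariance is exactly
$\sigma_Y^2 R$ — the model the GLS estimator assumes, which is what makes
the calibration experiments sharp. LD is block AR(1) (blocks of 5,
$\rho = 0.5$ by default, giving adjacent $r^2 = 0.25$, just under the 0.3
clumping threshold); alleles are drawn from {A, C, G, T} and 10% of
outcome-table records are deliberately coding-flipped to exercise
harmonisation.

Default sample-size proxies are the study conditions we simulate
throughout: $n_X = 86{,}507$ (the scale of the largest metabolite GWAS)
and $n_Y = 6{,}639$, the effective sample size $4/(1/\mathrm{cases} +
1/\mathrm{controls})$ of a dilated-cardiomyopathy GWAS with 2,719 cases
among 6,980 participants. The model-selection experiment instead uses an
outcome proxy of 2,500 (outcome-beta SE 0.02, matching the pleiotropy SD
of 0.02 at $\mu = 0.05$): per-variant pleiotropic effects comparable to
the outcome standard errors are the realistic regime in which pleiotropy
must be caught by the Egger intercept rather than trivially removed as
single outliers. These choices were fixed as experimental design, with the
experiment sizes below.

What the generator does **not** emulate: realistic MAF spectra or
MAF-dependent effect sizes, genome-wide scale, LD estimated with error
from a finite reference panel, sample overlap between exposure and
outcome, winner's-curse selection of instruments, or binary-trait
liability-scale subtleties (outcome effects are simulated directly on the
log-odds scale with Gaussian error). Passing calibration here therefore
shows the estimators and plumbing are correct under their stated model,
not that real cardiac GWAS meet that model.

The end-to-end fixture (`simulate_study()`) plants a complete study: six
metabolites (one null), eight proteins with cis loci on separate
chromosomes, two binary outcomes, a protein with only five cis variants
(exercising the discard rule), a protein whose direct disease effect
opposes its mediated path (exercising the concordance screen), and
cross-contamination by construction — each metabolite GWAS contains every
protein's cis variants, so discordant pQTL signals must be removed by the
outlier pruning for stage 1 to recover the planted slopes. Seven
concordant triangles follow from the planted effect matrices by
exhaustive enumeration.

## Numerical choices and degenerate inputs

* $\Omega$ gets a $10^{-8}$ ridge on the diagonal of $R$ before the
  Cholesky factorisation; clumping at $r^2 = 0.3$ deliberately leaves
  correlated instruments, and a matrix that still fails to factor raises
  an "ill-conditioned LD" error instead of silently pseudo-inverting.
* IVW needs at least 2 variants, Egger at least 3; both are moot under the
  default `min_variants = 6`.
* A zero effect has undefined direction: concordance on a zero sign is an
  error, and triangle assembly excludes zero slopes.
* Degenerate enrichment backgrounds ($\hat p_0 \in \{0, 1\}$) return
  $p = 1$ with a `degenerate` flag rather than a division by zero.
* Zero total expression gives cardiac fraction 0; a zero-variance tissue
  background falls back to a direct mean comparison.
* All randomness flows through explicit seeds; identical configurations
  give byte-identical simulated tables and pipeline outputs.

## Experiment sizes

The calibration experiments are sized to be decisive yet quick on a single
CPU: 1,000 null datasets (type-I error, accepted in [0.03, 0.07]), 500
datasets at $\theta = 0.3$ with 100 variants (mean bias within 2
Monte-Carlo SEs; empirical 95% CI coverage in [0.92, 0.98]), 200 paired
datasets for the pleiotropy/model-selection contrast, 50 random 8-variant
instances for the brute-force GLS oracle (agreement to 10 significant
digits), and 100 random instances of up to 10 variants for the clumping
oracle. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

Beyond the generator's idealisations, the package does not implement
weighted-median or mode estimators, multivariable MR, Steiger filtering,
winner's-curse correction, colocalisation, proxy-variant lookup, or
mediation quantification along the triangles; triangulation is a sign
test, not an effect-size decomposition. Whether the metabolite and
protein edges of a triangle should be constrained to the same estimator
(IVW vs Egger) is unstated in the methodology this follows; edges enter
as selected by the heterogeneity-difference rule.
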