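# mrtriangle

Two-sample Mendelian randomisation (MR) with correlated instruments, and
directional triangulation of metabolite and protein effects for cardiac
drug-target prioritisation.

## What it does

Genetic variants act as natural randomisers: a variant that raises a
plasma metabolite or protein lets us ask whether people randomised by
genotype to higher levels also have more (or less) cardiac disease. This
package implements that workflow end to end from GWAS summary statistics:

1. **Instrument selection** — per-variant F statistic
   (β/se)² ≥ 24, minor allele frequency ≥ 0.01, greedy LD clumping at
   r² > 0.3, and (for proteins) a cis window of the encoding gene ± 200 kb.
2. **Estimation** — the generalised least squares (GLS) form of the
   inverse-variance-weighted (IVW) estimator,

   θ̂ = (XᵀΩ⁻¹X)⁻¹XᵀΩ⁻¹y,  Ω = D·R·D,

   with D the diagonal of outcome standard errors and R the signed LD
   correlation matrix, plus the MR-Egger variant with a free intercept
   that absorbs directional pleiotropy. Variants with leverage above three
   times the mean or a squared standardised residual above 10.83 (χ²₁
   0.999 quantile) are pruned iteratively; IVW vs Egger is decided by the
   Rücker heterogeneity difference Q_IVW − Q_Egger against χ²₁; analyses
   with fewer than 6 variants are discarded.
3. **Triangulation** — a protein is prioritised only when the signs of its
   effects on a metabolite, the metabolite's on an outcome, and its own on
   that outcome are consistent: sign(β_PM)·sign(β_MD) = sign(β_PD), with
   every edge past its exact Bonferroni threshold.
4. **Annotation & follow-up** — cardiac expression and overexpression
   flags, druggability joins, Wald proportion-based pathway and
   metabolite-class enrichment, and nominal (p < 0.05) / conservative
   (p < 0.05/n) replication in independent proteomic studies.

A seeded simulator (`sim_config()`, `simulate_mr_dataset()`,
`simulate_study()`) generates two-sample summary statistics with known
causal slope, LD-correlated noise and configurable pleiotropy, so the
whole pipeline is testable offline; see the methods vignette
(`vignettes/triangulated-mr-methods.Rmd`) for the model and every default.

## Worked example

```r
library(mrtriangle)

d <- simulate_mr_dataset(sim_config(n_variants = 50, causal_effect = 0.3, seed = 7))
res <- run_mr(d$exposure, d$outcome, d$ld, outcome_type = "binary")
res$result[, c("estimator", "n_variants", "slope", "se", "estimate",
               "ci_lower", "ci_upper", "p_value")]
#>  estimator n_variants     slope         se estimate ci_lower ci_upper      p_value
#>        IVW         46 0.3021064 0.01142697 1.352705 1.322746 1.383343 5.01287e-154
```

The simulator planted a causal slope of 0.3 on the log-odds scale; after
harmonisation dropped 4 ambiguous palindromic variants, the GLS-IVW fit on
the remaining 46 recovers 0.302 (se 0.011) and reports it as an odds ratio
of 1.35 (95% CI 1.32–1.38) per unit of exposure.

```r
bonferroni_threshold(0.05, 174, 4)$threshold_reported
#> [1] 7e-05
```

For the full study flow, `analysis/` contains numbered drivers:
`01_simulate_study.R` writes a planted six-metabolite / eight-protein /
two-outcome study under `results/toy_study`; `02_run_pipeline.R` runs the
three MR screening stages, triangulation, annotation, enrichment and
replication (`results/pipeline`); `03_triangulation_report.R` prints the
seven concordant triangles and their annotation; `04_calibration.R` runs
the Monte-Carlo calibration (type-I error 0.041 over 1000 null datasets,
mean recovered slope 0.3000 with 95% CI coverage 0.950 over 500 datasets,
Egger selected 2.5% vs 89.5% of the time without vs with directional
pleiotropy).

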