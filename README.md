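# markstrat

Stratify tumor cohorts by a bimodally expressed marker gene, compare
disease-free survival between the resulting strata, and map the marker's
co-expression neighborhood across cohorts.

Many putative prognostic markers are expressed in an on/off fashion: an
activity score (a per-sample probability of expression in [0,1], such as a
UPC score) is near 0 for most tumors and near 1 for a minority. **markstrat**
turns that bimodality into an analysis pipeline:

- **Thresholding.** Per cohort, the marker's score density is estimated with
  a Gaussian kernel and the cut-point is the valley between the two tallest
  peaks; cohorts are pooled by the sample-size-weighted mean of their
  valleys, `c = Σ mᵢNᵢ / Σ Nᵢ`. When no valley exists (e.g. FPKM-UQ
  intensities), a two-Gaussian mixture is fitted by EM and the cut is placed
  where the weighted component densities reach a target ratio
  (`w₁φ₁(x)/(w₂φ₂(x)) = r`, with r = 1 or r = 0.10). Scores ≥ threshold are
  "high".
- **Survival.** First-principles Kaplan–Meier (`S(t) = Π (1 − dⱼ/nⱼ)`) and
  Mantel–Haenszel log-rank test (`χ² = U²/V` on 1 df), plus risk tables and
  a per-gene screen with a valley → mixture → median dichotomization chain.
- **Co-expression.** Tie-corrected Spearman correlations with BH-FDR,
  signed-p matrices `s = sign(r_s)·(1 − p)`, and cross-cohort **max-rank
  aggregation**: each gene is ranked per cohort by descending r_s, its
  statistic is its worst rank across cohorts, and the top-k of the ascending
  sort is selected.
- **Associations.** Wilcoxon / Kruskal–Wallis / Pearson tests of marker
  expression against clinicopathological covariates.
- **Synthetic cohorts.** A generator producing bimodal [0,1] marker scores,
  genes rank-correlated with the marker at a target Spearman ρ, and
  right-censored exponential survival with stratum-dependent hazard — so the
  whole pipeline is testable offline.

## Worked example

```r
library(markstrat)

cohorts <- generate_multi_cohort(
  lapply(c(226, 145, 557), function(n)
    cohort_config(n_samples = n, n_genes = 60, module_genes = 20, seed = 7)),
  shared_truth = TRUE)
entries <- lapply(names(cohorts), function(a)
  list(alias = a, cohort = cohorts[[a]]))
bundle <- run_pipeline(pipeline_config(entries, marker = "MARKER",
                                       k = 5, seed = 7))

bundle$threshold
#> <threshold_estimate> 0.525725 (pooled_valley)
bundle$stratification
#>    cohort high low total percent_high
#> 1 cohort1   47 179   226         20.8
#> 2 cohort2   36 109   145         24.8
#> 3 cohort3  155 402   557         27.8
#> 4   Total  238 690   928         25.6
bundle$per_cohort$cohort1$logrank
#> <logrank> chi^2 = 6.705 (1 df), p = 0.009612
head(bundle$correlation, 3)
#>     gene r_s.cohort1 fdr.cohort1 r_s.cohort2 fdr.cohort2 r_s.cohort3 fdr.cohort3 max_rank
#> 1 MOD014       0.490    6.83e-14       0.479    1.28e-08       0.490    3.22e-33        5
#> 2 MOD009       0.553    9.45e-18       0.456    6.11e-08       0.482    1.08e-32        8
#> 3 MOD018       0.461    1.78e-12       0.521    3.78e-10       0.476    6.54e-32        9
```

Reading the output: the pooled density valley lands at 0.526 (the analytic
valley of the generating mixture is 0.519), about a quarter of the 928
samples are marker-high, the marker-high stratum has significantly longer
disease-free survival in every cohort (the generator's hazard ratio is 2),
and the top genes by max-rank aggregation are module genes built to
correlate with the marker at Spearman ρ ≈ 0.45.

A command-line interface wraps the same stages
(`simulate`, `stratify`, `survive`, `coexpress`, `associate`, `run`):

```sh
Rscript -e 'markstrat::markstrat_cli()' simulate --out data/ --seed 7
Rscript -e 'markstrat::markstrat_cli()' stratify \
  --expression data/cohort1_expression.tsv --marker MARKER --activity \
  --out strata.tsv
```

## Layout

- `R/synthetic.R` — cohort simulator (mixture marker, copula module genes,
  exponential survival)
- `R/io.R` — TSV expression/clinical readers-writers, GMT gene sets, cohort
  harmonization
- `R/stratify.R` — density valley, pooled thresholds, EM mixture, ratio
  crossings, classification
- `R/survival.R` — Kaplan–Meier, log-rank, risk tables, per-gene screen
- `R/coexpression.R` — Spearman, BH-FDR, signed-p matrices, max-rank
  aggregation
- `R/association.R` — covariate tests and panels
- `R/pipeline.R`, `R/cli.R` — orchestration, report tables, manifest, CLI

See `vignettes/marker-stratification.Rmd` for the methods, parameter
defaults, and design rationale.
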