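---
title: "Stratifying cohorts by a bimodal marker: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying cohorts by a bimodal marker: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markstrat)
```

## The problem

A gene whose expression is bimodal across tumors — most samples essentially
silent, a minority clearly active — invites a natural prognostic question:
do the "marker-high" patients fare differently from the "marker-low" ones?
Answering it requires three ingredients that **markstrat** implements as
separable, individually testable modules:

1. a defensible cut-point on the expression scale (the *stratification*
   module),
2. a comparison of disease-free survival between the resulting strata (the
   *survival* module), and
3. a characterization of the marker's co-expression neighborhood across
   several cohorts (the *coexpression* module), plus association tests
   against clinicopathological covariates (the *association* module).

The package is written for activity-score data (per-sample expression
probabilities in $[0,1]$, e.g. UPC output), continuous log2 intensities
(RMA-like), and upper-quartile-normalized RNA-seq units (FPKM-UQ). A
synthetic-data module generates multi-cohort data with exactly the
structure the analysis assumes, so every stage can be validated offline.

## Thresholding a bimodal score

### Density-valley method

For each cohort the marker's scores are smoothed with a Gaussian kernel
(bandwidth: Silverman's rule-of-thumb, `bw.nrd0`) on a fixed 512-point grid
spanning `[min - 3h, max + 3h]`, clipped to $[0,1]$ for activity scores and
renormalized so the trapezoid integral is one. The per-cohort threshold is
the grid point of minimum density strictly *between the two tallest strict
local maxima*; the cross-cohort threshold is the sample-size-weighted mean
of the per-cohort valleys,

$$ c = \frac{\sum_i m_i N_i}{\sum_i N_i}. $$

Peak selection is deliberately pinned down: when more than two maxima tie
for the top heights, the two most separated are used; a unimodal density is
an explicit error rather than a guessed cut, and the pipeline then falls
back to the mixture method below. Classification is inclusive on the high
side: a score exactly equal to the threshold is "high".

The kernel bandwidth is a genuine tuning parameter. With the rule-of-thumb
bandwidth the estimated valley carries a bias of order the grid step plus
smoothing error; the recovery experiments in the test suite (three cohorts
of 226/145/557 samples, component means 0.2/0.8, sd 0.1) show the pooled
valley lands within ±0.05 of the analytic mixture valley in well over 95%
of seeds.

### Gaussian-mixture method

When no visible valley exists (typical for heavy-tailed RNA-seq
intensities), a two-component univariate Gaussian mixture is fitted by EM:

- initialization at the 25th/75th percentiles with the pooled standard
  deviation and equal weights;
- convergence when the relative log-likelihood change falls below
  $10^{-8}$ (at most 500 iterations); the log-likelihood trace is retained
  and is non-decreasing by construction;
- a collapsing component ($\sigma \to 0$) triggers a jittered restart, with
  an error after five restarts;
- components are relabeled after fitting so $\mu_1 < \mu_2$.

The cut-point is the smallest $x \in [\mu_1, \mu_2]$ where the weighted
component-density ratio $w_1 \phi_1(x) / (w_2 \phi_2(x))$ equals a target
ratio, located by bisection to $10^{-8}$. Ratio 1 is the equal-density
crossing; ratio 0.10 places the cut where the low component retains only
10% of the high component's density, a deliberately conservative "high"
call. For equal weights and equal $\sigma$ the closed form
$x = (\mu_1+\mu_2)/2 + \sigma^2 \ln r / (\mu_1 - \mu_2)$ is used as a test
oracle. Mixture fitting for FPKM-UQ-like data should be done on
$\log_2(x+1)$ values; raw FPKM-UQ is heavy-tailed enough that a
two-Gaussian fit is a poor description of the raw scale.

## Survival comparison

The Kaplan–Meier estimator and the Mantel–Haenszel log-rank test are
implemented from first principles so that both can be checked against
brute-force oracles (and, in the test suite, against the `survival`
package, which they match to machine precision). Conventions: right
censoring only; at tied times events precede censorings (a censored sample
with the same recorded time is still at risk); the log-rank variance uses
the hypergeometric form without continuity correction; the p-value comes
from $\chi^2_1$.

The asymptotic p-value is a large-sample quantity. At $n \le 10$ it
deviates from the exact label-permutation p-value by several percentage
points — an inherent property of the approximation, not an implementation
defect (the statistic itself is identical to `survival::survdiff`'s). The
calibration that matters in practice, the type-I error at nominal 5% with
100 samples per group, is verified to hold within ±1.5%.

The per-gene survival screen dichotomizes each gene with a fallback chain —
density valley, then equal-ratio mixture crossing, then median split — and
records which method was used for every gene. The chain is this package's
design choice: no published convention exists for screening thousands of
genes whose distributions range from cleanly bimodal to unimodal, and the
chain degrades gracefully while keeping provenance. A gene whose dichotomy
leaves a stratum empty is reported as not assessable rather than dropped
silently. Genes significant (log-rank $p < 0.05$) in at least two cohorts
are flagged.

## Co-expression neighborhood

Spearman correlations are computed as Pearson correlations of average
ranks (tie-corrected). P-values use the $t$ approximation with $n-2$
degrees of freedom; for $n \le 8$ without ties the exact permutation
distribution is enumerated instead. (Full enumeration to $n = 10$ — up to
3.6 million permutations — was judged too slow for a screening routine in
pure R; at $n = 9, 10$ the $t$ approximation is already accurate to a few
thousandths.) Correlations are computed on continuous intensities, never on
$[0,1]$ activity scores.

Multiple testing is controlled with the Benjamini–Hochberg step-up
procedure (monotonicity enforced, capped at 1), implemented directly and
validated against an independent step-up oracle.

Cross-cohort gene prioritization uses **max-rank aggregation**: within each
cohort genes are ranked in descending order of their correlation with the
marker; each gene's representative statistic is its *worst* rank across
cohorts; the top-$k$ list is the head of the ascending sort of that
statistic. Ties in $r_s$ get competition ranks with a lexicographic
gene-id tie-break, which keeps every cohort's ranks an exact permutation of
$1..G$ — average ranks would not — and makes the aggregation deterministic
and cohort-order invariant. Genes absent from any cohort are dropped before
ranking. The same machinery restricted to an externally determined
interactome gene set gives the "top partners" list ($k = 20$ by default).

For heatmap-style rendering the package computes the signed-p statistic
$s = \mathrm{sign}(r_s)\,(1 - p)$ pairwise; the diagonal is $+1$ by the
convention $r = 1, p \to 0$, and constant genes produce 0 entries with a
warning.

## Covariate associations

Dispatch follows covariate arity: two categories → Wilcoxon rank-sum
(statistic reported as the group-1 rank sum; normal approximation with tie
correction, no continuity correction), more than two → Kruskal–Wallis
(tie-corrected, $\chi^2_{k-1}$), continuous → Pearson correlation with the
$t$ test. Ordered stage-like categories are treated as unordered — a trend
test would be more powerful, but the unordered treatment matches the
analysis this package reproduces. Panel-level BH adjustment is emitted
alongside raw p-values.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces, per cohort:

- a marker activity score from a two-component Gaussian mixture *truncated
  to $[0,1]$* (truncation rather than a beta family, so the analytic
  mixture density and its valley are available in closed form for truth
  records);
- a module of genes rank-correlated with the marker via a shared latent
  variable: the marker's normal scores are blended with independent noise
  using the $2\sin(\pi\rho/6)$ Pearson-from-Spearman conversion, so the
  empirical Spearman correlation targets `module_rho` regardless of the
  marker's marginal;
- background genes as i.i.d. standard Gaussians;
- exponential survival with stratum-specific hazard, censored by an
  independent exponential time and an administrative cutoff.

Defaults encode the stated study world: mixture weight 0.267, component
means 0.2/0.8 with sd 0.1, three-cohort sizes 226/145/557, module
$\rho = 0.45$ (the scale of the strongest observed co-expression), hazards
0.15 and 0.075 per year (hazard ratio 2 favoring marker-high), censoring
rate 0.05/year, follow-up capped at 12 years. Where the emulated study
prints no value (gene counts, censoring, follow-up), values were chosen
once to be realistic for colon-cancer expression cohorts and are not tuned
against test outcomes.

A green test on synthetic data establishes that the algorithms do what
their definitions say under the stated statistical structure. It does
*not* establish robustness to what the generator deliberately omits: batch
effects, probe-level noise, non-exponential hazards, informative censoring,
correlated background genes, or platform differences between cohorts.

Seeding is hierarchical: each cohort's stream is derived from its config
seed and position, so a singleton run reproduces `generate_cohort()`
exactly and appending cohorts never perturbs earlier ones.

## Numerical choices and degenerate inputs

- Density curves are renormalized after grid clipping; the trapezoid
  integral is kept within $1 \pm 0.01$.
- `classify()` excludes samples with missing scores, with a logged count;
  high + low + missing always partitions the input.
- EM works in log space (log-sum-exp) to avoid underflow at extreme
  observations.
- TSV writers emit doubles with `%.17g`, so write/read round trips are
  exact.
- All fallbacks (probe selection by variance, threshold fallback to the
  mixture method, dropped samples or categories, capped $k$) are structured
  lines in the run manifest.

## Known limitations

- No Cox regression, multivariable adjustment, or competing risks; the
  survival module covers exactly KM + log-rank.
- The valley method needs a genuinely bimodal density; near-equal component
  means with large overlap will (correctly) refuse and fall back.
- Max-rank aggregation is sensitive to a single discordant cohort by
  design — that is what "worst rank" means; it is not a robust consensus
  statistic.
- Exact Spearman p-values are enumerated only to $n = 8$; below-tie-free
  $n = 9, 10$ the $t$ approximation is used.
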