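---
title: "Methods: IFN scores and multi-omics association in trisomy 21 cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IFN scores and multi-omics association in trisomy 21 cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnscore)
```

## The model

Trisomy 21 elevates interferon (IFN) signaling chronically; the package
summarizes each sample's IFN tone as a composite of interferon-stimulated
gene (ISG) expression. Writing $x_{gs}$ for the covariate-adjusted log2
expression of gene $g$ in sample $s$, and $\mu_g, \sigma_g$ for the mean
and sample SD of the euploid-control samples, the score is

$$\mathrm{score}(s) = \sum_{g \in S} \frac{x_{gs} - \mu_g}{\sigma_g},$$

a sum of control-referenced z-scores over a signature set $S$. The
construction makes three assumptions worth keeping in view:

1. **The control group defines the null.** Scores are on the scale of
   control-SD units; the control cohort mean is 0 by construction and a
   score of $+|S|$ means "one control SD above typical on every signature
   gene". External samples (a longitudinal subject, a second cohort) must
   be scored against a *frozen* reference (`reference_stats()` /
   `write_reference_stats()`), never against their own draws.
2. **Additivity.** Genes contribute independently and equally after
   standardization. No gene weighting is attempted; the signature's genes
   are strongly co-regulated, so weighting adds little beyond noise.
3. **Scale.** z-scores are computed on adjusted `log2(RPKM + 0.5)` by
   default. On the linear scale, per-gene SDs are dominated by the
   right tail, letting a few high-expression samples carry the score;
   the log scale makes the Gaussian reference summary defensible.
   `score_cohort(log2_scale = FALSE)` provides the linear-scale reading
   for comparison.

### Signature derivation

The signature is data-derived, not fixed: `differential_expression()`
fits, per gene, an ordinary linear model on `log2(RPKM + 0.5)` with
karyotype, age and sex, and `select_isg_signature()` keeps genes with
linear fold change $\geq$ 1.5 (elevated only), BH $q < 0.1$, ISG
annotation, and chromosome $\neq$ chr21. chr21 ISGs (e.g. the IFNAR2,
MX1, MX2 analogues in the generator) are excluded because their elevation
reflects the extra gene copy, not pathway activity. Relaxing `fc_min`
yields the broader signature variants used for robustness checks; scores
from nested signatures on a shared latent axis are rank-correlated above
0.95 in the test suite.

The per-gene Gaussian linear model is a stand-in for count-based
differential expression: the pipeline consumes abundance-scale matrices
(RPKM-like), where a Wald test on the karyotype coefficient of the log2
model is the natural analogue. Count-level inference is out of scope.

## Preprocessing rules

- **Extreme outliers** (`exclude_extreme_outliers()`): per analyte and per
  karyotype stratum, values outside $[Q_1 - 3\,\mathrm{IQR},\;
  Q_3 + 3\,\mathrm{IQR}]$ are excluded. Quartiles use linear interpolation
  between order statistics (R's type 7) — a convention had to be fixed and
  this is the dominant default; it is exposed via `quantile_type`. The
  classification is a single pass: fences are not recomputed after
  exclusion. Strata with fewer than 4 non-missing values are skipped with
  a warning rather than fenced on meaningless quartiles.
- **Immunoassay fit-range handling** (`resolve_out_of_range()`): values
  below/above the standard-curve range are replaced by the minimum/maximum
  in-range calculated concentration of that analyte *on the same plate*,
  then duplicate wells are averaged; analytes with more than 10 % of wells
  out of range are flagged (and retained, so the flag is advisory).
  In-range values pass through bit-identical.
- **Metabolites** (`normalize_metabolites()`): reported zeros are replaced
  by a seeded draw from $U(0, 0.5 \times \min_{\neq 0})$ per metabolite,
  then each sample is rescaled so its median equals the global median of
  the replaced matrix. The operation is idempotent on a zero-free matrix.
- **Covariate adjustment** (`adjust_covariates()`): per feature, a linear
  model with nuisance covariates (age, sex, source) plus a *protected*
  karyotype term; only the fitted nuisance contributions are subtracted,
  with nuisance regressors centered so the grand level is retained. The
  protected term ensures the karyotype contrast survives adjustment even
  when covariates are imbalanced between groups; the operation is exactly
  idempotent. Sample source enters as a fixed covariate: a random-intercept
  treatment of source pursues the same adjustment goal, and with a handful
  of sources and large per-source counts the fixed-effect fit is
  essentially equivalent while keeping the estimator closed-form.
- Missing values propagate as missing everywhere; the immunoassay rule is
  the only imputation in the pipeline.

## Association screens

Each screen returns one tidy table (`feature`, `kind`, `estimate`, `p`,
`q`, `n`), and BH adjustment is computed **within that screen alone** —
q-values are per-analysis, never pooled across layers.

- **Spearman** (`spearman_screen()`): average-rank rho on
  pairwise-complete observations (≥ 4 pairs), p from the t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$. Constant features are excluded from
  the BH family.
- **Differential abundance** (`differential_abundance()`): per analyte,
  `log2(abundance) ~ karyotype + age + sex + source`; the karyotype
  coefficient is the log2 fold change. Nonpositive abundances at this
  stage are a contract violation (QC must run first) and error.
- **Beta regression** (`fit_beta_regression()`, `beta_screen()`): cell
  cluster frequencies $y \in (0,1)$ are modelled as
  $y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
  $\mathrm{logit}(\mu) = X\beta$ and constant precision $\phi$. The exact
  likelihood is maximized by BFGS with analytic gradients in
  $(\beta, \log\phi)$; starting values come from OLS on
  $\mathrm{logit}(y)$, standard errors from the observed information at
  the optimum, and Wald p-values per coefficient. Exact 0/1 frequencies —
  absent in real compositions but possible in toys — are handled by the
  optional Smithson–Verkuilen shrinkage $y' = (y(n-1)+0.5)/n$; without it
  they are an error. The screen reports
  $\exp(\hat\beta_{\mathrm{predictor}})$ as the fold change per predictor
  unit. The test suite checks the fitter against a dense likelihood grid
  (3 significant figures) and verifies 95 % Wald coverage of a planted
  slope within [0.92, 0.98] at $n = 500$, $\phi = 30$.
- **Preranked GSEA** (`preranked_gsea()`): weighted Kolmogorov–Smirnov
  running-sum ES with weight exponent 1; the null is gene-label
  permutation (default 10,000, seeded), $\mathrm{NES} = ES /
  \mathrm{mean}(|ES_{\mathrm{null}}|)$ over same-sign nulls, and p uses
  the $(b+1)/(m+1)$ permutation estimator. Ranking ties are broken by
  gene ID so results are reproducible. The standard ranking metrics are
  RNA log2 fold change, proteomics $\log_2 FC \times -\log_{10} p$, and
  Spearman rho.

## Stratification

**Consensus clustering** (`consensus_cluster()`) follows the Monti
resampling scheme: per repetition, a subsample of samples (default
fraction 0.8, 100 repetitions) is clustered hierarchically (average
linkage) on $1 - $ Pearson correlation distance and cut at each $k$;
consensus$(i,j)$ is the co-clustering rate among co-sampled repetitions.
Subsample fraction and linkage are defaults of the resampling scheme and
are exposed as arguments. Cluster number is chosen from the
consensus-CDF area curve: `select_k_delta_area()` returns the largest $k$
reached before the relative area gain first drops below `gain_threshold`
(default 0.05). An automatic rule is needed in a pipeline where a human
would eyeball the delta-area plot; the threshold is configurable and the
full curve is returned (`tidy()`, `autoplot()`).

**Clinical clustering** (`stratify_clinical()`) combines binary condition
flags (pre-filtered to at least 10 cases *and* 10 controls) with the IFN
score into a Gower distance: binary variables contribute symmetric simple
matching — co-absence counts as agreement, matching the default treatment
of mixed data — numeric variables contribute range-normalized absolute
differences, and unknown values drop out pairwise. PAM clusters the
distance matrix; $k$ is chosen by the highest average silhouette width
(singleton-cluster members score 0 by convention). Enrichment per
condition and cluster is summarized as observed/expected cases (expected
under equal rates) with a two-sided Fisher exact test per condition
(Monte-Carlo p for more than two clusters) and BH across conditions;
score differences between clusters use two-sided Mann–Whitney U tests
(exact for small tie-free samples, normal approximation with tie
correction otherwise).

**PAM and local optima.** Classic PAM (greedy BUILD, then steepest-descent
single swaps) can terminate in a swap-locked local optimum of the
k-medoids objective — a descent property shared by the reference
`cluster::pam`, not an implementation quirk. Because a stratification
pipeline should not depend on which local optimum the descent happens to
reach, `pam_cluster()` restarts the SWAP phase from seeded random medoid
sets (default 20 restarts) and keeps the lowest-cost solution, with
deterministic tie-breaking. The test suite verifies the restarted solver
against an exhaustive search over all medoid subsets on randomized small
instances.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with one latent per-individual IFN activity variable
$a_s \sim N(\mu_{\mathrm{karyotype}}, \sigma_\ell)$, $\mu_{T21} = 1$,
$\mu_{\mathrm{control}} = 0$, $\sigma_\ell = 1$ by default:

- **Expression** is generated on the log2 scale and exponentiated, so
  configured effects are multiplicative fold changes: chr21 genes carry a
  1.5× dosage factor in T21; 18 planted ISGs respond to $a_s$ with slope
  0.9 log2 units per latent SD (≈ 1.87× mean elevation in T21 — safely
  above the 1.5× selection threshold, while per-seed latent sampling keeps
  recovery nontrivial); 120 further ISGs respond weakly (slope 0.25,
  ≈ 1.19×, below threshold), so ISG-wide analyses such as the on/off drug
  contrast have a realistic universe of 138 non-chr21 ISGs; and 3 chr21
  ISGs respond strongly, exercising the chr21 exclusion. Small per-gene
  age and sex effects make covariate adjustment consequential.
- **Analyte layers** (proteomics, immunoassay, metabolomics) put log2
  slopes on $a_s$ for a named subset of features (defaults 0.4; the
  metabolite panel plants kynurenine at +0.3 and tryptophan at −0.2 so
  the kynurenine/tryptophan ratio rises with IFN activity). The
  immunoassay layer has plates, duplicate wells, and a configurable
  fraction of below/above fit-range wells (two analytes are deliberately
  flag-heavy); the metabolite layer has a configurable reported-zero
  fraction. These exercise every preprocessing rule.
- **Cell compositions** are softmax-transformed Gaussian logits (a
  logistic-normal), so per-cluster logit slopes on $a_s$ correspond
  directly to what the beta-regression screen estimates; frequencies are
  positive and sum to 1 per sample by construction.
- **Condition flags** are Bernoulli with logit linear in $a_s$ (baseline
  prevalence ≈ 0.3, planted slopes 0.8 on half the conditions), planting
  the high-activity/condition-burden cluster structure the clinical
  stratification should find.
- **The longitudinal subject** (`generate_longitudinal_subject()`) sits at
  the upper T21 latent range ($\mu_{T21} + 1.5\sigma_\ell$); off-drug
  draws use that activity, on-drug draws shrink the ISG component toward
  the control mean by `drug_effect` (default schedule: 7 on, 4 off,
  interleaved). `drug_effect = 0` makes on/off exchangeable;
  `drug_effect = 1` puts expected on-drug ISG expression at the control
  baseline.

Effect sizes are free parameters: no public source specifies them for any
layer, so the defaults above were chosen once as values a cohort study of
this kind would call realistic-but-strong, and are documented rather than
fitted. All randomness flows from one master seed through per-layer
sub-streams, so adding analytes to one layer never perturbs another, and
identical configurations are byte-identical.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: sequencing-count noise (expression is
log-normal, not negative binomial), batch effects beyond a source label,
heavy-tailed and missing-not-at-random assay noise, correlated gene
modules beyond the single latent axis, age- or sex-dependent effect
modification, and longitudinal within-subject drift. Results on real
cohorts depend on those structures; the synthetic checks establish
correctness of the machinery, not robustness to everything biology does.

## Numerical choices

- Quantiles everywhere (fences, reference bands) use type 7; the sample SD
  uses the $n-1$ denominator.
- The log2 pseudocount is 0.5 throughout (`log2(RPKM + 0.5)`).
- Zero-SD signature genes are dropped from the reference with a warning;
  zero-variance features are excluded from BH families rather than
  assigned p-values.
- The beta-regression optimizer runs BFGS to `reltol = 1e-12` with
  analytic gradients; non-converged fits are flagged and excluded from
  screens with a warning.
- GSEA ranking ties break by gene ID; PAM ties break toward the lexically
  smallest medoid set; consensus and PAM resampling are seeded.
- Degenerate inputs fail loudly: rank-deficient adjustment designs name
  the collinear columns, constant beta-screen predictors error, and
  record pairs with no shared non-missing Gower variables error.

## Problem sizes in the test suite

The packaged tests run the full pipeline at the cohort scale the methods
target (300 T21 / 100 control, 2000 genes) for signature recovery and
score validity, with 10–20 seed replicates for stochastic properties;
calibration checks use 200 beta-regression replicates at $n = 500$, 20
consensus panels of 60 samples, and 1000 null gene sets with 500
permutations each. These sizes were chosen so each property is measured
with useful Monte-Carlo precision while the whole suite stays comfortably
interactive.

## Known limitations

- The differential-expression stand-in is Gaussian on log2 abundances;
  genes with many zeros or very low expression are better served by
  count models, which this package deliberately does not reimplement.
- Beta regression uses a constant precision $\phi$; strongly
  heteroskedastic compositions would need precision covariates.
- The delta-area rule makes the elbow choice explicit but is still a
  heuristic; inspect `autoplot()` of the consensus result when the gain
  curve is flat.
- Gower distances do not satisfy the triangle inequality in general; PAM
  does not require it, but do not feed them to methods that do.
- The generator's single latent axis means all planted cross-layer
  associations are mutually consistent; real cohorts can and do decouple.
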