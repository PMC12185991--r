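---
title: "Methods: from gut metagenomic profiles to lung-function odds ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gut metagenomic profiles to lung-function odds ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiome)
```

## The analysis problem

People living with HIV carry an excess burden of pulmonary comorbidity even
under effective antiretroviral therapy. One candidate contributor is the gut
microbiome: compositional shifts in gut bacteria may mark — or drive —
accelerated loss of lung function. `dysbiome` implements a complete,
reusable version of the corresponding cohort analysis. It starts from two
inputs:

* a species-level relative-abundance table in the MetaPhlAn merged-profile
  dialect (pipe-delimited `k__...|s__...` lineages, values on a 0–100
  percent scale), and
* per-sample clinical metadata with spirometry at two visits, smoking
  status, demographics, HIV-history covariates and two cytokines.

From these it derives the outcomes, compares community structure between
outcome groups, identifies differentially abundant species, condenses them
into a single per-sample **microbial dysbiosis index**, and estimates the
adjusted odds of poor lung function per unit of that index.

## Outcomes

Two outcomes are derived from spirometry (`derive_outcomes()`):

* **Rapid lung-function decline** — FEV1 loss strictly greater than
  40 mL/year, computed as
  `(fev1_baseline − fev1_followup) / followup_years`. A decline of exactly
  40 mL/year is *not* rapid; samples without follow-up spirometry get a
  missing value and drop out of decline analyses only.
* **Airflow limitation** — FEV1/FVC below 0.70 *and* FEV1 below 80% of the
  predicted value (moderate-or-worse obstruction). Percent-predicted FEV1
  is consumed as a given metadata column; reference-equation computation is
  out of scope.

## Diversity analyses

Alpha diversity uses the Shannon and inverse Simpson indices on per-sample
proportions; group contrasts use the Mann–Whitney U test. Beta diversity is
the Bray–Curtis dissimilarity on the raw percent values, ordinated by
principal coordinates (classical scaling of the Gower-centred matrix;
negative eigenvalues are reported but yield no axes). Group effects on
community structure are tested with PERMANOVA via `vegan::adonis2`, using
sequential (terms-in-order) sums of squares with adjustment covariates
entered *before* the group term and free permutation of sample identities
(999 permutations by default, seed-deterministic). Sequential rather than
marginal partitioning is that tool's default behaviour and matches how the
adjusted test is conventionally reported; the covariate list is an explicit
argument because which covariates differ between groups is a property of
each cohort.

## Differential abundance: a negative-binomial Wald engine

The differential-abundance stage is a self-contained NB Wald implementation
(C++ core) rather than a call to an external package, so that every
modelling choice is explicit and testable:

1. **Pseudo-counts.** NB likelihoods need integers; MetaPhlAn emits
   percentages. Each sample is scaled to a fixed depth
   (`to_counts()`, default 100,000), which keeps size factors
   interpretable. Taxa present in fewer than 10% of samples are excluded
   beforehand (`prevalence_filter()`); rare-taxon NB fits are unstable and
   contribute little.
2. **Normalization.** Median-of-ratios size factors over the taxa observed
   in every sample, normalized to geometric mean 1; if no taxon is
   ubiquitous the geometric means fall back to positive counts only, with
   a warning.
3. **Dispersion.** Per-taxon maximum-likelihood dispersion under an NB GLM
   with log link and size-factor offsets (profile likelihood in the
   coefficients, golden-section search on the log scale over
   [1e-8, 1e5]); a parametric trend `alpha(mu) = a0 + a1/mu` fitted across
   taxa by iterated gamma-family regression with outlier exclusion; and a
   posterior-mode estimate shrinking each taxon toward the trend under a
   log-scale normal prior with fixed variance 0.25. Fixing the prior
   variance (rather than estimating it) removes a fragile estimation step
   at the few-hundred-taxa scale; it is exposed as `prior_var`.
4. **Testing.** Per taxon, one NB GLM on
   `[intercept | smoking dummies | condition]` (smoking enters as two
   dummies with "never" as reference), Wald `z = coef/SE` for the condition
   coefficient, two-sided normal p-values, and Benjamini–Hochberg
   adjustment across the converged taxa within the analysed rank.
   Non-converged taxa are flagged and excluded from the BH family.
   Coefficients are reported as log2 fold changes.

There is no independent filtering and no fold-change shrinkage: the core is
deliberately the smallest faithful Wald pipeline. In the Poisson limit
(dispersion → 0) the fits agree with `glm(..., family = poisson)` to 1e-6,
and at matched size factors and dispersions the coefficients agree with
DESeq2's `nbinomWaldTest` to 1e-4 (both checked in the test suite).

One approximation is worth naming: multiplying every count by a constant
leaves size factors exactly unchanged, but re-estimated dispersions retain
a weak dependence on the absolute count scale (shot noise), so fold
changes agree across scales only to ~1e-2. This is shared by any NB
pipeline that re-estimates dispersion.

## The dysbiosis index

Significant taxa (BH-adjusted p < 0.05) are split by direction into
*increased* and *decreased* sets. A Mann–Whitney sensitivity screen then
prunes each candidate: the taxon's abundances are compared between outcome
groups and taxa with p > 0.10 are removed (exactly 0.10 is retained). The
Mann–Whitney implementation enumerates all group assignments exactly for
pooled sizes up to 12 — which remains valid under ties, where the
permutation distribution of U is still symmetric — and otherwise uses the
normal approximation with continuity and tie corrections.

The per-sample index is

> log10( (sum of increased-taxa abundances + pc) /
>        (sum of decreased-taxa abundances + pc) )

with a pseudocount `pc` defaulting to half the smallest nonzero abundance
in the table — standard compositional practice that keeps the index finite
when a sample lacks every taxon of one set; the value used is recorded in
the output. The index is antisymmetric under exchanging the two sets and
invariant to rescaling abundances and pseudocount together. If either set
is empty after pruning the index is undefined and the pipeline stops with
an explanatory status rather than fabricating a value. The index is built
on the rapid-decline contrast and then applied unchanged to the
airflow-limitation models.

## Association models

`run_models()` fits multivariable logistic regressions of each outcome on
the index (untransformed, per unit of log10 ratio):

* **model 1** (rapid decline): index + smoking + age + sex + BMI +
  ethnicity + transmission mode + nadir CD4 < 200 + HIV duration.
  Smoking is included alongside the other adjustments since it is the
  built-in confounder of the design.
* **model 2**: model 1 + IL-1β + IL-10.
* **sensitivity fits**: model 1 on the pneumonia-history-free subset and
  on the high-quality-spirometry subset (grades A–C).
* **airflow limitation**: because cases are few, a family of small models
  each adjusts for age, BMI and one further covariate at a time (default
  smoking, HIV duration, cART years; configurable).

Fits are maximum likelihood via IRLS with explicit rank and separation
checks: if a separating hyperplane exists, or a coefficient diverges, the
fit *errors* naming the term — there is no silent Firth-style correction.
Confidence intervals are Wald intervals on the log-odds scale
(`exp(coef ± 1.96 SE)`), matching how adjusted odds ratios are
conventionally printed. Samples missing any covariate required by a model
are dropped from that model only, never imputed, and each result row
carries `n_used`.

## Co-occurrence networks

Spearman correlations (midranks; exact permutation p for n ≤ 9, else the
t approximation) connect taxa within each outcome group. Nodes are the 50
most abundant taxa united with the differentially abundant ones; edges
require rho > 0.5 (signed, as printed in the field's convention; an
absolute-value switch exists) and raw p < 0.05. No multiple-testing
correction is applied on edges — a deliberately liberal rule, flagged as
such. Exports are edge-list TSV and GraphML.

## The synthetic-cohort generator

Real cohorts of this kind have restricted metadata, so the package ships a
generator (`generate_cohort()`) whose defaults encode the study conditions
the pipeline targets: 350 samples, 400 species, ~44.7% rapid decliners,
~10% airflow limitation, 6 enriched and 2 depleted planted species at one
log2 unit, smoking as confounder (odds ratio 1.5 for current smokers, with
current smoking also shifting 20 non-planted taxa so that smoking
adjustment is non-trivial), multinomial read depth 100,000, and 10%
missing follow-up spirometry.

Design choices that matter:

* **Across-taxa profile vs within-taxon noise.** Abundance centres are
  log-normal across taxa (a few dominant species, a long rare tail), but
  sample-to-sample biological variation within a taxon is *gamma*
  distributed with per-taxon dispersion — the mixing distribution under
  which read counts are negative-binomial. A log-normal within-taxon
  alternative (`taxon_noise = "lognormal"`, variance-matched) is available
  but is markedly heavier-tailed than the NB model assumes and makes any
  NB Wald test — not just this one — anti-conservative; with the gamma
  default the null type-I rate of the DA stage is nominal (~0.05),
  which is what a calibration suite must be able to verify.
* **Planted taxa** are placed among moderately abundant, consistently
  colonizing species (centre quantiles 0.60–0.90, dispersion 0.6), so they
  pass the prevalence filter and carry enough information for recovery.
* **Outcome model.** Labels are drawn from a logistic model calibrated to
  the target prevalence, with smoking and `beta_index` times the centred
  baseline planted log10-ratio as linear terms; cases then have enriched
  taxa multiplied by `2^fc` and depleted by `2^-fc`. `beta_index`
  (default ln 1.2) is the generative log-odds per unit of baseline index.
* **What the case-shift implies for in-sample odds ratios.** With a
  planted fold change of one log2 unit the two outcome groups are
  separated by ~0.6 index units while the within-group index SD is ~0.4,
  so a logistic fit of outcome on the *post-shift* index estimates a slope
  near separation — an in-sample adjusted OR far above `exp(beta_index)`.
  This is an inherent property of case-shift designs, not an estimation
  error: the shift mechanism and the logistic link answer different
  questions. Parameter recovery of the association machinery is therefore
  validated on cohorts generated with `effect_log2fc = 0`, where the
  outcome depends on the index only through the configured link and the
  fitted model-1 adjusted OR should (and does) concentrate around
  `exp(beta_index) = 1.2`; recovery of the planted fold changes and of the
  direction sets is validated under the default shift design.
* Spirometry is generated consistently with the labels (rapid decliners
  get FEV1 slopes in (40, 120] mL/yr, others in [−20, 40]; airflow cases
  get FEV1/FVC < 0.70 and <80% predicted), and remaining covariates are
  drawn from distributions matched to the target cohort's demographics.

`generate_null_cohort()` zeroes every effect (planted shifts, the index
link, the smoking–outcome and smoking–taxa links) for type-I-error and
coverage suites.

What passing tests on these cohorts do **not** show: robustness to the
heavy-tailed, zero-inflated, compositionally correlated structure of real
gut metagenomes (the log-normal noise switch exists precisely to probe
that mismatch), to batch effects, or to confounders beyond smoking.

## Numerical choices and degenerate inputs

* Dispersion search range [1e-8, 1e5] on the log scale; golden-section
  tolerance 5e-3; IRLS convergence on relative coefficient change
  (1e-7 inside the dispersion search, 1e-10 for reported fits, max 50
  iterations); taxa that fail to converge fall back to the trend
  dispersion and are flagged.
* Logistic IRLS: epsilon 1e-10, max 100 iterations; separation is an
  error, as is rank deficiency (naming the aliased columns).
* Exact-test thresholds: Mann–Whitney enumerates pooled sizes ≤ 12;
  Spearman enumerates n ≤ 9.
* Ties use midranks throughout; the exact Mann–Whitney two-sided p is
  computed from the symmetric permutation distribution of |U − n1 n2 / 2|.
* Empty direction sets, all-zero samples, constant grouping variables,
  duplicated taxa or samples, and negative abundances are errors with
  named offenders, not warnings.
* All randomness flows from one root seed; the pipeline derives one
  sub-seed per stage with a fixed documented offset scheme, so reports are
  byte-identical across reruns.
* Configuration files are YAML.

## Validation scale

The shipped suites run at the cohort scale the defaults encode: 200
null-cohort replicates for type-I calibration and PERMANOVA p uniformity
(199 permutations per replicate in the calibration loops), 500 replicates
for CI coverage, and 50 planted replicates each for direction-set recovery
and link recovery. `scripts/acceptance.R` reproduces a single end-to-end
run plus reduced-size calibration and recovery summaries in well under an
hour on one CPU.

## Known limitations

* The NB engine has no fold-change shrinkage and no independent filtering;
  with very low counts its Wald p-values are approximate.
* The co-occurrence edge rule is raw-p and signed by default.
* The generator plants effects on prevalent taxa only; recovery of rare,
  sparsely observed taxa is untested.
* Single baseline microbiome sample per subject; no longitudinal
  microbiome modelling, no UniFrac/phylogenetic metrics, no
  read-level simulation, no pathway-level analysis.
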