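# dysbiome

Gut-microbiome dysbiosis and lung-function decline: a tested, reusable R
pipeline for cohort studies that ask whether compositional shifts in the
gut metagenome are associated with accelerated loss of lung function —
a question of particular interest in people living with HIV, where
pulmonary comorbidity persists under effective antiretroviral therapy.

Starting from a MetaPhlAn-style species-level relative-abundance table and
clinical metadata (spirometry at two visits, smoking, demographics,
HIV-history covariates, cytokines), the package:

1. derives the outcomes — **rapid lung-function decline**
   (FEV1 loss > 40 mL/year, strictly) and **airflow limitation**
   (FEV1/FVC < 0.70 with FEV1 < 80% predicted);
2. computes alpha diversity (Shannon, inverse Simpson), Bray–Curtis
   dissimilarity, PCoA ordination and covariate-adjusted PERMANOVA;
3. runs a from-scratch **negative-binomial Wald differential-abundance
   analysis** (median-of-ratios normalization, parametric dispersion trend
   with posterior-mode shrinkage, smoking-adjusted design; C++ core);
4. condenses the significant species into a per-sample
   **microbial dysbiosis index**

   ```
   MDI = log10( Σ abundance(species increased in cases) + pc
              / Σ abundance(species decreased in cases) + pc )
   ```

   after a Mann–Whitney sensitivity screen that removes candidate species
   with p > 0.10 (exact enumeration for small groups, tie-corrected normal
   otherwise);
5. estimates **adjusted odds ratios** for both outcomes from multivariable
   logistic regressions (model 1: traditional + HIV-related risk factors;
   model 2: + IL-1β, IL-10; pneumonia-free and high-quality-spirometry
   sensitivity subsets; small rotating-covariate models for airflow
   limitation); and
6. builds Spearman co-occurrence networks (rho > 0.5, p < 0.05) per
   outcome group.

Because real cohorts of this kind have restricted metadata, the package
also ships a **synthetic-cohort generator** with planted enriched/depleted
species, a smoking confounder, a configurable logistic link between the
planted index and the outcome, and a ground-truth record — the test
surface for calibration and parameter-recovery validation. See the methods
vignette (`vignettes/dysbiome-methods.Rmd`) for the model details and
design rationale.

## Worked example

End-to-end on a simulated cohort (the defaults encode the target study
conditions: n = 350, 400 species, ~45% rapid decliners, 6 + 2 planted
species at one log2 unit):

```r
library(dysbiome)
report <- run_pipeline(pipeline_config(seed = 1))
#> [simulate] n=350 samples, 400 taxa
#> [outcomes] 315 with valid follow-up of 350; 136 rapid decliners (43.2%); 36 airflow limited
#> [diversity] Shannon MWU p=0.66; PERMANOVA group p=0.449
#> [da] 361 taxa tested (prevalence >= 0.1); 6 increased, 2 decreased at BH < 0.05
#> [prune] retained 8 of 8 taxa at MWU p <= 0.1
#> [index] per-sample index computed (pseudocount 0.0005)
#> [associate] model1 aOR=835.607 [190.771, 3660.101], p=4.34e-19 (n=315)
#> [network] 5 edges (rapid), 0 edges (normal)
```

The run recovers exactly the 6 enriched and 2 depleted planted species
(`report$sets_pruned`), overall diversity does not differ between groups
(Shannon Mann–Whitney p = 0.66, PERMANOVA p = 0.449 — compositional
signal without a community-wide shift), and the in-sample adjusted OR is
enormous because a planted 2-fold shift in cases nearly separates the
groups on the index scale (the methods vignette explains why that is a
property of case-shift designs, not of the estimator).

Recovery of a realistic odds ratio is demonstrated on cohorts where the
outcome depends on the index only through the generator's logistic link
(`beta_index = ln 1.2`, no case shift):

```r
co  <- generate_cohort(sim_config(effect_log2fc = 0, beta_index = log(1.2)),
                       seed = 7)
sets <- structure(list(increased = co$truth$candidate_enriched,
                       decreased = co$truth$candidate_depleted, alpha = 0.05),
                  class = "direction_sets")
idx <- dysbiosis_index(co$abundance, sets)
run_models(idx, co$metadata, "rapid")[1, c("model", "aOR", "ci_low", "ci_high")]
#>    model   aOR ci_low ci_high
#> 1 model1 1.259  0.673   2.357
```

— one unit of dysbiosis index multiplies the adjusted odds of rapid
decline by ~1.26 in this replicate (generative value 1.20); across 50
replicates the median model-1 aOR sits at ~1.2.

Reading real data instead of simulating:

```r
tab  <- read_abundance_table("abundance.tsv", rank = "species")
meta <- read_metadata("metadata.tsv")
report <- run_pipeline(pipeline_config(simulate = FALSE,
                                       abundance = "abundance.tsv",
                                       metadata = "metadata.tsv",
                                       outdir = "results", seed = 1))
```

A thin CLI with `simulate` and `run` subcommands lives at
`inst/scripts/dysbiome.R`.

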