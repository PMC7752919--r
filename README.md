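# metacohort

Tools for building a harmonized gene-level meta-cohort out of several
colorectal-cancer expression datasets (mixed microarray and RNA-seq) and
for relating gene expression to clinical outcome in the merged cohort.

Pooling public tumor expression series naively confounds biology with the
center that collected each sample, the day its array was scanned, the
quality of its RNA, and the clinical mix of each series. `metacohort`
addresses these layers as separate, individually tested stages:

1. **Technical correction** — per feature and dataset, a mixed-effects
   model `y ~ center + MSI + quality metrics + (1 | scan batch)` (REML,
   OLS fallback on boundary fits) whose fitted center, shrunken-batch and
   metric components are subtracted, preserving each feature's grand mean
   and all biological covariates.
2. **Probeset-to-gene summarization** — the first principal component of
   the probesets mapping to a gene, re-centered/re-scaled to the
   |loading|-weighted mean of the probeset means and SDs and
   sign-matched to the dominant probeset.
3. **Standardization to a reference cohort** — quantile normalization to
   the reference's gene-level quantiles, then gene-wise
   `x' = (x − m_D)/s_D · s_ref + m_ref` with weighted median/MAD on the
   dataset side; the weights are truncated inverse-probability ratios
   `min(Pd/Pr, 5)` from a forward-stepwise-AIC logistic model of cohort
   affiliation on gender, age, site, MSI and stage. Values are clipped to
   the reference range and datasets merged on their gene intersection
   (unknown-stage samples dropped).
4. **Association** — endpoint-specific cohorts (relapse: stage I–III;
   overall survival: stage I–III and IV strata), expression tertiles, Cox
   proportional hazards with likelihood-ratio and pairwise Wald tests,
   Kaplan–Meier curves, and a stage linear model with F-test and adjusted
   group means.
5. **Utilities** — DE-table filtering and gene-set overlap statistics
   (Jaccard, hypergeometric), ΔΔCt fold changes, ChIP-qPCR percent input.

A synthetic multi-cohort generator (`simulate_meta_cohort()`) with known
center/batch offsets, metric artifacts, composition shifts and
survival ground truth underpins the test suite end to end.

## Tests

```r
testthat::test_dir("tests/testthat", package = "metacohort",
                   load_package = "installed")
```

## Worked example

```r
library(metacohort)

cfg <- simulation_config(n_datasets = 3, samples_per_dataset = 80,
                         n_genes = 100, cox_log_hr = 0.7, seed = 1)
sim <- simulate_meta_cohort(cfg)
cohort <- harmonize_cohorts(sim$expression, sim$clinical,
                            sim$annotation, reference_id = "DS01")
#> dataset DS01: 80 samples, 246 probesets -> 100 genes (76 fallback fits)
#> ...
#> dataset DS02: affiliation covariates {msi, site, age, gender, stage},
#>   14 weights truncated at 5
#> merged cohort: 100 genes x 231 samples (9 unknown-stage samples dropped)

res <- associate_gene(cohort, cfg$target_gene_id, endpoint = "os_premet")
res$cox$hr
#>         contrast   hr ci_lower ci_upper   wald_p
#> 1  medium_vs_low 4.09    2.400     6.98 2.25e-07
#> 2    high_vs_low 5.13    3.022     8.71 1.41e-09
#> 3 high_vs_medium 1.25    0.848     1.85 2.57e-01
res$cox$lrt_p
#> 1.58e-11
```

The generator ties the hazard to the standardized signal of the target
gene (`cox_log_hr = 0.7` per SD here), so after harmonization the medium
and high expression tertiles show the expected graded increase in hazard
relative to the low tertile, with the likelihood-ratio test strongly
rejecting the null of no group effect on the 191 pre-metastatic samples.

## Documentation

The methods vignette (`vignettes/harmonization-methods.Rmd`) describes
the models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the package's numerical choices
and limitations.
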