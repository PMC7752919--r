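---
title: "Harmonizing multi-cohort tumor transcriptomes and associating expression with outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-cohort tumor transcriptomes and associating expression with outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacohort)
```

## The problem

Public colorectal-cancer expression resources mix RNA-seq cohorts with
Affymetrix microarray series collected over many years, centers and
scanners. Before a gene's expression can be related to relapse or overall
survival across such a collection, three nuisance layers have to be dealt
with: (i) within each dataset, technical structure — center of origin,
scanning day or sequencing plate, and per-array quality drift — adds
feature-specific offsets; (ii) arrays measure genes through several
probesets that must be collapsed to one gene-level value; (iii) datasets
differ in clinical composition (sex, age, tumor site, microsatellite
status, stage), so naive pooling confounds cohort membership with biology.
`metacohort` implements this harmonization chain and the downstream
association battery as reusable, separately testable stages, together with
a synthetic multi-cohort generator that provides ground truth for every
stage.

## Technical correction

For each feature $p$ in one dataset, the log2 intensity is modeled as

$$ y_{pi} = \mu_p + \text{center}_{c(i)} + b_{k(i)} + \boldsymbol\gamma_p^\top
\mathbf{m}_i + \text{MSI}_{s(i)} + \varepsilon_{pi},
\qquad b_k \sim N(0, \tau_p^2), $$

with center a fixed effect (sum-to-zero coding), the scan batch (or
RNA-seq plate) a random intercept, $\mathbf m_i$ the three mean-centered
per-array quality metrics (`pm_iqr`, `rma_iqr`, `rna_deg`), and MSI status
a biological covariate estimated to avoid confounding but never removed.
Fits use REML (`lme4`); a single batch level, a non-convergent fit, or a
boundary variance estimate falls back to ordinary least squares without
the batch term, flagged per feature. `remove_technical_effects()`
subtracts the fitted center, shrunken (BLUP) batch, and metric components,
after centering the technical component across samples so every feature's
grand mean is preserved exactly. Because the batch term is a prediction,
not a group mean, correction is shrinkage-aware and approximately
idempotent — both properties are tested.

## Probeset-to-gene summarization

Probesets mapping to one gene are collapsed to the scores of their first
principal component (covariance-based, probesets mean-centered across
samples). The raw PC score has arbitrary location, scale and sign, so it
is made canonical by three rules:

* its mean is set to the weighted mean of the probeset means and its SD
  to the weighted mean of the probeset SDs (denominator $n-1$), with
  weights the absolute loadings of the first eigenvector;
* its sign is flipped, if needed, so that it correlates positively with
  the probeset of largest absolute loading (ties broken by annotation
  order);
* single-probeset genes pass through unchanged, and an all-constant gene
  returns its mean row with a warning.

Absolute loadings are used as weights because a weight must be
non-negative; signed and squared alternatives are exposed via
`weight_type`, and correlation-based PCA via `use_correlation`, for users
whose platforms mix intensity scales. The sign rule makes the output
invariant to the eigenvector-sign ambiguity of any numerical backend,
which the tests exercise directly.

## Standardization to a reference cohort

One dataset is designated the reference (the largest microarray series in
a typical application; dataset 1 in synthetic runs). Each other dataset is
first quantile-normalized so that every sample's sorted values equal the
reference's gene-level quantile vector (ties mapped to the mean of their
span; a reference vector of different length is linearly interpolated on
an equal-spaced probability grid).

Composition differences are then addressed by inverse probability
weighting. For dataset D, a logistic model of cohort affiliation
(D vs reference) is built by forward stepwise selection over gender, age,
site, MSI and stage, adding at each step the covariate with the largest
AIC improvement until none improves; covariates causing complete
separation are skipped with a warning. From the fitted probabilities the
per-sample weight is $P_d/P_r$ truncated at 5, so no single sample
dominates. Note the direction of this ratio: as written it up-weights
samples *typical of D*. The package implements it this way and also
exposes `direction = "to_reference"` ($P_r/P_d$), which up-weights D
samples that resemble the reference and is the direction under which the
covariate-balance diagnostic (`standardized_mean_difference()`) is
guaranteed to improve; the balance tests use that direction.

Gene-wise standardization then maps D onto the reference's robust
location and scale: $x' = (x - m_D)/s_D \cdot s_{ref} + m_{ref}$ with
$m_D, s_D$ the weighted median and weighted MAD of D and $m_{ref},
s_{ref}$ the unweighted median and raw MAD of the reference. The weighted
median follows the cumulative-weight rule (smallest value whose weight
share reaches one half, midpoint interpolation at exact halves), which
reduces to `stats::median()` under unit weights; no MAD consistency
constant is applied on either side, so the constant cannot cancel
incorrectly. A gene with zero weighted MAD receives a location-only
shift. Finally values are clipped to the reference's observed per-gene
range, and datasets are merged on their gene intersection with
unknown-stage samples dropped — the full order is
correct → summarize → quantile-normalize → standardize → truncate →
merge, with `prepare_rnaseq()` (log2 + within-dataset quantile
normalization) replacing the first two stages for count-based datasets.

## Expression–outcome association

`select_endpoint_samples()` encodes the endpoint conventions: relapse is
analyzed in stage I–III patients, overall survival separately in
pre-metastatic (I–III) and metastatic (IV) strata, unknown stages are
excluded, and rectum samples of designated datasets can be removed.
Expression is stratified at the tertiles of its distribution using a
rank-based rule (cut values are the ⌈n/3⌉-th and ⌈2n/3⌉-th order
statistics; ties spanning a cut all fall in the lower group), which makes
the grouping invariant under any strictly monotone transform. The
association battery is a Cox proportional-hazards model on the two group
indicators (Breslow ties by default, Efron optional) with a
likelihood-ratio test overall and Wald tests pairwise, Kaplan–Meier
curves per group, and, for stage, a linear model with an F-test, adjusted
(here: unadjusted-covariate) group means with 95% confidence intervals
and pairwise Wald comparisons. The 5% significance convention is left to
the caller; all p-values are returned raw.

## Small deterministic calculators

`de_filter()` reproduces the usual post-processing of a DESeq2-style
table: genes under a total read count are removed first, p-values are
re-adjusted (Benjamini–Hochberg) over the remaining genes, and survivors
must pass an adjusted-p and absolute log-fold-change cutoff. The
fold-change cutoff is applied to the table's column as supplied; the
conventional scale is log2, and users whose tables carry log10
fold-changes should scale the cutoff accordingly — source material is not
always consistent about the base, so the column's base is deliberately
the caller's contract. `overlap_stats()` returns the intersection size,
Jaccard index and one-sided hypergeometric enrichment p of two gene sets
in a stated universe. `ddct_fold_change()` averages duplicate wells
before differencing and assumes perfect doubling; `chip_percent_input()`
uses the standard dilution-adjusted formula
$100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$ with the input
fraction $f$ an explicit, required argument.

## The synthetic generator

`simulate_meta_cohort()` emulates the structure the pipeline is built
for: several datasets whose probeset values are
`intercept + loading × gene signal + center offset + batch offset +
metric slopes · metrics + noise`, with per-dataset clinical composition
tables (the defaults deliberately shift sex, site, MSI, stage and age
across datasets so IPW has real work to do), correlated Gaussian quality
metrics, a fraction of genes carrying an MSI-associated shift, and
survival drawn from an exponential hazard
$h_0 \exp(\beta z)$ in the standardized target-gene signal with
administrative censoring — a form chosen because its event probability
$1 - e^{-h_0 C}$ (at $\beta = 0$) is available in closed form for
checking. Relapse is only generated for stage I–III samples, mirroring
the endpoint definitions. Defaults (4 datasets × 120 samples × 400 genes
× 1–4 probesets, center/batch SDs of 0.5, noise 0.3, baseline hazard
0.02/month, censoring at 60 months) describe a realistic mid-sized
meta-cohort while keeping a full run around a minute; these sizes are the
package's standard validation conditions. One master seed drives a
documented draw order with an independent stream per dataset, so runs are
byte-reproducible and adding a dataset leaves earlier ones unchanged.

What the generator does *not* emulate: probe-level (CEL) structure,
count-based noise, copy-number segments, non-proportional hazards,
informative censoring, or correlated gene–gene modules. Passing tests on
this generator therefore demonstrate that the stages remove what they
claim to remove and estimate what they claim to estimate under additive
Gaussian technical structure and proportional hazards — not that real
cohort idiosyncrasies (platform-specific saturation, stage migration
between series, differential follow-up) are handled.

## Numerical choices and limitations

* Eigen decomposition is `eigen(symmetric = TRUE)` on the per-gene
  covariance; the sign rule removes its sign ambiguity; degenerate
  (zero-variance) genes return mean rows.
* Boundary random-effect variances are treated as "no batch effect"
  (OLS fallback, flagged); with few batch levels this is common and the
  fallback agrees with the mixed path when the true batch variance is
  zero.
* Weighted-median midpoints use the next order statistic (not next
  distinct value), matching `stats::median()` under unit weights.
* Quantile normalization to a short reference vector interpolates
  linearly; extreme quantiles are therefore flattened relative to a
  longer reference.
* The Cox monotone-likelihood flag is conservative: it fires whenever a
  group has all or no events, including configurations whose MLE is
  finite.
* `fit_feature_models()` assumes one dataset at a time; cross-dataset
  correction is deliberately out of scope (that is what standardization
  is for).

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_datasets = 3, samples_per_dataset = 80,
                         n_genes = 100, seed = 1)
sim <- simulate_meta_cohort(cfg)
cohort <- harmonize_cohorts(sim$expression, sim$clinical,
                            sim$annotation, reference_id = "DS01")
res <- associate_gene(cohort, cfg$target_gene_id, endpoint = "os_premet")
res$cox$hr
```
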