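---
title: "Pathway-specific polygenic risk scores for AMD: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-specific polygenic risk scores for AMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the scoring
model and its assumptions, the quality-control and inference machinery,
what the synthetic cohort generator does and does not emulate, and the
design choices made where the design was genuinely open.

## The scoring model

A polygenic risk score aggregates many small genetic effects into a single
per-person number. `pathprs` computes it as a raw weighted dosage sum,

$$\mathrm{PRS}_s = \sum_{i \in V} \beta_i \, d_{si},$$

with $d_{si} \in [0,2]$ the imputed expected copy number of the effect
allele of variant $i$ in sample $s$ and $\beta_i$ a published per-allele
log-odds effect size. Three modelling commitments follow from how such
scores are reported in the AMD literature and are deliberate here:

* **No averaging, no standardization, no centering.** Scores live on the
  scale of the effect sizes; cohort means can be negative because the
  $\beta_i$ are signed. Dividing by the variant count or z-scoring would
  change every downstream regression coefficient.
* **Additivity and independence.** The sum assumes additive allele effects
  and ignores linkage disequilibrium; this is appropriate for a panel of
  independent lead SNPs from a meta-analysis, not for dense regional
  panels.
* **Pathway partition by gene label.** Each variant carries the gene label
  of its nearest locus, and `pathway_registry()` fixes the gene sets of
  the four pathways (complement; extracellular matrix, including the
  metalloproteinase loci *ADAM19* and *MMP9*; lipid metabolism;
  *ARMS2/HTRA1*). The combined complement + ARMS2/HTRA1 score is the union
  of two disjoint sets, so `c_ah_prs = c_prs + ah_prs` holds exactly —
  an identity the test suite asserts. Proximity-based gene assignment is a
  heuristic; the partition should be read as a structured exploration of
  pathway involvement, not as established biology.

The gene-to-pathway assignment travels in the scoring file (a
tab-separated, PGS-Catalog-style table extended with `gene_label` and
`pathway` columns) rather than being hard-coded to rsIDs, because the
exact variant panel surviving QC differs between cohorts and arrays.

## Effect-allele alignment

Scoring files state an effect and other allele; VCFs state REF and ALT.
`align_effect_alleles()` reconciles them per variant:

* effect = ALT: dosage used as is;
* effect = REF: dosage flipped, $d \leftarrow 2 - d$;
* match only after complementing both scoring alleles: treated as a
  strand reporting difference, then the same as-is/flip logic;
* A/T and C/G pairs are strand-ambiguous — complementing maps the pair
  onto itself, so strand cannot be resolved without external allele
  frequencies. Default policy: exclude with a warning (`"keep"` assumes
  same-strand reporting). No frequency-based disambiguation is attempted.
* anything else is `unmatched` and contributes to no score.

Missing dosages are mean-imputed per variant (equivalently, replaced by
twice the effect-allele frequency), the standard scoring-tool default; an
"omit term" alternative would make scores of samples with different
missingness patterns incomparable in a sum-based score.

## Variant QC

Four filters with the conventional thresholds for imputed array data:
imputation $R^2 \ge 0.3$ (dimensionless, from the imputation pipeline's
INFO field), call rate $\ge 0.9$, minor allele frequency $\ge 0.01$, and
Hardy–Weinberg exact $P \ge 10^{-6}$. Decisions taken where practice
varies:

* **Filter order is fixed** (R² → call rate → MAF → HWE) so that the
  verdict recorded for a failing variant is deterministic; the surviving
  set is order-independent, and an idempotence test asserts that
  re-filtering removes nothing.
* **Variants without an R² annotation** pass the R² rule by default
  (`assume_genotyped = TRUE`): an unannotated variant is interpreted as
  directly genotyped rather than imputed.
* **HWE on dosages.** The exact test needs discrete genotypes; dosages
  within 0.1 of 0/1/2 are hard-called, others are excluded from the test
  only. Call rate is computed on raw missingness, keeping the two filters
  independent. The HWE sample set defaults to all samples (single,
  ancestrally homogeneous cohort assumption) and is configurable to a
  subset via `hwe_samples`.
* **The exact HWE test** conditions on the observed allele counts and sums
  the probabilities of all heterozygote configurations no more probable
  than the observed one (two-sided probability-mass ordering). A mid-P
  variant (subtract half the observed configuration's mass) is available
  behind `midp = TRUE`; the plain version is the default because the
  $10^{-6}$ screening threshold is calibrated for it.

Numerically, the conditional distribution is built by the standard
ratio recurrence in log space and normalized once; ties in the mass
ordering are compared with a relative tolerance of $10^{-7}$ so that
floating-point noise cannot drop a configuration that is analytically
tied with the observed one. The suite checks the implementation against
an independent closed-form enumeration oracle for every genotype triple
with total $\le 60$ (about 20,000 cases) at $10^{-12}$ absolute
tolerance.

## Association models

All models are ordinary least squares with the **PRS as the dependent
variable** and stage or biomarkers as predictors, adjusted for age
(years) and sex. This direction is deliberately descriptive — it compares
mean scores between phenotype groups net of age and sex — and is not a
causal model; the biology runs the other way.

Reference categories are fixed: AMD-free controls for stage, female for
sex, "neither atrophy lesion" for the joint iRORA/cRORA model. The
combined atrophy coding assigns a sample with any cRORA lesion to the
cRORA group regardless of iRORA (the reader repairs violations of this
coding with a warning), so the two dummies are never both 1.

The least-squares core (`fit_ols`) is written in the package: QR
factorization for the coefficients, $\hat\sigma^2 (X^\top X)^{-1}$ from
the R factor (un-pivoted) for the covariance, t-distribution inference
with $n - p$ degrees of freedom, and 95% confidence intervals
$\hat\beta \pm t_{0.975,\,n-p}\,\mathrm{SE}$. Rank deficiency is an error
that names the collinear columns rather than a silent coefficient drop.
P values are never adjusted for multiplicity anywhere in the package; the
analyses are exploratory by design and the outputs say so.

**Estimated marginal means.** The adjusted mean of stage $g$ is the fitted
value at that stage with age at the cohort mean and sex at the observed
male proportion (proportional weighting). Equal weighting of sex was the
open alternative; proportional weighting is the more common convention for
purely observational covariates and is what the package documents and
tests. Pairwise differences are linear contrasts $L\hat\beta$ with
variance $L \hat\Sigma L^\top$; because the covariate terms cancel in a
difference, each contrast reduces algebraically to a difference of stage
coefficients, but its standard error uses the full coefficient
covariance. The suite cross-checks every contrast, SE and P value against
the independent `emmeans` implementation on an `lm` fit of the same
model, and verifies invariance of the contrasts under re-referencing the
stage factor.

**Extended models.** Two multi-biomarker variants are fitted: variant A
(RPD + PA + HRF + age + sex) and variant B (adding iRORA + cRORA). The
pair exists to study how atrophy adjustment attenuates the RPD
coefficient when RPD and cRORA co-occur.

## The synthetic cohort generator

The generator exists so that every pipeline stage — and especially the
sign and significance of the association models — can be tested against a
known ground truth. Its defaults encode the study conditions of the
emulated cohort:

* 556 participants split 46/33/404/73 across no/early/intermediate/late
  AMD; age truncated-normal 71.6 ± 6.94 years on [55, 86] with later
  stages older (planted shifts of −3.7/−0.2/−0.1/+3.1 years relative to
  the overall mean); 34.9% male.
* ~50 clean score SNPs (complement 8, ECM 9, lipid 6, ARMS2/HTRA1 2,
  untagged 25), independent (no LD), biallelic, with genotypes drawn
  $\mathrm{Binomial}(2, p)$ — i.e. in Hardy–Weinberg proportions — and
  allele frequencies uniform on [0.05, 0.5]. Per-SNP effect sizes are
  scaled so each pathway score's standard deviation matches the published
  intermediate-AMD dispersions (AH 0.226, C 0.183, E 0.126, L 0.110,
  global 0.425); signs are random, so cohort score means are small but
  not matched to any published value.
* Decoy SNPs planted to fail each QC rule (R² = 0.2; exactly >10% missing
  cells; a heterozygote deficit with inbreeding coefficient F = 0.9 at
  allele frequency 0.5, which fails the exact test decisively from a few
  hundred samples; allele frequency 0.002).
* **Stage assignment.** Stages are assigned by a multinomial logit on the
  true global PRS and on age whose intercepts and PRS slopes are solved
  numerically (BFGS on the moment residuals) so that, for the realized
  sample, the expected stage proportions hit their targets and the
  conditional mean PRS shift of each stage versus controls equals the
  planted value (+0.175/+0.405/+0.481 by default) exactly in expectation.
  A simpler threshold-on-liability rule was considered and rejected: it
  matches proportions but cannot plant an exact shift, and the parameter-
  recovery tests need the planted shift to be the estimand. Because the
  PRS and age enter the assignment independently and are themselves
  independent, the age-adjusted stage coefficients recover the planted
  shifts (verified empirically: bias about 0.01 versus a standard error
  of 0.023 at n = 4,000).
* **Biomarkers** are drawn only for intermediate-stage samples, from
  logistic models on centered true pathway scores: RPD on the AH and E
  scores, cRORA on the AH score, PA/HRF/iRORA intercept-only. Intercepts
  are calibrated numerically (monotone root-finding on the sample linear
  predictor) so marginal prevalences hit the targets 23.8% (RPD), 47.8%
  (PA), 46.8% (HRF), 8.7% (iRORA), 7.2% (cRORA); iRORA is drawn only
  among cRORA-free samples with a rate compensated for the masking, which
  enforces the combined-model coding while preserving its marginal
  prevalence. The planted logistic coefficients are free parameters; they
  were set to (published linear estimate) / (target score variance) —
  1.39 and 2.06 for AH and E on RPD, 2.62 for AH on cRORA — so that the
  implied linear-model estimates land near the published ones (e.g. the
  recovered RPD coefficient on the AH score averages ≈ 0.069 against a
  published 0.071). Because the generative direction (biomarker given
  genotype) is the reverse of the fitted direction (score given
  biomarker), recovery tests assert sign and significance, not numerical
  equality.

What the generator does **not** emulate: linkage disequilibrium,
population stratification, relatedness, genotyping batch effects,
imputation error beyond a scalar R² and a small dosage jitter
(SD 0.02, within the hard-call tolerance), and any structure-function
relationship. Passing tests therefore demonstrate that the pipeline's
statistics behave correctly under the stated generative model, not that
the published cohort's estimates would be reproduced on real data.

## Problem sizes and runtime choices

The test suite uses the sizes at which each property is informative:
parameter recovery over 200 replicates of n = 4,000 intermediate-only
cohorts; prevalence calibration at n = 20,000; type-I error and 95% CI
coverage over 2,000 refits at n = 200; HWE oracle equivalence exhaustively
to genotype totals of 60. These sizes make the Monte-Carlo error small
relative to the acceptance bands (e.g. a pooled null-significance rate
over 4,600 tests has a standard error of ~0.3 percentage points against a
±2-point band).

## Known limitations

* Scores are only comparable within one scoring file and one allele
  alignment; no cross-panel harmonization is attempted.
* The exact HWE test assumes a single random-mating population; in a
  stratified cohort it will flag real stratification as disequilibrium.
* Multi-allelic sites are rejected (or dropped) rather than split; the
  scoring model expects biallelic lead SNPs.
* The EMM contrasts are valid for the fitted homoscedastic linear model;
  no robust or sandwich variants are provided.
* The descriptive rounding convention (one decimal on percentages,
  recomputed from integer counts) matches how such cohort tables are
  reported; full precision is preserved in all CSV outputs.
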