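# pathprs

Pathway-partitioned polygenic risk scores (PRS) and genotype–phenotype
association models for age-related macular degeneration (AMD), built for
analysts who work with imputed genotype data and structured retinal
phenotypes and want a reproducible, tested pipeline from VCF to fitted
models.

## What it computes

AMD risk is strongly polygenic, and its known risk loci cluster into a few
biological pathways. `pathprs` computes, for every sample *s*, the raw
(non-averaged) weighted dosage sum

```
PRS_s = Σ_i  β_i · d_si
```

where `d_si ∈ [0, 2]` is the effect-allele dosage of variant *i* and `β_i`
its published per-allele effect size. Besides the **global** score over all
quality-controlled variants, five pathway-specific scores (psPRS) restrict
the sum to variants whose assigned gene belongs to one pathway:

| score | pathway | genes |
|---|---|---|
| C-PRS | complement activation | *C3*, *CFB/C2*, *CFH*, *CFI* |
| AH-PRS | ARMS2/HTRA1 locus | *ARMS2/HTRA1* |
| C+AH-PRS | union of the two above | — |
| E-PRS | extracellular matrix | *ADAM19*, *ADAMTS9-AS2*, *COL4A3*, *COL8A1*, *MMP9*, *SYN3/TIMP3*, *VEGF-A* |
| L-PRS | lipid metabolism | *ABCA1*, *APOE*, *CETP*, *LIPC* |

Around the scores the package provides:

* **Variant QC** — imputation R² ≥ 0.3, genotype call rate ≥ 90%, minor
  allele frequency ≥ 1%, and a from-scratch two-sided **exact
  Hardy–Weinberg equilibrium test** (probability-mass ordering, optional
  mid-P), applied in a fixed order with deterministic failure attribution.
* **Effect-allele alignment** — scoring-file alleles are matched to the
  VCF REF/ALT encoding as-is, by flipping (`d ← 2 − d`), or after strand
  complementation; strand-ambiguous A/T and C/G SNPs are excluded by
  default.
* **Association models** on a self-written least-squares core with
  t-based inference: the *stage model* (PRS ~ AMD stage + age + sex,
  reference: no AMD, female), *per-biomarker models* on the
  intermediate-AMD subset for each score and each structural biomarker —
  reticular pseudodrusen (RPD), pigmentary abnormalities (PA),
  hyper-reflective foci (HRF), and incomplete/complete RPE and outer
  retinal atrophy (iRORA/cRORA, jointly in one model) — plus *extended*
  multi-biomarker variants, and **estimated-marginal-means pairwise stage
  contrasts** (covariates at cohort means, unadjusted P values).
* **A synthetic cohort generator** that plants known pathway effects
  (HWE genotypes, calibrated stage shifts of the global PRS, logistic
  biomarker models on true pathway scores, QC decoy SNPs) so the whole
  pipeline is testable without patient data. All shipped example data are
  synthetic.

## Worked example

The package ships a small synthetic fixture (80 samples × 16 SNPs, four of
them QC decoys) under `inst/extdata/demo`:

```r
library(pathprs)
demo <- system.file("extdata", "demo", package = "pathprs")

gm <- read_genotypes(file.path(demo, "fixture.vcf"))
gm
#> genotype_matrix: 80 samples x 16 variants
#>   imputation R2 annotated for 16 variant(s); 20 missing dosage cell(s)

qc <- apply_variant_qc(gm)
qc_verdict_counts(qc$report)
#>          pass       fail_r2 fail_callrate      fail_maf      fail_hwe
#>            12             1             1             1             1

wt     <- read_scoring_file(file.path(demo, "weights.tsv"))
cohort <- read_phenotypes(file.path(demo, "phenotypes.csv"))
scores <- compute_all_scores(impute_missing_dosage(
  align_effect_alleles(wt, qc$matrix)))
head(scores, 3)
#>   sample_id global_prs ah_prs   c_prs c_ah_prs  e_prs  l_prs
#> 1    S00001      -1.41 -0.485 0.00282   -0.482 -0.605 -0.336
#> 2    S00002      -1.30 -0.490 0.06565   -0.425 -0.151 -0.338
#> 3    S00003      -1.08 -0.490 0.20199   -0.288 -0.451 -0.341

fit_stage_model(cohort, scores)
#> model: stage_global_prs
#> n = 80  residual df = 74  R2 = 0.144
#>               term  estimate       se statistic       p    ci_low  ci_high
#>        (Intercept) -1.683000 0.569900   -2.9540 0.00421 -2.819000 -0.54780
#>         stageearly -0.101800 0.276300   -0.3684 0.71364 -0.652400  0.44880
#>  stageintermediate  0.364700 0.201000    1.8150 0.07365 -0.035780  0.76520
#>          stagelate  0.478200 0.234100    2.0430 0.04461  0.011810  0.94450
#>                age  0.006833 0.007888    0.8663 0.38914 -0.008884  0.02255
#>            sexmale  0.024290 0.100300    0.2423 0.80925 -0.175500  0.22410
```

Four of the 16 variants were removed, one per QC rule (the fixture plants
one decoy per rule). The stage coefficients are the mean difference in
global PRS of each stage versus AMD-free controls, adjusted for age and
sex: the generator plants shifts of +0.175/+0.405/+0.481 for
early/intermediate/late AMD, and even at n = 80 the fitted estimates (−0.10,
+0.36, +0.48) track the intermediate and late shifts; significance is
limited by the tiny demo cohort. Pairwise stage contrasts of the
model-adjusted means come from `emm_pairwise_contrasts(fit)`, and a full
run (`run_pipeline()`) additionally writes the QC report, score matrix,
descriptive tables, all model CSVs, a stage box plot, and a JSON manifest.

A command-line front end over the same functions lives at
`inst/cli/pathprs.R`:

```sh
Rscript inst/cli/pathprs.R simulate --out sim --seed 7 --n-samples 556
Rscript inst/cli/pathprs.R run --vcf sim/fixture.vcf \
  --weights sim/weights.tsv --phenotypes sim/phenotypes.csv --out results
```

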