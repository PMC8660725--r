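# diabclust

Phenotype-driven subtyping of young-onset type 2 diabetes in R.

Adult-onset diabetes without autoimmune markers is commonly subclassified
into four data-driven subtypes from five routine clinical variables —
age at diagnosis, BMI, HbA1c, and the HOMA2 indices of beta-cell function
(HOMA2-B) and insulin resistance (HOMA2-IR) derived from fasting glucose
and C-peptide:

| Subtype | Meaning | Signature |
|---|---|---|
| SIDD | severe insulin-deficient | low HOMA2-B, high HbA1c |
| SIRD | severe insulin-resistant | high HOMA2-IR, high C-peptide |
| MOD  | mild obesity-related | high BMI, moderate glycaemia |
| MARD | mild age-related | oldest at diagnosis, mildest disturbance |

`diabclust` is for epidemiologists and clinical researchers who want to
apply this subclassification to their own cohorts, reproducibly and with
every rule tested. It implements the full pipeline:

* **Ingestion** — CSV phenotype tables with unit harmonisation (HbA1c
  %↔mmol/mol by the IFCC/NGSP master equation, glucose mg/dl↔mmol/l,
  C-peptide ng/ml↔nmol/l), total row accounting (every row becomes a
  record or a reject with a reason), YAML configs for all reference data.
* **HOMA2-style indices** — a documented steady-state model of the
  fasting glucose/C-peptide feedback loop, normalised so the healthy
  reference state maps to (HOMA2-B, HOMA2-IR) = (100, 1), solved by
  damped Newton iteration and certified against an independent
  closed-form inversion. Inputs are capped to glucose [3, 25] mmol/l and
  C-peptide [0.2, 3.5] ng/ml.
* **Supervised assignment** — z-scoring with reference-cohort scaling
  parameters, single-pass 5-SD outlier exclusion, nearest-centroid
  classification (Euclidean; deterministic tie-break), subgroup tables
  overall/per sex, and a diabetes-duration sensitivity split.
* **De novo clustering** — sex-stratified Lloyd k-means with seeded
  restarts, silhouette-based choice of k, optimal cross-sex label
  alignment, and concordance tables against the supervised subtypes.
* **Type 1 diabetes genetic risk score** — 9 SNPs (7 additive + the
  rs2187668/rs3957146 HLA DR3/DR4 haplotype combination table), VCF or
  tabular dosage input with effect-allele orientation, percentile
  proportions against a reference distribution, logistic discrimination.
* **Complications and statistics** — MDRD eGFR, CKD staging, composite
  outcomes with three-valued logic, prevalence/treatment tables with
  available-data denominators, χ², t/ANOVA (optionally
  duration-adjusted), covariate-adjusted odds ratios, Bonferroni flags.
* **Synthetic cohorts** — a seeded generator reproducing the published
  summary structure of a young-onset clinic cohort (per-sex subtype
  mixture, moment-matched lognormal skew, subtype-specific complication
  prevalences, HWE genotypes), so the entire pipeline is testable
  without access to patient data.

The shipped centroid coordinates and GRS weights are clearly labelled
synthetic stand-ins (`inst/extdata/synthetic_*`); scientific use requires
your own validated configs (`readCentroidModel()`, `readGRSConfig()`).

## Worked example

```r
library(diabclust)

spec   <- wellgenCohortSpec(n = 2000)        # published-summary generative spec
cohort <- generateCohort(spec, seed = 42)    # phenotypes + sidecar truth labels
model  <- centroidModelFromSpec(spec)        # centroids implied by the spec
res    <- classifyCohort(cohort$records, model)
res$table
#>   label   n   pct n_male pct_male n_female pct_female
#> 1  SIDD 919 46.16    533    47.13      386      44.88
#> 2  SIRD  55  2.76     32     2.83       23       2.67
#> 3   MOD 656 32.95    326    28.82      330      38.37
#> 4  MARD 361 18.13    240    21.22      121      14.07
```

The insulin-deficient subtype is the largest subgroup overall and in men,
while MOD is relatively more common in women — the qualitative pattern
the generator encodes. With the full published spreads the four
components overlap heavily, so the classified shares shrink toward each
other relative to the generating mixture; at a quarter of the published
SDs the classifier recovers ≥99% of true labels (see the acceptance
output below).

HOMA2-style indices for an insulin-deficient-like and an
obesity-related-like fasting profile:

```r
homa2(c(10.77, 7.85), c(0.68, 0.89))[, 1:2]
#>   homa2_b homa2_ir
#> 1    42.6      2.2
#> 2    78.6      2.5
```

De novo two-cluster solution versus the supervised subtypes:

```r
dn <- sexStratifiedDenovo(cohort$records, k = 2, nRestarts = 10, seed = 42)
sup <- classifyCohort(cohort$records, model, excludeSD = Inf)
concordance(dn$labels, sup$assignments$label, sex = cohort$records$sex)$overlap
#>   cluster best_match overlap_pct overlap_pct_male overlap_pct_female
#> 1       1       SIDD        82.7             76.8               93.1
#> 2       2        MOD        67.6             68.5               66.8
```

Cluster 1 (the dominant de novo cluster) is essentially the SIDD
subgroup; cluster 2 best matches MOD.

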