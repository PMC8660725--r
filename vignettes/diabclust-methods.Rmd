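---
title: "Methods: phenotype-driven subtyping of young-onset type 2 diabetes"
author: "diabclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-driven subtyping of young-onset type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabclust)
```

# The subtyping model

Adult-onset diabetes is clinically heterogeneous. A widely used data-driven
subclassification partitions patients without autoimmune markers into four
subtypes on the basis of five routinely measured variables — age at
diagnosis (years), BMI (kg/m²), HbA1c (mmol/mol), and the HOMA2 indices of
beta-cell function (HOMA2-B, % of normal) and insulin resistance (HOMA2-IR,
dimensionless) computed from fasting glucose and fasting C-peptide:

* **SIDD** — severe insulin-deficient diabetes: low HOMA2-B, high HbA1c;
* **SIRD** — severe insulin-resistant diabetes: high HOMA2-IR and C-peptide;
* **MOD** — mild obesity-related diabetes: high BMI, moderate glycaemia;
* **MARD** — mild age-related diabetes: oldest at diagnosis, mildest
  metabolic disturbance.

`diabclust` implements both routes to these subtypes:

1. **Supervised (nearest centroid).** Each participant's five features are
   z-scored with *reference-cohort* scaling parameters (mean and SD per
   feature, carried in a `CentroidModel`) and assigned to the subtype whose
   reference centroid is nearest in Euclidean distance. The reference
   coordinates are configuration, not code: the coordinates actually used
   in clinical research derive from the original Swedish derivation cohort
   and must be supplied by the user. The package ships a clearly labelled
   synthetic stand-in (`exampleCentroidModel()`, built from published
   summary means of a young European comparison cohort) for interface
   examples and tests only.
2. **De novo (k-means + silhouette).** Features are re-scaled *from the
   data itself*, k-means is run separately within each sex, and the number
   of clusters is chosen by maximal mean silhouette width. Cross-sex
   cluster labels are aligned by optimal matching of the scaled cluster
   centers, and the de novo partition is cross-tabulated against the
   supervised labels (`concordance()`).

## Preprocessing rules

* **Outlier exclusion.** Participants more than 5 SDs from the cohort mean
  on any clustering feature are excluded. The rule is applied in a single
  pass: means and SDs are computed once on the input set and not
  recomputed after removal. This is the simplest deterministic reading; an
  iterated rule would exclude (slightly) more. A feature with zero SD
  excludes nobody.
* **HOMA2 input capping.** Fasting glucose outside [3, 25] mmol/l and
  fasting C-peptide outside [0.2, 3.5] ng/ml are capped to the proximal
  limit before the indices are computed (the operating range of the HOMA2
  model). The C-peptide limits are defined in ng/ml and converted to the
  canonical nmol/l with the molar-mass factor below. Capping is
  idempotent and flagged per analyte.
* **Units.** Canonical units are HbA1c mmol/mol, glucose mmol/l,
  C-peptide nmol/l, creatinine mg/dl. Conversions: glucose mg/dl ÷ 18.016;
  C-peptide nmol/l = 0.331 × ng/ml (molar mass of C-peptide, configurable);
  HbA1c % = 0.09148 × mmol/mol + 2.152 (the IFCC↔NGSP master equation,
  configurable). Published cohort tables that print both HbA1c units are
  reproduced by the master equation to within 0.1 percentage points,
  which is the agreement one can expect without knowing whether a given
  source derived or measured its second unit.
* **Scaling.** `scaleFeatures()` applies `(t(x) − mean)/SD` per feature
  with an optional log transform hook `t` (off by default). The hook
  exists because reference scaling conventions for the right-skewed HOMA2
  indices differ between derivations and are not always documented; a
  config flag makes either convention expressible without code changes.

## Tie-breaking and degenerate inputs

Exact distance ties in nearest-centroid assignment are broken by the
model's declared label order (SIDD first). Ties are measure-zero for
continuous data but matter for determinism on constructed inputs. An empty
cohort, an all-excluded cohort, a zero contingency-table margin and a
k-means stratum smaller than k are errors; an empty duration stratum
yields a zero-count table with a warning.

# The HOMA2-style index model

The HOMA2 indices are defined through a steady-state model of the fasting
glucose–insulin feedback loop, with C-peptide (co-secreted equimolar with
insulin, cleared at a near-constant rate) standing in for insulin
secretion. The widely used implementation of this computation is
distributed only as a calculator program; `diabclust` instead specifies
its own fully documented steady-state model with the same interface,
normalisation and qualitative behaviour, and certifies it against an
independently computed grid (below). Values are therefore *HOMA2-style*
indices: on the same scale and monotone in the same directions, suitable
for clustering and simulation, but not bit-identical to any external
calculator.

Two dimensionless parameters describe an individual: beta-cell function
*b* (HOMA2-B = 100·b) and insulin sensitivity *s* (HOMA2-IR = 1/s). With
concentrations relative to the healthy fasting reference G_ref = 4.5
mmol/l, C_ref = 0.5 nmol/l:

* **Secretion** (beta-cell dose–response, Hill form, half-maximal at
  K_B = 10 mmol/l): C = b · C_ref · σ(G)/σ(G_ref), σ(G) = G²/(G² + K_B²).
* **Glucose balance** (production = disposal), with c = C/C_ref:
  * production = (1 + κ)/(1 + κ·s·c), κ = 2 — hepatic glucose output
    suppressed by insulin, at most (1+κ)-fold above reference;
  * disposal = (d0 + d1·s·c) · φ(G) + renal(G), d0 = d1 = 0.5 — equal
    insulin-independent and insulin-dependent shares at reference;
    φ(G) = G(G_ref + K_U)/(G_ref(G + K_U)), K_U = 10 mmol/l — saturable
    uptake; renal(G) = 0.05·max(0, G − 10)/G_ref — glycosuria above the
    renal threshold, which also guarantees a steady state exists for
    every (b, s).

At (b, s) = (1, 1) the steady state is exactly (G_ref, C_ref), so the
reference healthy fasting state maps to (HOMA2-B, HOMA2-IR) = (100, 1) by
construction. `homa2()` inverts the model numerically: damped Newton
iteration on (log b, log s) with the forward steady state obtained by
root-finding (tolerance 1e-12 on the balance equation, 1e-9 on the scaled
Newton residual, at most 50 iterations; non-convergence is an error that
carries the offending inputs). The same model admits a closed-form
inversion (the balance equation is quadratic in s·c), which is kept *out*
of the package and used as the independent oracle: the shipped grid
`inst/extdata/synthetic_homa2_grid.csv` was computed once with the
closed form, and the test suite requires the Newton route to reproduce it
within 5% relative (observed agreement is ~1e-10).

The calibration (K_B, K_U, κ, d0, d1, renal term) was chosen once so that
the model lands near published cohort-level index values at typical
young-onset operating points — e.g. glucose 9.26 mmol/l with C-peptide
0.76 nmol/l yields HOMA2-B ≈ 55 and HOMA2-IR ≈ 2.3 — and was not adjusted
afterwards. Monotonicity (HOMA2-B strictly decreasing in glucose,
both indices strictly increasing in C-peptide) holds analytically over
the whole capped domain and is property-tested.

# De novo clustering details

* **Lloyd k-means, seeded restarts.** `kmeansRestarts()` runs Lloyd's
  algorithm from random initial centers (distinct data points) and keeps
  the lowest total within-cluster SS over `nRestarts` (default 100, as a
  conventional multiple-restart default). Convergence: center shift
  < 1e-6 or 300 iterations. An emptied cluster is re-seeded at the point
  farthest from its assigned center. The objective is asserted
  non-increasing across iterations (except across a forced re-seed). Each
  restart draws from a seed stream derived from (seed, k, restart), so
  results are reproducible and independent of evaluation order. The
  implementation is cross-checked in the tests against `stats::kmeans`
  and, for n ≤ 8, exhaustive bipartition enumeration.
* **Silhouette.** Standard Euclidean silhouette, singleton clusters
  contribute 0; verified against `cluster::silhouette` and naive
  recomputation. `selectK()` scans k = 2..8 by default (the smallest
  range that brackets the plausible 2–5 subtype solutions with head
  room), maximising mean silhouette; ties go to the smaller k.
* **Sex stratification and alignment.** Clustering runs within sex on
  sex-specific self-scaling. Labels are aligned across sexes by the
  optimal 1-to-1 matching of scaled cluster centers (exact enumeration
  over permutations; k ≤ 8). Global label 1 is the largest cluster of
  the reference (first) stratum, so "cluster 1" consistently denotes the
  dominant phenotype.

# Genetic risk score

The type 1 diabetes GRS is a weighted sum over nine SNPs: seven additive
terms (weight × effect-allele dosage) plus an HLA haplotype term looked up
from a 3×3 genotype-combination table over rs2187668 (tagging DR3) and
rs3957146 (a perfect-LD proxy for rs7454108, tagging DR4), using
hard-called (rounded) genotypes. The combination table captures the
super-additive DR3/DR4 heterozygote risk. All weights, effect alleles,
allele frequencies and reference percentile cut-offs are configuration;
the shipped `exampleGRSConfig()` carries synthetic illustrative weights of
realistic magnitude because the validated published weight table is not
redistributable here. Dosages from VCF (ALT copies or the DS field) or
tabular files are oriented to the configured effect allele (flipping
2 − d when the file counts the other allele); unresolvable allele
mismatches mark the variant unusable. Missing additive dosages are imputed
at 2 × frequency and flagged; missing haplotype genotypes are an error
unless a fallback weight is configured. Group discrimination is a
maximum-likelihood logistic fit (slope ± SE, Wald p), with separation
detected and flagged rather than fatal.

# Outcomes and statistics

* **eGFR** by the 4-variable MDRD equation with the IDMS-traceable
  constant 175 (186 available by argument, since sources that cite "the
  MDRD formula" without qualification may mean either).
* **CKD staging**: >90 normal, (60, 90] early, (30, 60] moderate,
  ≤30 severe; boundary values go to the worse stage (published band
  definitions overlap at their endpoints, so a convention is required and
  tested).
* **Composites** use three-valued logic: unknown OR true is true, unknown
  OR false stays unknown. Prevalence and treatment tables always use
  available-data denominators, never the full group size.
* **Comparisons**: Pearson χ² without continuity correction; classical
  pooled-variance t test / one-way ANOVA (F = t² for two groups);
  duration adjustment via a linear model with duration entered first and
  the group term tested by F. Complication contrasts between two subtypes
  use logistic regression adjusted by default for age at diagnosis, sex
  and diabetes duration — the most inclusive of the covariate sets seen
  in practice; the covariates are an argument. Bonferroni significance
  flags use p < α/m with m recorded.

# The synthetic cohort generator

Because the clinical cohorts this methodology is applied to are not
publicly deposited, the package is exercised end-to-end on synthetic
cohorts (`wellgenCohortSpec()`, `generateCohort()`,
`attachOutcomes()`, `generateGenotypes()`). The default spec reproduces
the published summary structure of a young-onset Indian clinic cohort:

* sex ratio 56% male; per-sex subtype mixing proportions (SIDD dominant
  in men at ~61%, MOD dominant in women at ~53%, SIRD ~1% overall);
* per-sex, per-subtype means and SDs for all seven clinical variables;
* right-skewed variables (glucose, HbA1c, C-peptide, HOMA2-B, HOMA2-IR)
  drawn lognormal with moment-matched parameters, age and BMI normal;
* diabetes duration lognormal with mean 9.72 y, SD 8.21 y;
* subtype-specific complication prevalences and treatment-category
  probabilities, with per-outcome missingness rates that reproduce
  realistic available-data denominators (retinopathy graded in ~41% of
  participants, for example).

What the generator deliberately does *not* emulate: within-subtype
correlations between features (only marginal moments are published, so
features are independent within subtype and sex), measurement error and
assay drift, informative missingness, longitudinal subtype transitions,
and the physiological coupling between sampled HOMA2 indices and sampled
glucose/C-peptide in the default `feature_space` mode. The alternative
`raw_measurement` mode restores that coupling by sampling the analytes
and pushing them through `homa2()`, at the cost of only approximating the
subtype HOMA2 targets (flagged on the result). Consequently, green tests
demonstrate the pipeline's correctness and calibration under a known
generating process — not that real cohorts satisfy that process.

Truth labels are emitted in a sidecar table, never in the phenotype
table. All generators are pure functions of (spec, seed).

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use cohorts of n = 4000–5000
for classification experiments, n = 20,000–50,000 for law-of-large-number
checks of the generator, 20 seeded replicates (3 k-means restarts each)
for the silhouette model-selection experiment, and 2000 null replicates
for type-I-error calibration of the χ² and ANOVA paths. These sizes were
chosen to make Monte-Carlo error comfortably smaller than the asserted
tolerances while keeping a full run on one CPU in minutes. Every source
of randomness flows through explicit integer seeds (`withr::with_seed`
streams derived from a master seed), so all results in the README and
the acceptance output are exactly reproducible.

# Known limitations

* The shipped centroid model and GRS weights are synthetic stand-ins;
  scientific use requires the user's own validated configs.
* HOMA2-style indices are a documented re-specification, not the
  calculator-distributed model; absolute values can differ by more than
  the 5% internal certification tolerance from other software,
  particularly at extreme C-peptide.
* Single-pass outlier exclusion and the boundary conventions above are
  choices among defensible readings; both are configurable or documented
  where they bite.
* The k-means seed-stream design makes results independent of row order
  only up to local-optimum ties; with few restarts on weakly separated
  data different row orders can reach different local optima of equal or
  near-equal objective.
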