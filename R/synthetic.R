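## Synthetic cohorts with the statistical structure the analysis assumes:
## a four-component mixture over the clinical features with per-sex,
## per-subtype means and SDs, subtype-specific complication prevalences and
## treatment probabilities, lognormal diabetes duration, and
## Hardy-Weinberg genotypes for the genetic risk score. Every generator is
## a pure function of (spec, seed).

# moment-matched lognormal draw: E = m, SD = s
.rlnormMS <- function(n, m, s) {
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

.drawFeature <- function(n, m, s, family) {
  if (identical(family, "lognormal")) .rlnormMS(n, m, s)
  else stats::rnorm(n, m, s)
}

#' Default generative spec: a young-onset Indian-type cohort
#'
#' A [CohortSpec-class] whose per-sex subtype mixing proportions, per-sex
#' per-feature means and SDs, complication prevalences, treatment
#' probabilities, sex ratio, duration distribution and per-outcome
#' missingness rates reproduce the published summary structure of a
#' young-onset type 2 diabetes clinic cohort in which SIDD dominates in men
#' and MOD in women. Right-skewed features (C-peptide, HOMA2-B, HOMA2-IR)
#' are generated lognormal with moment-matched parameters; the rare SIRD
#' component (about 1\% overall) is retained so rare-subgroup code paths
#' are exercised. Features are sampled independently within a subtype
#' (marginal means/SDs are specified; the within-subtype correlation
#' structure is not).
#'
#' @param n Cohort size.
#' @param sdFactor Multiplier applied to every feature SD (1 = published
#'   spread; smaller values separate the clusters, used by label-recovery
#'   tests).
#' @param mode Generation mode, see [CohortSpec-class].
#'
#' @return A [CohortSpec-class] object.
#' @export
wellgenCohortSpec <- function(n = 5000, sdFactor = 1,
                              mode = "feature_space") {
  f <- function(age, bmi, glu, a1c, cpep, b, ir)
    list(center = c(age_at_diagnosis = age[1], bmi = bmi[1],
                    fasting_glucose = glu[1], hba1c = a1c[1],
                    fasting_cpeptide = cpep[1], homa2_b = b[1],
                    homa2_ir = ir[1]),
         spread = c(age_at_diagnosis = age[2], bmi = bmi[2],
                    fasting_glucose = glu[2], hba1c = a1c[2],
                    fasting_cpeptide = cpep[2], homa2_b = b[2],
                    homa2_ir = ir[2]) * sdFactor)
  family <- c(age_at_diagnosis = "normal", bmi = "normal",
              fasting_glucose = "lognormal", hba1c = "lognormal",
              fasting_cpeptide = "lognormal", homa2_b = "lognormal",
              homa2_ir = "lognormal")

  male <- list(
    SIDD = f(c(36.96, 5.67), c(24.44, 3.08), c(10.29, 3.22),
             c(84.67, 20.57), c(0.66, 0.38), c(39.33, 22.5),
             c(1.96, 1.34)),
    SIRD = f(c(42.07, 10.27), c(28.75, 3.54), c(5.75, 1.0),
             c(49.07, 10.27), c(2.17, 0.44), c(229.16, 40.98),
             c(4.99, 1.23)),
    MOD  = f(c(36.59, 5.43), c(28.77, 3.67), c(7.63, 2.43),
             c(59.94, 13.35), c(1.08, 0.51), c(92.27, 42.49),
             c(2.76, 1.41)),
    MARD = f(c(40.7, 4.12), c(23.41, 2.34), c(6.52, 1.53),
             c(47.55, 10.02), c(0.60, 0.30), c(75.58, 31.92),
             c(1.47, 0.78))
  )
  female <- list(
    SIDD = f(c(36.68, 6.06), c(26.07, 3.82), c(11.64, 3.53),
             c(91.22, 16.11), c(0.71, 0.41), c(34.67, 21.47),
             c(2.29, 1.49)),
    SIRD = f(c(37.51, 4.92), c(28.23, 5.92), c(5.89, 1.44),
             c(59.63, 13.21), c(1.98, 0.63), c(209.54, 41.32),
             c(4.63, 1.71)),
    MOD  = f(c(36.05, 5.96), c(28.18, 4.22), c(7.98, 2.33),
             c(57.34, 12.57), c(0.77, 0.42), c(68.5, 39.13),
             c(1.98, 1.12)),
    MARD = f(c(41.98, 2.51), c(21.69, 2.75), c(6.33, 0.97),
             c(44.85, 12.98), c(0.42, 0.20), c(59.05, 19.27),
             c(1.03, 0.47))
  )
  propMale <- c(SIDD = 547, SIRD = 5, MOD = 230, MARD = 120) / 902
  propFemale <- c(SIDD = 304, SIRD = 13, MOD = 378, MARD = 15) / 710

  outcomePrev <- list(
    SIDD = c(cvd = 61 / 851, nephropathy = 340 / 851,
             macroalbuminuria = 172 / 816, retinopathy = 112 / 304,
             neuropathy = 322 / 829),
    SIRD = c(cvd = 0 / 18, nephropathy = 6 / 18,
             macroalbuminuria = 0 / 18, retinopathy = 4 / 7,
             neuropathy = 9 / 18),
    MOD  = c(cvd = 39 / 608, nephropathy = 147 / 608,
             macroalbuminuria = 66 / 582, retinopathy = 51 / 284,
             neuropathy = 323 / 600),
    MARD = c(cvd = 20 / 135, nephropathy = 68 / 135,
             macroalbuminuria = 12 / 128, retinopathy = 13 / 62,
             neuropathy = 56 / 129)
  )
  treatment <- list(
    SIDD = c(diet_only = 68, oha_only = 457, insulin_only = 58,
             oha_plus_insulin = 268) / 851,
    SIRD = c(diet_only = 4, oha_only = 13, insulin_only = 0,
             oha_plus_insulin = 1) / 18,
    MOD  = c(diet_only = 54, oha_only = 409, insulin_only = 19,
             oha_plus_insulin = 126) / 608,
    MARD = c(diet_only = 9, oha_only = 100, insulin_only = 8,
             oha_plus_insulin = 18) / 135
  )

  clusters <- lapply(subtypeLabels(), function(l)
    ClusterSpec(
      label = l,
      proportion = c(male = unname(propMale[l]),
                     female = unname(propFemale[l])),
      center = list(male = male[[l]]$center,
                    female = female[[l]]$center),
      spread = list(male = male[[l]]$spread,
                    female = female[[l]]$spread),
      family = family,
      outcomePrev = outcomePrev[[l]],
      treatmentProb = treatment[[l]]
    ))
  CohortSpec(
    n = n, maleFraction = 902 / 1612, clusters = clusters,
    durationMeanSD = c(9.72, 8.21), mode = mode,
    # fraction of participants with the outcome unrecorded
    missingness = c(cvd = 0, nephropathy = 0,
                    macroalbuminuria = 1 - 1544 / 1612,
                    retinopathy = 1 - 657 / 1612,
                    neuropathy = 1 - 1576 / 1612)
  )
}

#' Generate a synthetic cohort
#'
#' Draws sex, subtype (per-sex mixing proportions), clinical features
#' (per-sex per-subtype means/SDs, normal or moment-matched lognormal) and
#' diabetes duration. In \code{feature_space} mode HOMA2 indices are drawn
#' directly from the cluster specs; in \code{raw_measurement} mode fasting
#' glucose and C-peptide are drawn and the indices are computed through
#' [homa2()] (nothing is inverted, so cluster HOMA2 targets then hold only
#' approximately and the result carries
#' \code{attr(, "homa2_approximate") = TRUE}).
#'
#' The truth labels are returned in a separate element, never as a column
#' of the phenotype table, so downstream classification cannot use them.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Integer seed; the generator is a pure function of
#'   \code{(spec, seed)}.
#'
#' @return List with \code{records} (phenotype data.frame with
#'   participant_id, sex, clinical columns) and \code{truth} (data.frame
#'   participant_id, label).
#' @export
generateCohort <- function(spec, seed = 1L) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- as.integer(spec@n)
  labels <- cohortClusterLabels(spec)
  withr::with_seed(as.integer(seed), {
    sex <- ifelse(stats::runif(n) < spec@maleFraction, "male", "female")
    cl <- character(n)
    for (s in c("male", "female")) {
      idx <- sex == s
      props <- vapply(spec@clusters, function(c) c@proportion[[s]], 0)
      cl[idx] <- sample(labels, sum(idx), replace = TRUE, prob = props)
    }
    feats <- c("age_at_diagnosis", "bmi", "fasting_glucose", "hba1c",
               "fasting_cpeptide", "homa2_b", "homa2_ir")
    M <- matrix(NA_real_, n, length(feats),
                dimnames = list(NULL, feats))
    for (ci in seq_along(spec@clusters)) {
      cs <- spec@clusters[[ci]]
      for (s in c("male", "female")) {
        idx <- which(sex == s & cl == cs@label)
        if (!length(idx)) next
        for (ft in feats) {
          fam <- if (ft %in% names(cs@family)) cs@family[[ft]] else "normal"
          M[idx, ft] <- .drawFeature(length(idx),
                                     cs@center[[s]][[ft]],
                                     cs@spread[[s]][[ft]], fam)
        }
      }
    }
    duration <- .rlnormMS(n, spec@durationMeanSD[1], spec@durationMeanSD[2])
    rec <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      sex = sex,
      age_at_diagnosis = M[, "age_at_diagnosis"],
      diabetes_duration = duration,
      bmi = M[, "bmi"],
      hba1c = M[, "hba1c"],
      fasting_glucose = M[, "fasting_glucose"],
      fasting_cpeptide = M[, "fasting_cpeptide"],
      stringsAsFactors = FALSE
    )
    approx <- FALSE
    if (spec@mode == "feature_space") {
      rec$homa2_b <- M[, "homa2_b"]
      rec$homa2_ir <- M[, "homa2_ir"]
    } else {
      idx <- homa2(rec$fasting_glucose, rec$fasting_cpeptide)
      rec$homa2_b <- idx$homa2_b
      rec$homa2_ir <- idx$homa2_ir
      approx <- TRUE
    }
    # serum creatinine: mildly right-skewed, higher in men
    rec$serum_creatinine <- .rlnormMS(n, ifelse(sex == "male", 1.0, 0.8),
                                      0.25)
    out <- list(records = rec,
                truth = data.frame(participant_id = rec$participant_id,
                                   label = cl, stringsAsFactors = FALSE))
    attr(out, "homa2_approximate") <- approx
    out
  })
}

#' Attach complication and treatment outcomes to a synthetic cohort
#'
#' Each outcome is Bernoulli with its subtype-specific prevalence; the
#' treatment category is a single multinomial draw per participant.
#' Per-outcome missingness (from the spec, or the \code{missingness}
#' override) blanks a random subset to NA, reproducing available-data
#' denominators downstream.
#'
#' @param cohort List from [generateCohort()].
#' @param spec The [CohortSpec-class] used to generate it.
#' @param seed Integer seed (independent of the feature seed).
#' @param missingness Optional named override of per-outcome missingness.
#'
#' @return \code{cohort} with outcome/treatment columns added to
#'   \code{$records} (\code{cvd} is split into coronary_event/stroke 3:1,
#'   retinopathy into NPDR/PDR; \code{macroalbuminuria},
#'   \code{neuropathy}, \code{treatment} as flags/categories).
#' @export
attachOutcomes <- function(cohort, spec, seed = 1L, missingness = NULL) {
  rec <- cohort$records
  lab <- cohort$truth$label
  n <- nrow(rec)
  miss <- if (is.null(missingness)) spec@missingness else missingness
  specOf <- stats::setNames(spec@clusters, cohortClusterLabels(spec))
  withr::with_seed(as.integer(seed) + 1000003L, {
    draw <- function(outcome) {
      p <- vapply(lab, function(l) {
        pv <- specOf[[l]]@outcomePrev
        if (outcome %in% names(pv)) pv[[outcome]] else 0
      }, 0)
      if (any(p < 0 | p > 1)) stop("prevalence outside [0, 1]")
      v <- stats::runif(n) < p
      m <- if (outcome %in% names(miss)) miss[[outcome]] else 0
      if (m > 0) v[stats::runif(n) < m] <- NA
      v
    }
    cvd <- draw("cvd")
    coronary <- cvd & (stats::runif(n) < 0.75)
    stroke <- cvd & !coronary
    # a few participants have both recorded event types
    both <- which(cvd & stats::runif(n) < 0.05)
    coronary[both] <- TRUE; stroke[both] <- TRUE
    rec$coronary_event <- coronary
    rec$stroke <- stroke
    rec$macroalbuminuria <- draw("macroalbuminuria")
    retino <- draw("retinopathy")
    grade <- ifelse(is.na(retino), NA_character_,
                    ifelse(!retino, "none",
                           ifelse(stats::runif(n) < 0.93, "NPDR", "PDR")))
    rec$retinopathy_grade <- grade
    rec$neuropathy <- draw("neuropathy")
    rec$treatment <- vapply(lab, function(l) {
      pr <- specOf[[l]]@treatmentProb
      sample(names(pr), 1L, prob = pr)
    }, "")
  })
  cohort$records <- rec
  cohort
}

#' Generate Hardy-Weinberg genotype dosages
#'
#' Independent loci with dosages ~ Binomial(2, p) per locus.
#'
#' @param n Number of individuals.
#' @param alleleFreqs Named numeric vector of effect-allele frequencies in
#'   (0, 1); names are rsids.
#' @param seed Integer seed.
#'
#' @return List with \code{dosages} (n x loci matrix, sample names
#'   \code{S1..Sn}) and \code{freqs}.
#' @export
generateGenotypes <- function(n, alleleFreqs, seed = 1L) {
  if (any(alleleFreqs <= 0) || any(alleleFreqs >= 1))
    stop("allele frequencies must lie in (0, 1)")
  withr::with_seed(as.integer(seed), {
    D <- vapply(alleleFreqs, function(p) stats::rbinom(n, 2L, p),
                numeric(n))
    if (n == 1L) D <- matrix(D, nrow = 1,
                             dimnames = list(NULL, names(alleleFreqs)))
    rownames(D) <- paste0("S", seq_len(n))
    list(dosages = D, freqs = alleleFreqs)
  })
}

#' Effect-allele frequencies from a GRSConfig
#'
#' Convenience: frequencies for every score SNP (additive SNPs from the
#' config's \code{eaf}; haplotype SNPs default to 0.1 each, typical for the
#' HLA tag alleles).
#'
#' @param config A [GRSConfig-class].
#' @param haplotypeFreqs Frequencies for the two haplotype SNPs.
#' @return Named numeric vector usable with [generateGenotypes()].
#' @export
grsConfigFrequencies <- function(config, haplotypeFreqs = c(0.1, 0.1)) {
  c(stats::setNames(config@snps$eaf, config@snps$rsid),
    stats::setNames(haplotypeFreqs,
                    c(config@haplotypeA, config@haplotypeB)))
}

#' Write genotype dosages as a minimal VCF
#'
#' Emits a VCF v4.2 with GT and DS FORMAT fields, one pseudo-position per
#' locus, REF/ALT set so that ALT is the counted (effect) allele. The file
#' round-trips exactly through [readDosages()].
#'
#' @param dosages n x loci matrix (values in [0, 2]).
#' @param path Output path (should end in .vcf).
#' @param alleles Optional data.frame (rsid, ref, alt); defaults to REF=G,
#'   ALT=A for every locus.
#' @return Invisibly, the path.
#' @export
writeVCF <- function(dosages, path, alleles = NULL) {
  rsids <- colnames(dosages)
  samples <- rownames(dosages)
  if (is.null(alleles))
    alleles <- data.frame(rsid = rsids, ref = "G", alt = "A",
                          stringsAsFactors = FALSE)
  gtOf <- function(d) {
    hard <- round(d)
    c("0/0", "0/1", "1/1")[hard + 1]
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Dosage of ALT allele\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  for (j in seq_along(rsids)) {
    al <- alleles[alleles$rsid == rsids[j], ]
    d <- dosages[, j]
    cells <- paste(gtOf(d), format(d, trim = TRUE, digits = 6), sep = ":")
    cells[is.na(d)] <- "./.:."
    lines <- c(lines, paste(c("1", as.character(1000 + j), rsids[j],
                              al$ref, al$alt, ".", "PASS", ".", "GT:DS",
                              cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a CentroidModel from a cohort spec's generating means
#'
#' Sex-weighted subtype means of the five clustering features become the
#' centroids; the mixture's overall mean and SD per feature become the
#' scaling parameters (component-mixture moments, not simulation). This is
#' the model a supervised classifier "should" use for data generated from
#' \code{spec}, and is the basis of the label-recovery checks.
#'
#' @param spec A [CohortSpec-class].
#' @return A [CentroidModel-class].
#' @export
centroidModelFromSpec <- function(spec) {
  feats <- clusteringFeatures()
  labels <- cohortClusterLabels(spec)
  pm <- spec@maleFraction
  # overall mixing proportion of each cluster
  w <- vapply(spec@clusters, function(cs)
    pm * cs@proportion[["male"]] + (1 - pm) * cs@proportion[["female"]], 0)
  clMean <- t(vapply(spec@clusters, function(cs)
    vapply(feats, function(ft)
      (pm * cs@proportion[["male"]] * cs@center[["male"]][[ft]] +
         (1 - pm) * cs@proportion[["female"]] *
           cs@center[["female"]][[ft]]) /
        (pm * cs@proportion[["male"]] +
           (1 - pm) * cs@proportion[["female"]]), 0),
    numeric(length(feats))))
  # mixture moments per feature over (sex x cluster) components
  mixMean <- numeric(length(feats)); mixVar <- numeric(length(feats))
  names(mixMean) <- names(mixVar) <- feats
  for (ft in feats) {
    ws <- c(); ms <- c(); vs <- c()
    for (ci in seq_along(spec@clusters)) {
      cs <- spec@clusters[[ci]]
      for (s in c("male", "female")) {
        wgt <- (if (s == "male") pm else 1 - pm) * cs@proportion[[s]]
        ws <- c(ws, wgt)
        ms <- c(ms, cs@center[[s]][[ft]])
        vs <- c(vs, cs@spread[[s]][[ft]]^2)
      }
    }
    mixMean[ft] <- sum(ws * ms)
    mixVar[ft] <- sum(ws * (vs + ms^2)) - mixMean[ft]^2
  }
  Z <- sweep(sweep(clMean, 2, mixMean, "-"), 2, sqrt(mixVar), "/")
  CentroidModel(Z, center = mixMean, scale = sqrt(mixVar),
                labels = labels, featureOrder = feats)
}

#' Shipped example centroid model (synthetic stand-in)
#'
#' A reference centroid model in the published coordinate convention:
#' per-feature scaling means/SDs of a young European comparison cohort and
#' four centroids placed at its published subtype means, z-scored with
#' those parameters. The true reference coordinates used in practice come
#' from the original Swedish derivation and are not published in this
#' package's sources, so this model is a clearly labelled synthetic
#' stand-in for interface examples and tests, not a clinical instrument.
#' It is also shipped as a YAML config at
#' \code{system.file("extdata", "synthetic_andis_like_centroids.yaml",
#' package = "diabclust")}.
#'
#' @return A [CentroidModel-class].
#' @export
exampleCentroidModel <- function() {
  feats <- clusteringFeatures()
  center <- c(age_at_diagnosis = 38.83, bmi = 32.96, hba1c = 69.28,
              homa2_b = 84.11, homa2_ir = 3.21)
  scale <- c(age_at_diagnosis = 5.96, bmi = 6.92, hba1c = 25.88,
             homa2_b = 48.91, homa2_ir = 1.58)
  # subtype means; HOMA2-B for SIRD is the sex-weighted value (the pooled
  # figure in the source summary is inconsistent with its sex-specific
  # values and was not used)
  raw <- rbind(
    SIDD = c(38.98, 28.29, 100.6, 41.03, 2.67),
    SIRD = c(39.94, 36.62, 55.19, 197.93, 6.17),
    MOD  = c(38.56, 34.92, 58.87, 94.79, 3.31),
    MARD = c(42.50, 24.11, 45.85, 80.15, 1.78)
  )
  colnames(raw) <- feats
  Z <- sweep(sweep(raw, 2, center, "-"), 2, scale, "/")
  CentroidModel(Z, center = center, scale = scale,
                labels = rownames(raw), featureOrder = feats)
}

#' Shipped example GRS weight config (synthetic stand-in)
#'
#' Nine-SNP type 1 diabetes risk score configuration with illustrative
#' weights: seven additive non-HLA SNPs and the rs2187668 + rs3957146
#' HLA haplotype combination table in which the DR3/DR4-equivalent
#' heterozygote carries the largest weight. The published weight table for
#' the validated score is not redistributed here; these weights are
#' synthetic examples with realistic magnitudes (log odds ratios), and all
#' weights are treated as data. Also shipped as YAML at
#' \code{system.file("extdata", "synthetic_t1d_grs_weights.yaml",
#' package = "diabclust")}.
#'
#' @return A [GRSConfig-class].
#' @export
exampleGRSConfig <- function() {
  snps <- data.frame(
    rsid = c("rs689", "rs2304256", "rs11594656", "rs1265564",
             "rs2292239", "rs3087243", "rs12722495"),
    effect_allele = c("A", "C", "T", "C", "T", "G", "T"),
    other_allele = c("T", "A", "A", "A", "C", "A", "C"),
    weight = c(0.69, 0.33, 0.17, 0.16, 0.30, 0.18, 0.48),
    eaf = c(0.70, 0.72, 0.70, 0.58, 0.34, 0.55, 0.09),
    stringsAsFactors = FALSE
  )
  hw <- rbind(
    c(0.00, 1.27, 2.34),   # DR3 copies = 0; DR4 0/1/2
    c(1.03, 3.87, 2.34),   # DR3 copies = 1 (DR3/DR4 heterozygote peak)
    c(2.04, 1.03, 0.00)    # DR3 copies = 2
  )
  GRSConfig(snps, haplotypeA = "rs2187668", haplotypeB = "rs3957146",
            haplotypeWeights = hw,
            haplotypeEffectAlleles = c("A", "A"))
}
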