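#' @import methods
NULL

#' Canonical clustering features
#'
#' The five clinical features used for subtype assignment and de novo
#' clustering: age at diagnosis (years), BMI (kg/m2), HbA1c (mmol/mol),
#' HOMA2-B (% of normal beta-cell function) and HOMA2-IR (dimensionless).
#'
#' @return Character vector of the five canonical feature names.
#' @export
clusteringFeatures <- function() {
  c("age_at_diagnosis", "bmi", "hba1c", "homa2_b", "homa2_ir")
}

#' Canonical subtype labels
#'
#' SIDD (severe insulin-deficient), SIRD (severe insulin-resistant),
#' MOD (mild obesity-related) and MARD (mild age-related) diabetes,
#' in the conventional cluster order 2--5.
#'
#' @return Character vector of the four subtype labels.
#' @export
subtypeLabels <- function() {
  c("SIDD", "SIRD", "MOD", "MARD")
}

#' CentroidModel: reference subtype coordinates in scaled feature space
#'
#' Holds the reference cluster centroids used for supervised nearest-centroid
#' assignment, together with the scaling parameters (per-feature centre and
#' SD from the reference cohort) and optional per-feature transforms that map
#' raw clinical values into the centroids' coordinate space.
#'
#' @slot labels Character vector of subtype labels, one per centroid.
#' @slot centroids Numeric matrix, one row per subtype, one column per
#'   feature, in scaled space.
#' @slot center Named numeric vector of reference means per feature
#'   (applied after \code{transform}).
#' @slot scale Named numeric vector of reference SDs per feature.
#' @slot transform Named character vector, \code{"none"} or \code{"log"}
#'   per feature, applied before centring.
#' @slot featureOrder Character vector of the five feature names in model
#'   order.
#'
#' @seealso [CentroidModel()], [assignSubtype()], [readCentroidModel()]
#' @export
setClass("CentroidModel",
  slots = c(
    labels       = "character",
    centroids    = "matrix",
    center       = "numeric",
    scale        = "numeric",
    transform    = "character",
    featureOrder = "character"
  )
)

setValidity("CentroidModel", function(object) {
  msg <- character()
  p <- length(object@featureOrder)
  if (p != 5L || anyDuplicated(object@featureOrder))
    msg <- c(msg, "featureOrder must hold 5 distinct feature names")
  if (!all(object@featureOrder %in% clusteringFeatures()))
    msg <- c(msg, sprintf("featureOrder entries must be among: %s",
                          paste(clusteringFeatures(), collapse = ", ")))
  if (length(object@labels) != nrow(object@centroids))
    msg <- c(msg, "one centroid row per label required")
  if (length(object@labels) != 4L)
    msg <- c(msg, "exactly 4 centroids (SIDD, SIRD, MOD, MARD) required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique")
  if (ncol(object@centroids) != p)
    msg <- c(msg, "centroid dimension must equal number of features")
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "center and scale must cover all features")
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    msg <- c(msg, "scaling SDs must be finite and > 0")
  if (!all(object@transform %in% c("none", "log")))
    msg <- c(msg, "transform must be 'none' or 'log' per feature")
  if (length(msg)) msg else TRUE
})

#' Construct a CentroidModel
#'
#' @param centroids Numeric matrix (4 x 5) of centroid coordinates in scaled
#'   space; rows may be named by subtype label.
#' @param center,scale Numeric vectors of per-feature reference means and SDs
#'   used to scale raw features into centroid space.
#' @param labels Subtype labels in assignment/tie-break priority order.
#' @param featureOrder Feature names in column order.
#' @param transform Per-feature transform applied before centring
#'   (\code{"none"} or \code{"log"}).
#'
#' @return A [CentroidModel-class] object.
#' @examples
#' m <- exampleCentroidModel()
#' centroidLabels(m)
#' @export
CentroidModel <- function(centroids, center, scale,
                          labels = subtypeLabels(),
                          featureOrder = clusteringFeatures(),
                          transform = rep("none", length(featureOrder))) {
  centroids <- as.matrix(centroids)
  dimnames(centroids) <- list(labels, featureOrder)
  names(center) <- names(scale) <- featureOrder
  transform <- rep_len(transform, length(featureOrder))
  names(transform) <- featureOrder
  new("CentroidModel",
      labels = labels, centroids = centroids,
      center = as.numeric(center) |> stats::setNames(featureOrder),
      scale = as.numeric(scale) |> stats::setNames(featureOrder),
      transform = transform, featureOrder = featureOrder)
}

#' @describeIn CentroidModel Subtype labels in priority order.
#' @param object,x A \code{CentroidModel}.
#' @export
centroidLabels <- function(object) object@labels

#' @describeIn CentroidModel Centroid coordinate matrix (scaled space).
#' @export
centroidCoords <- function(object) object@centroids

#' @describeIn CentroidModel Feature names in model column order.
#' @export
featureOrder <- function(object) object@featureOrder

#' @describeIn CentroidModel Scaling parameters as a data.frame with
#'   columns feature, center, scale, transform.
#' @export
scalingParams <- function(object) {
  data.frame(feature = object@featureOrder,
             center = unname(object@center),
             scale = unname(object@scale),
             transform = unname(object@transform),
             row.names = NULL)
}

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel with", nrow(object@centroids), "subtypes:",
      paste(object@labels, collapse = ", "), "\n")
  cat("features:", paste(object@featureOrder, collapse = ", "), "\n")
  cat("centroids (scaled space):\n")
  print(round(object@centroids, 3))
  invisible(NULL)
})

#' GRSConfig: weights for a type 1 diabetes genetic risk score
#'
#' Configuration for a weighted 9-SNP type 1 diabetes genetic risk score in
#' which seven SNPs contribute additively (weight x effect-allele dosage) and
#' two HLA-tagging SNPs (rs2187668 tagging DR3 and rs3957146, a perfect-LD
#' proxy for rs7454108, tagging DR4) contribute through a genotype-combination
#' weight looked up from a 3 x 3 table, capturing the non-additive DR3/DR4
#' heterozygote risk.
#'
#' @slot snps data.frame with columns rsid, effect_allele, other_allele,
#'   weight, eaf (effect-allele frequency, used to impute missing dosages).
#' @slot haplotypeA,haplotypeB rsids of the two haplotype-defining SNPs.
#' @slot haplotypeEffectAlleles Effect alleles of haplotypeA and haplotypeB
#'   (the alleles whose copy numbers index the weight table).
#' @slot haplotypeWeights 3 x 3 numeric matrix indexed by hard-called
#'   genotype (0, 1, 2 copies) of haplotypeA (rows) and haplotypeB (columns).
#' @slot referenceCutoffs Named numeric vector of score cut-offs, names are
#'   reference-distribution percentiles (e.g. \code{"80"}, \code{"90"}).
#'
#' @seealso [GRSConfig()], [computeGRS()], [exampleGRSConfig()]
#' @export
setClass("GRSConfig",
  slots = c(
    snps                   = "data.frame",
    haplotypeA             = "character",
    haplotypeB             = "character",
    haplotypeEffectAlleles = "character",
    haplotypeWeights       = "matrix",
    referenceCutoffs       = "numeric"
  )
)

setValidity("GRSConfig", function(object) {
  msg <- character()
  need <- c("rsid", "effect_allele", "other_allele", "weight", "eaf")
  if (!all(need %in% names(object@snps)))
    msg <- c(msg, sprintf("snps must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(object@snps) + 2L != 9L)
      msg <- c(msg, "9 SNPs in total required (7 additive + 2 haplotype)")
    if (any(!is.finite(object@snps$weight)))
      msg <- c(msg, "weights must be finite")
    if (any(object@snps$eaf <= 0 | object@snps$eaf >= 1))
      msg <- c(msg, "effect-allele frequencies must lie in (0, 1)")
    if (any(c(object@haplotypeA, object@haplotypeB) %in% object@snps$rsid))
      msg <- c(msg, "haplotype SNPs must not also be additive SNPs")
  }
  if (length(object@haplotypeEffectAlleles) != 2L)
    msg <- c(msg, "haplotypeEffectAlleles must have length 2")
  if (!identical(dim(object@haplotypeWeights), c(3L, 3L)))
    msg <- c(msg, "haplotypeWeights must be a 3 x 3 matrix (genotypes 0/1/2)")
  if (any(!is.finite(object@haplotypeWeights)))
    msg <- c(msg, "haplotype weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a GRSConfig
#'
#' @param snps data.frame of additive SNPs (columns rsid, effect_allele,
#'   other_allele, weight, eaf).
#' @param haplotypeA,haplotypeB rsids of the haplotype-defining SNPs
#'   (defaults rs2187668 and rs3957146).
#' @param haplotypeWeights 3 x 3 matrix of combination weights indexed by
#'   hard-called genotypes of (haplotypeA, haplotypeB).
#' @param haplotypeEffectAlleles Effect alleles of the two haplotype SNPs.
#' @param referenceCutoffs Named numeric vector of percentile score cut-offs.
#'
#' @return A [GRSConfig-class] object.
#' @export
GRSConfig <- function(snps, haplotypeA = "rs2187668",
                      haplotypeB = "rs3957146",
                      haplotypeWeights,
                      haplotypeEffectAlleles = c("A", "A"),
                      referenceCutoffs = numeric()) {
  haplotypeWeights <- as.matrix(haplotypeWeights)
  dimnames(haplotypeWeights) <- list(0:2, 0:2)
  new("GRSConfig", snps = as.data.frame(snps),
      haplotypeA = haplotypeA, haplotypeB = haplotypeB,
      haplotypeEffectAlleles = haplotypeEffectAlleles,
      haplotypeWeights = haplotypeWeights,
      referenceCutoffs = referenceCutoffs)
}

#' @describeIn GRSConfig rsids used by the score (additive then haplotype).
#' @param object A \code{GRSConfig}.
#' @export
grsSNPs <- function(object) {
  c(object@snps$rsid, object@haplotypeA, object@haplotypeB)
}

setMethod("show", "GRSConfig", function(object) {
  cat("GRSConfig:", nrow(object@snps), "additive SNPs + haplotype (",
      object@haplotypeA, "+", object@haplotypeB, ")\n")
  print(object@snps[, c("rsid", "effect_allele", "weight")])
  if (length(object@referenceCutoffs)) {
    cat("reference percentile cut-offs:\n")
    print(object@referenceCutoffs)
  }
  invisible(NULL)
})

#' ClusterSpec: generative parameters for one diabetes subtype
#'
#' Per-sex means and SDs of the clinical features, distribution family per
#' feature, complication prevalences and treatment-category probabilities
#' for one mixture component of a synthetic cohort.
#'
#' @slot label Subtype label.
#' @slot proportion Named numeric, mixing proportion within each sex
#'   (\code{male}, \code{female}).
#' @slot center,spread Lists with elements \code{male} and \code{female},
#'   each a named numeric vector of per-feature means / SDs.
#' @slot family Named character vector, \code{"normal"} or \code{"lognormal"}
#'   per feature (lognormal parameters are moment-matched to mean/SD).
#' @slot outcomePrev Named numeric vector of complication prevalences.
#' @slot treatmentProb Named numeric vector of probabilities over the four
#'   mutually exclusive treatment categories.
#'
#' @seealso [ClusterSpec()], [wellgenCohortSpec()]
#' @export
setClass("ClusterSpec",
  slots = c(
    label         = "character",
    proportion    = "numeric",
    center        = "list",
    spread        = "list",
    family        = "character",
    outcomePrev   = "numeric",
    treatmentProb = "numeric"
  )
)

setValidity("ClusterSpec", function(object) {
  msg <- character()
  if (!all(c("male", "female") %in% names(object@proportion)))
    msg <- c(msg, "proportion must be named for male and female")
  for (s in c("male", "female")) {
    if (is.null(object@center[[s]]) || is.null(object@spread[[s]]))
      msg <- c(msg, sprintf("center/spread must have a '%s' element", s))
    else if (any(object@spread[[s]] <= 0))
      msg <- c(msg, "all SDs must be > 0")
  }
  if (!all(object@family %in% c("normal", "lognormal")))
    msg <- c(msg, "family must be 'normal' or 'lognormal'")
  if (length(object@outcomePrev) &&
      (any(object@outcomePrev < 0) || any(object@outcomePrev > 1)))
    msg <- c(msg, "outcome prevalences must lie in [0, 1]")
  if (length(object@treatmentProb) &&
      abs(sum(object@treatmentProb) - 1) > 1e-8)
    msg <- c(msg, "treatment probabilities must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterSpec
#'
#' @param label Subtype label.
#' @param proportion Named numeric mixing proportion per sex.
#' @param center,spread Lists (male/female) of named per-feature means / SDs.
#' @param family Named character vector of per-feature families.
#' @param outcomePrev Named numeric complication prevalences.
#' @param treatmentProb Named numeric treatment-category probabilities.
#'
#' @return A [ClusterSpec-class] object.
#' @export
ClusterSpec <- function(label, proportion, center, spread,
                        family = character(),
                        outcomePrev = numeric(),
                        treatmentProb = numeric()) {
  new("ClusterSpec", label = label, proportion = proportion,
      center = center, spread = spread, family = family,
      outcomePrev = outcomePrev, treatmentProb = treatmentProb)
}

setMethod("show", "ClusterSpec", function(object) {
  cat("ClusterSpec", object@label,
      sprintf("(male %.1f%%, female %.1f%% within sex)\n",
              100 * object@proportion[["male"]],
              100 * object@proportion[["female"]]))
  invisible(NULL)
})

#' CohortSpec: generative parameters for a synthetic diabetes cohort
#'
#' @slot n Number of participants.
#' @slot maleFraction Probability that a participant is male.
#' @slot clusters List of [ClusterSpec-class] objects (4 by default).
#' @slot durationMeanSD Mean and SD (years) of the lognormal diabetes
#'   duration distribution (moment-matched).
#' @slot mode \code{"feature_space"} samples HOMA2 indices directly from the
#'   cluster specs; \code{"raw_measurement"} samples fasting glucose and
#'   C-peptide and derives HOMA2 indices through [homa2()] (cluster HOMA2
#'   targets then hold only approximately).
#' @slot missingness Named numeric vector of per-outcome missingness rates.
#'
#' @seealso [CohortSpec()], [wellgenCohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  slots = c(
    n              = "numeric",
    maleFraction   = "numeric",
    clusters       = "list",
    durationMeanSD = "numeric",
    mode           = "character",
    missingness    = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@n) != 1L || object@n < 1)
    msg <- c(msg, "n must be a positive count")
  if (object@maleFraction < 0 || object@maleFraction > 1)
    msg <- c(msg, "maleFraction must lie in [0, 1]")
  if (!length(object@clusters))
    msg <- c(msg, "at least one cluster spec required")
  if (!all(vapply(object@clusters, is, logical(1), "ClusterSpec")))
    msg <- c(msg, "clusters must be ClusterSpec objects")
  else {
    for (s in c("male", "female")) {
      tot <- sum(vapply(object@clusters,
                        function(cl) cl@proportion[[s]], numeric(1)))
      if (abs(tot - 1) > 1e-6)
        msg <- c(msg, sprintf("%s mixing proportions must sum to 1", s))
    }
  }
  if (!object@mode %in% c("feature_space", "raw_measurement"))
    msg <- c(msg, "mode must be 'feature_space' or 'raw_measurement'")
  if (length(object@missingness) &&
      (any(object@missingness < 0) || any(object@missingness > 1)))
    msg <- c(msg, "missingness rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param n Number of participants.
#' @param maleFraction Probability of male sex.
#' @param clusters List of [ClusterSpec-class] objects.
#' @param durationMeanSD Mean and SD (years) for lognormal diabetes duration.
#' @param mode Generation mode, see [CohortSpec-class].
#' @param missingness Named per-outcome missingness rates.
#'
#' @return A [CohortSpec-class] object.
#' @export
CohortSpec <- function(n, maleFraction, clusters,
                       durationMeanSD = c(9.72, 8.21),
                       mode = "feature_space",
                       missingness = numeric()) {
  new("CohortSpec", n = n, maleFraction = maleFraction,
      clusters = clusters, durationMeanSD = durationMeanSD,
      mode = mode, missingness = missingness)
}

#' @describeIn CohortSpec Subtype labels of the component clusters.
#' @param object A \code{CohortSpec}.
#' @export
cohortClusterLabels <- function(object) {
  vapply(object@clusters, function(cl) cl@label, character(1))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: n =", object@n,
      sprintf("(%.1f%% male), %d clusters [%s], mode = %s\n",
              100 * object@maleFraction, length(object@clusters),
              paste(cohortClusterLabels(object), collapse = ", "),
              object@mode))
  invisible(NULL)
})
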