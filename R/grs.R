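## Type 1 diabetes genetic risk score: 7 additive SNPs plus a two-SNP HLA
## haplotype term (rs2187668 tagging DR3, rs3957146 as a perfect-LD proxy
## for rs7454108 tagging DR4). Weights, allele orientations and reference
## percentile cut-offs are configuration, never code.

#' Read a genotype dosage matrix from VCF or tabular text
#'
#' For VCF input, dosages are taken from the \code{DS} FORMAT field when
#' present, otherwise counted from \code{GT} (effect alleles = ALT copies).
#' Tabular input is a delimited file with columns \code{rsid},
#' \code{counted_allele}, \code{other_allele} then one column per sample.
#'
#' Dosages are oriented to each variant's configured effect allele: when the
#' file counts the other allele the dosage is flipped to \code{2 - d}; when
#' neither file allele matches the config the variant is marked unusable.
#'
#' @param path VCF (\code{.vcf}) or tabular dosage file.
#' @param config A [GRSConfig-class]; defines requested rsids, effect
#'   alleles and orientation.
#'
#' @return List with \code{dosages} (samples x variants matrix, NA where
#'   missing), \code{found} (rsids located), \code{unusable} (rsids with
#'   unresolvable alleles). Variants absent from the file are reported with
#'   a warning and appear as all-NA columns.
#' @export
readDosages <- function(path, config) {
  rsids <- grsSNPs(config)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  isVcf <- grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)
  if (isVcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ids <- vcfR::getID(v)
    ref <- vcfR::getREF(v)
    alt <- vcfR::getALT(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
    if ("DS" %in% fmt) {
      ds <- suppressWarnings(
        apply(vcfR::extract.gt(v, element = "DS"), 2, as.numeric))
      if (is.null(dim(ds))) ds <- matrix(ds, nrow = length(ids))
    } else {
      cnt <- function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
      }
      ds <- apply(gt, c(1, 2), cnt)
    }
    rownames(ds) <- ids
    samples <- colnames(v@gt)[-1]
    fileCounted <- alt  # DS / ALT copies count the ALT allele
    fileOther <- ref
    names(fileCounted) <- names(fileOther) <- ids
    D <- t(ds)  # samples x variants
    rownames(D) <- samples
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    need <- c("rsid", "counted_allele", "other_allele")
    if (!all(need %in% names(tab)))
      stop("tabular dosage file must have columns: ",
           paste(need, collapse = ", "))
    ids <- tab$rsid
    fileCounted <- stats::setNames(tab$counted_allele, ids)
    fileOther <- stats::setNames(tab$other_allele, ids)
    D <- t(as.matrix(tab[, setdiff(names(tab), need), drop = FALSE]))
    colnames(D) <- ids
    if (any(stats::na.omit(c(D)) < 0) || any(stats::na.omit(c(D)) > 2))
      stop("dosages must lie in [0, 2]")
  }

  out <- matrix(NA_real_, nrow = nrow(D), ncol = length(rsids),
                dimnames = list(rownames(D), rsids))
  unusable <- character()
  for (rs in rsids) {
    if (!rs %in% colnames(D)) {
      warning("rsid absent from genotype file: ", rs)
      next
    }
    eff <- .effectAllele(config, rs)
    d <- D[, rs]
    if (identical(fileCounted[[rs]], eff)) {
      out[, rs] <- d
    } else if (identical(fileOther[[rs]], eff)) {
      out[, rs] <- 2 - d
    } else {
      warning("allele mismatch for ", rs, ": variant marked unusable")
      unusable <- c(unusable, rs)
    }
  }
  list(dosages = out,
       found = intersect(rsids, colnames(D)),
       unusable = unusable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# effect allele of any score SNP (additive table or haplotype slot)
.effectAllele <- function(config, rsid) {
  i <- match(rsid, config@snps$rsid)
  if (!is.na(i)) return(config@snps$effect_allele[i])
  if (rsid == config@haplotypeA) return(config@haplotypeEffectAlleles[1])
  if (rsid == config@haplotypeB) return(config@haplotypeEffectAlleles[2])
  stop("unknown rsid: ", rsid)
}

#' Compute the weighted type 1 diabetes GRS
#'
#' \code{score = sum_j weight_j x dosage_j + haplotype weight}, where the
#' haplotype weight is looked up from the 3 x 3 combination table using
#' hard-called genotypes (dosages rounded to the nearest integer) of the two
#' HLA-tagging SNPs. Missing additive dosages are imputed at twice the
#' configured effect-allele frequency and flagged; both haplotype SNPs
#' missing is an error unless \code{haplotypeFallback} supplies a weight.
#'
#' @param dosages Samples x variants matrix from [readDosages()] (oriented
#'   to effect alleles), or any matrix with matching column names.
#' @param config A [GRSConfig-class].
#' @param haplotypeFallback Optional numeric weight used when the haplotype
#'   genotypes are unavailable for a sample.
#'
#' @return data.frame with \code{sample}, \code{score},
#'   \code{n_imputed} (count of additive SNPs imputed from frequency) and
#'   \code{haplotype_fallback} flag.
#' @examples
#' cfg <- exampleGRSConfig()
#' g <- generateGenotypes(5, grsConfigFrequencies(cfg), seed = 1)
#' computeGRS(g$dosages, cfg)
#' @export
computeGRS <- function(dosages, config, haplotypeFallback = NULL) {
  D <- as.matrix(dosages)
  addit <- config@snps
  missingCols <- setdiff(c(addit$rsid, config@haplotypeA,
                           config@haplotypeB), colnames(D))
  for (mc in missingCols)
    D <- cbind(D, matrix(NA_real_, nrow(D), 1,
                         dimnames = list(NULL, mc)))
  nImp <- integer(nrow(D))
  add <- numeric(nrow(D))
  for (i in seq_len(nrow(addit))) {
    d <- D[, addit$rsid[i]]
    miss <- is.na(d)
    d[miss] <- 2 * addit$eaf[i]
    nImp <- nImp + miss
    add <- add + addit$weight[i] * d
  }
  gA <- round(D[, config@haplotypeA])
  gB <- round(D[, config@haplotypeB])
  hapMiss <- is.na(gA) | is.na(gB)
  if (any(hapMiss) && is.null(haplotypeFallback))
    stop("haplotype SNP genotypes missing for ", sum(hapMiss),
         " sample(s) and no fallback weight configured")
  hw <- numeric(nrow(D))
  okIdx <- which(!hapMiss)
  if (length(okIdx)) {
    gA2 <- pmin(pmax(gA[okIdx], 0), 2)
    gB2 <- pmin(pmax(gB[okIdx], 0), 2)
    hw[okIdx] <- config@haplotypeWeights[cbind(gA2 + 1, gB2 + 1)]
  }
  if (any(hapMiss)) hw[hapMiss] <- haplotypeFallback
  data.frame(
    sample = rownames(D) %||% as.character(seq_len(nrow(D))),
    score = add + hw,
    n_imputed = nImp,
    haplotype_fallback = hapMiss,
    row.names = NULL
  )
}

#' Proportion of scores at or above reference percentile cut-offs
#'
#' @param scores Numeric GRS values (nonempty).
#' @param cutoffs Named numeric vector of score cut-offs; names are
#'   reference percentiles (e.g. from a type 1 diabetes reference
#'   distribution).
#'
#' @return data.frame with \code{percentile}, \code{cutoff}, \code{n_above}
#'   (scores >= cutoff), \code{n} and \code{pct}.
#' @export
percentileProportions <- function(scores, cutoffs) {
  if (!length(scores)) stop("empty score vector")
  if (!length(cutoffs)) stop("no cut-offs supplied")
  data.frame(
    percentile = names(cutoffs) %||% as.character(seq_along(cutoffs)),
    cutoff = unname(cutoffs),
    n_above = vapply(cutoffs, function(ct) sum(scores >= ct), 0L),
    n = length(scores),
    pct = vapply(cutoffs,
                 function(ct) 100 * mean(scores >= ct), 0),
    row.names = NULL
  )
}

#' Percentile cut-offs from a reference score distribution
#'
#' @param referenceScores Scores of the reference group (e.g. confirmed
#'   type 1 diabetes cases).
#' @param percentiles Percentiles to extract (default 80 and 90).
#' @return Named numeric vector usable as \code{cutoffs} in
#'   [percentileProportions()].
#' @export
referenceCutoffs <- function(referenceScores, percentiles = c(80, 90)) {
  q <- stats::quantile(referenceScores, probs = percentiles / 100,
                       names = FALSE, type = 7)
  stats::setNames(q, as.character(percentiles))
}

#' Discrimination of two groups by GRS (logistic regression)
#'
#' Maximum-likelihood logistic fit of group membership on the score,
#' reporting the slope (log-odds per score unit), its standard error and
#' the Wald p value. Perfect or quasi-perfect separation is detected (from
#' glm convergence diagnostics and fitted probabilities at the boundary)
#' and flagged rather than raising an error.
#'
#' @param scores Numeric GRS values.
#' @param groups Two-level factor/character/logical group labels; the
#'   second level is modelled as the event.
#'
#' @return data.frame (one row): \code{slope}, \code{se}, \code{z},
#'   \code{p}, \code{separation} flag.
#' @export
grsDiscrimination <- function(scores, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) == 0L)) stop("both groups must be nonempty")
  y <- as.integer(g) - 1L
  fit <- suppressWarnings(stats::glm(
    y ~ scores, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  co <- summary(fit)$coefficients
  mu <- fit$fitted.values
  sep <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  data.frame(slope = co["scores", "Estimate"],
             se = co["scores", "Std. Error"],
             z = co["scores", "z value"],
             p = co["scores", "Pr(>|z|)"],
             separation = sep)
}
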