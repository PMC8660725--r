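#' Build the clustering feature matrix from a cohort table
#'
#' Assembles the n x 5 matrix of clustering features (age at diagnosis, BMI,
#' HbA1c, HOMA2-B, HOMA2-IR) in the requested order, computing the HOMA2
#' indices from capped fasting glucose and C-peptide when they are not
#' already present as columns.
#'
#' @param records Cohort data.frame from [readCohort()] or
#'   [generateCohort()].
#' @param featureOrder Feature names, see [clusteringFeatures()].
#'
#' @return Numeric matrix with rownames taken from \code{participant_id};
#'   attribute \code{"sex"} carries the sex vector.
#' @export
buildFeatureMatrix <- function(records, featureOrder = clusteringFeatures()) {
  stopifnot(all(featureOrder %in% clusteringFeatures()))
  rec <- records
  if (!all(c("homa2_b", "homa2_ir") %in% names(rec))) {
    idx <- homa2(rec$fasting_glucose, rec$fasting_cpeptide)
    rec$homa2_b <- idx$homa2_b
    rec$homa2_ir <- idx$homa2_ir
  }
  X <- as.matrix(rec[, featureOrder, drop = FALSE])
  rownames(X) <- rec$participant_id
  attr(X, "sex") <- rec$sex
  X
}

#' Exclude extreme outliers on the clustering features
#'
#' Computes, in a single pass, the per-feature mean and SD on the input set
#' and excludes every row lying more than \code{nSD} standard deviations
#' from the mean on any feature. Means/SDs are not recomputed after
#' exclusion. Features with zero SD (all values identical) exclude nothing.
#'
#' @param X Numeric feature matrix (rows = participants), at least 2 rows.
#' @param nSD Exclusion threshold in SD units (default 5).
#'
#' @return List with \code{kept} and \code{excluded} (row subsets of
#'   \code{X}, partitioning the input) and logical vector \code{mask}
#'   (TRUE = kept).
#' @export
excludeOutliers <- function(X, nSD = 5) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("at least 2 rows required")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  dev <- abs(sweep(X, 2, mu, "-"))
  lim <- nSD * sd
  # zero-SD features cannot flag anything
  over <- sweep(dev, 2, lim, ">") & rep(sd > 0, each = nrow(X))
  mask <- !apply(over, 1, any)
  if (!any(mask)) stop("all rows excluded: degenerate cohort")
  sexes <- attr(X, "sex")
  kept <- X[mask, , drop = FALSE]
  excl <- X[!mask, , drop = FALSE]
  if (!is.null(sexes)) {
    attr(kept, "sex") <- sexes[mask]
    attr(excl, "sex") <- sexes[!mask]
  }
  list(kept = kept, excluded = excl, mask = mask)
}

#' Scale features with reference parameters
#'
#' Applies, per feature, the optional transform then centring/scaling:
#' \eqn{z = (t(x) - \mu) / \sigma}. The parameters normally come from a
#' [CentroidModel-class] (the reference cohort's values), so a new cohort is
#' projected into the reference coordinate space rather than self-scaled.
#'
#' @param X Numeric feature matrix (columns in \code{feature} order of
#'   \code{params}).
#' @param params A [CentroidModel-class] or a data.frame as returned by
#'   [scalingParams()] (columns feature, center, scale, transform).
#'
#' @return Scaled matrix of the same shape (attributes preserved).
#' @seealso [unscaleFeatures()] for the exact inverse.
#' @export
scaleFeatures <- function(X, params) {
  if (is(params, "CentroidModel")) params <- scalingParams(params)
  X <- as.matrix(X)
  stopifnot(all(params$feature %in% colnames(X)) || ncol(X) ==
              nrow(params))
  if (!is.null(colnames(X)))
    params <- params[match(colnames(X), params$feature), ]
  if (any(params$scale <= 0)) stop("scaling SDs must be > 0")
  Z <- X
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (identical(params$transform[j], "log")) {
      if (any(v <= 0)) stop("log transform requires positive values in ",
                            params$feature[j])
      v <- log(v)
    }
    Z[, j] <- (v - params$center[j]) / params$scale[j]
  }
  Z
}

#' Invert [scaleFeatures()]
#'
#' @param Z Scaled matrix.
#' @param params As in [scaleFeatures()].
#' @return Matrix on the raw scale; \code{unscaleFeatures(scaleFeatures(X))}
#'   round-trips to floating-point accuracy.
#' @export
unscaleFeatures <- function(Z, params) {
  if (is(params, "CentroidModel")) params <- scalingParams(params)
  Z <- as.matrix(Z)
  if (!is.null(colnames(Z)))
    params <- params[match(colnames(Z), params$feature), ]
  X <- Z
  for (j in seq_len(ncol(Z))) {
    v <- Z[, j] * params$scale[j] + params$center[j]
    if (identical(params$transform[j], "log")) v <- exp(v)
    X[, j] <- v
  }
  X
}

#' Self-scaling parameters of a cohort
#'
#' Per-feature mean and SD computed from the data itself (used by the
#' de novo clustering path, where scaling is not inherited from a reference
#' cohort).
#'
#' @param X Feature matrix.
#' @param transform Per-feature transform tags (default none).
#' @return data.frame usable as \code{params} in [scaleFeatures()].
#' @export
selfScalingParams <- function(X, transform = rep("none", ncol(X))) {
  X <- as.matrix(X)
  tX <- X
  for (j in seq_len(ncol(X)))
    if (identical(transform[j], "log")) tX[, j] <- log(X[, j])
  data.frame(feature = colnames(X),
             center = colMeans(tX),
             scale = apply(tX, 2, stats::sd),
             transform = transform,
             row.names = NULL)
}
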