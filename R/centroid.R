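#' Assign participants to subtypes by nearest centroid
#'
#' Computes, for each row of a scaled feature matrix, the Euclidean distance
#' to each of the four reference centroids and assigns the label of the
#' nearest one. Exact ties are broken by the model's declared label order
#' (SIDD first by default), making assignment deterministic.
#'
#' @param Z Scaled feature matrix (columns in the model's feature order),
#'   or a single vector of length 5.
#' @param model A [CentroidModel-class].
#'
#' @return data.frame with columns \code{participant_id} (rownames of
#'   \code{Z} if present), \code{label}, one distance column per subtype
#'   (\code{dist_SIDD}, ...), and \code{margin} (second-best minus best
#'   distance, non-negative).
#' @examples
#' m <- exampleCentroidModel()
#' assignSubtype(centroidCoords(m)["SIRD", ], m)$label  # "SIRD"
#' @export
assignSubtype <- function(Z, model) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  Z <- as.matrix(Z)
  if (ncol(Z) != ncol(centroidCoords(model)))
    stop("dimension mismatch: vectors have ", ncol(Z),
         " features, model expects ", ncol(centroidCoords(model)))
  cent <- centroidCoords(model)
  # direct per-centroid distances (k = 4): exact at the centroids, no
  # cancellation from the quadratic expansion
  D <- vapply(seq_len(nrow(cent)), function(j)
    sqrt(rowSums(sweep(Z, 2, cent[j, ], "-")^2)), numeric(nrow(Z)))
  if (nrow(Z) == 1L) D <- matrix(D, nrow = 1)
  colnames(D) <- centroidLabels(model)
  best <- apply(D, 1, which.min)  # which.min takes the first = label order
  sorted <- t(apply(D, 1, sort))
  margin <- sorted[, 2] - sorted[, 1]
  out <- data.frame(
    participant_id = if (!is.null(rownames(Z))) rownames(Z) else
      as.character(seq_len(nrow(Z))),
    label = centroidLabels(model)[best],
    stringsAsFactors = FALSE
  )
  for (l in centroidLabels(model)) out[[paste0("dist_", l)]] <- D[, l]
  out$margin <- margin
  rownames(out) <- NULL
  out
}

#' Subgroup count/percentage table
#'
#' @param labels Character vector of subtype labels.
#' @param sex Optional sex vector of the same length; adds per-sex columns.
#' @param allLabels Label universe (rows of the table).
#'
#' @return data.frame with one row per label: \code{n}, \code{pct} and,
#'   when \code{sex} is given, \code{n_male}, \code{pct_male},
#'   \code{n_female}, \code{pct_female}. Percentages are within-column and
#'   sum to 100 up to rounding.
#' @export
subgroupTable <- function(labels, sex = NULL, allLabels = subtypeLabels()) {
  f <- factor(labels, levels = allLabels)
  tab <- data.frame(label = allLabels,
                    n = as.integer(table(f)),
                    stringsAsFactors = FALSE)
  tab$pct <- if (sum(tab$n) > 0) 100 * tab$n / sum(tab$n) else NA_real_
  if (!is.null(sex)) {
    for (s in c("male", "female")) {
      ns <- as.integer(table(f[sex == s]))
      tab[[paste0("n_", s)]] <- ns
      tab[[paste0("pct_", s)]] <- if (sum(ns) > 0) 100 * ns / sum(ns)
        else NA_real_
    }
  }
  tab
}

#' Classify a cohort against reference centroids
#'
#' Full supervised pipeline step: builds the feature matrix, applies the
#' model's reference scaling, assigns each participant to the nearest
#' centroid and tabulates the subgroup distribution overall and per sex.
#' Outlier exclusion (see [excludeOutliers()]) is applied first when
#' \code{excludeSD} is finite.
#'
#' @param records Cohort data.frame.
#' @param model A [CentroidModel-class].
#' @param excludeSD Outlier threshold in SDs (default 5); \code{Inf}
#'   disables exclusion.
#'
#' @return List with \code{assignments} (see [assignSubtype()], plus a
#'   \code{sex} column), \code{table} (see [subgroupTable()]) and
#'   \code{excluded} (participant ids dropped as outliers).
#' @export
classifyCohort <- function(records, model, excludeSD = 5) {
  if (nrow(records) == 0L) stop("empty cohort")
  X <- buildFeatureMatrix(records, featureOrder(model))
  excludedIds <- character()
  if (is.finite(excludeSD) && nrow(X) >= 2L) {
    ex <- excludeOutliers(X, nSD = excludeSD)
    excludedIds <- rownames(ex$excluded)
    X <- ex$kept
  }
  Z <- scaleFeatures(X, model)
  asg <- assignSubtype(Z, model)
  asg$sex <- attr(X, "sex")
  list(assignments = asg,
       table = subgroupTable(asg$label, asg$sex, centroidLabels(model)),
       excluded = excludedIds)
}

#' Subgroup distribution by diabetes duration stratum
#'
#' Sensitivity analysis splitting the cohort at a duration threshold
#' (default 5 years since diagnosis) and tabulating the subgroup
#' distribution within each stratum.
#'
#' @param assignments Assignment data.frame from [classifyCohort()].
#' @param duration Numeric vector of diabetes duration (years), aligned with
#'   \code{assignments}.
#' @param split Threshold in years; strata are \code{duration < split} and
#'   \code{duration >= split}.
#' @param allLabels Label universe.
#'
#' @return List with elements \code{below} and \code{above}, each a
#'   [subgroupTable()] data.frame. An empty stratum yields a zero-count
#'   table with a warning.
#' @export
durationSensitivity <- function(assignments, duration, split = 5,
                                allLabels = subtypeLabels()) {
  stopifnot(length(duration) == nrow(assignments))
  if (any(is.na(duration))) stop("duration must be present for all")
  lo <- duration < split
  mk <- function(idx, nm) {
    if (!any(idx)) {
      warning("empty stratum: ", nm)
      return(subgroupTable(character(), allLabels = allLabels))
    }
    subgroupTable(assignments$label[idx],
                  sex = assignments$sex[idx], allLabels = allLabels)
  }
  list(below = mk(lo, paste0("duration < ", split)),
       above = mk(!lo, paste0("duration >= ", split)))
}
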