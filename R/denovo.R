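## De novo clustering: seeded Lloyd k-means with restarts, mean silhouette
## width for model selection, sex-stratified runs with cross-sex cluster
## alignment, and concordance against the supervised subtype assignment.

# squared Euclidean distances rows of X vs rows of C
.sqDistTo <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  d2[d2 < 0] <- 0
  d2
}

# one Lloyd run from given initial centers; objective must never increase
.lloyd <- function(X, centers, tol = 1e-6, maxIter = 300L) {
  k <- nrow(centers)
  n <- nrow(X)
  obj <- Inf
  for (iter in seq_len(maxIter)) {
    d2 <- .sqDistTo(X, centers)
    lab <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters at the point farthest from its center
    reseeded <- FALSE
    repeat {
      empty <- setdiff(seq_len(k), unique(lab))
      if (!length(empty)) break
      far <- which.max(d2[cbind(seq_len(n), lab)])
      lab[far] <- empty[1]
      d2[far, ] <- -Inf  # cannot be picked as farthest again
      reseeded <- TRUE
    }
    newCenters <- centers
    for (j in seq_len(k))
      newCenters[j, ] <- colMeans(X[lab == j, , drop = FALSE])
    d2new <- .sqDistTo(X, newCenters)
    newObj <- sum(d2new[cbind(seq_len(n), lab)])
    # Lloyd guarantees monotone descent except across a forced re-seed
    if (!reseeded && newObj > obj + 1e-8 * max(1, obj))
      stop("internal error: k-means objective increased")
    shift <- sqrt(max(rowSums((newCenters - centers)^2)))
    centers <- newCenters
    obj <- newObj
    if (shift < tol) break
  }
  # final consistent labelling for the returned centers
  d2 <- .sqDistTo(X, centers)
  lab <- max.col(-d2, ties.method = "first")
  for (j in seq_len(k))
    if (any(lab == j))
      centers[j, ] <- colMeans(X[lab == j, , drop = FALSE])
  obj <- sum(.sqDistTo(X, centers)[cbind(seq_len(n), lab)])
  list(labels = lab, centers = centers, tot_withinss = obj,
       iterations = iter)
}

#' k-means with seeded random restarts
#'
#' Lloyd's algorithm run \code{nRestarts} times from random initial centers
#' (distinct data points), keeping the partition with the smallest total
#' within-cluster sum of squares. Iterations stop when the largest center
#' shift falls below \code{tol} or after \code{maxIter} iterations; a
#' cluster that empties is re-seeded at the point farthest from its current
#' center. Restart \code{r} draws its initialisation from a seed stream
#' derived from \code{(seed, k, r)}, so results are reproducible and
#' independent of row order of evaluation.
#'
#' @param X Numeric data matrix (rows = observations), typically scaled.
#' @param k Number of clusters (2 or more; \code{n >= k} required).
#' @param nRestarts Number of random restarts (default 100).
#' @param seed Master seed.
#' @param tol Convergence tolerance on center shift.
#' @param maxIter Maximum Lloyd iterations per restart.
#'
#' @return List (class \code{"diabclustPartition"}) with \code{labels}
#'   (1..k per row), \code{centers}, \code{tot_withinss}, \code{k},
#'   \code{restart} (index of the winning restart).
#' @export
kmeansRestarts <- function(X, k, nRestarts = 100L, seed = 1L,
                           tol = 1e-6, maxIter = 300L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("n < k: fewer observations than clusters")
  if (nRestarts < 1L) stop("nRestarts must be >= 1")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    # independent, reproducible stream per (seed, k, restart)
    streamSeed <- (as.integer(seed) + 7919L * as.integer(k) +
                     104729L * r) %% .Machine$integer.max
    init <- withr::with_seed(streamSeed, sample.int(n, k))
    fit <- .lloyd(X, X[init, , drop = FALSE], tol = tol, maxIter = maxIter)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) {
      best <- fit
      best$restart <- r
    }
  }
  best$k <- k
  class(best) <- "diabclustPartition"
  best
}

#' @export
print.diabclustPartition <- function(x, ...) {
  cat("k-means partition: k =", x$k, ", n =", length(x$labels),
      ", total within-SS =", format(x$tot_withinss, digits = 6), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Mean silhouette width of a partition
#'
#' Standard silhouette with Euclidean distances: for each point,
#' \eqn{s = (b - a) / \max(a, b)} where \eqn{a} is the mean distance to the
#' other members of its own cluster and \eqn{b} the smallest mean distance
#' to another cluster. Members of singleton clusters contribute
#' \eqn{s = 0}. Requires at least two nonempty clusters.
#'
#' @param labels Integer cluster labels (1..k).
#' @param X Data matrix the clustering was computed on.
#'
#' @return Mean silhouette width, a number in [-1, 1].
#' @export
meanSilhouette <- function(labels, X) {
  .meanSilhouetteD(labels, .fullDist(as.matrix(X)))
}

# full Euclidean distance matrix via BLAS (as.matrix(dist(.)) is too slow
# at cohort sizes)
.fullDist <- function(X) {
  dg <- rowSums(X^2)
  D2 <- -2 * tcrossprod(X)
  D2 <- D2 + dg              # adds dg[row] (column-wise recycling)
  D2 <- sweep(D2, 2, dg, "+")
  D2[D2 < 0] <- 0
  sqrt(D2)
}

# silhouette from a precomputed distance matrix (shared across k in selectK)
.meanSilhouetteD <- function(labels, D) {
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette requires at least 2 clusters")
  n <- nrow(D)
  lab <- match(labels, ks)
  Ind <- matrix(0, n, length(ks))
  Ind[cbind(seq_len(n), lab)] <- 1
  sizes <- colSums(Ind)
  M <- (D %*% Ind) / rep(sizes, each = n)  # mean dist to each cluster
  ownIdx <- cbind(seq_len(n), lab)
  nOwn <- sizes[lab]
  a <- M[ownIdx] * nOwn / pmax(nOwn - 1, 1)  # exclude self from own mean
  Mo <- M
  Mo[ownIdx] <- Inf
  b <- do.call(pmin, lapply(seq_along(ks), function(j) Mo[, j]))
  s <- (b - a) / pmax(a, b)
  s[nOwn == 1] <- 0
  mean(s)
}

#' Choose the number of clusters by silhouette
#'
#' Runs [kmeansRestarts()] for each candidate \code{k} and returns the
#' \code{k} maximising the mean silhouette width of the best partition;
#' ties go to the smaller \code{k}.
#'
#' @param X Data matrix (scaled).
#' @param kRange Candidate cluster counts (subset of 2..n-1).
#' @param nRestarts,seed,tol,maxIter Passed to [kmeansRestarts()].
#'
#' @return List with \code{best_k}, \code{silhouettes} (data.frame of
#'   \code{k}, \code{mean_silhouette}, \code{tot_withinss}) and
#'   \code{partitions} (one partition per k).
#' @export
selectK <- function(X, kRange = 2:8, nRestarts = 100L, seed = 1L,
                    tol = 1e-6, maxIter = 300L) {
  if (!length(kRange)) stop("empty k range")
  X <- as.matrix(X)
  if (any(kRange < 2L) || any(kRange > nrow(X) - 1L))
    stop("kRange must lie within [2, n-1]")
  parts <- lapply(kRange, function(k)
    kmeansRestarts(X, k, nRestarts = nRestarts, seed = seed,
                   tol = tol, maxIter = maxIter))
  D <- .fullDist(X)
  sil <- vapply(parts, function(p) .meanSilhouetteD(p$labels, D), 0)
  tab <- data.frame(k = kRange, mean_silhouette = sil,
                    tot_withinss = vapply(parts, `[[`, 0, "tot_withinss"))
  best <- kRange[which.max(sil)]  # which.max: first max -> smallest k
  list(best_k = best, silhouettes = tab,
       partitions = stats::setNames(parts, paste0("k", kRange)))
}

# optimal 1-to-1 matching of rows of B to rows of A by total center
# distance; k is small (<= 8), so permutations are enumerated exactly
.matchCenters <- function(A, B) {
  k <- nrow(A)
  perms <- .permutations(k)
  D <- sqrt(.sqDistTo(B, A))  # D[i, j] = dist(B_i, A_j)
  costs <- vapply(seq_len(nrow(perms)), function(p)
    sum(D[cbind(seq_len(k), perms[p, ])]), 0)
  perms[which.min(costs), ]   # m[i] = cluster of A matched to B_i
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Sex-stratified de novo clustering with cross-sex label alignment
#'
#' Scales the features within each sex (self-scaling: each sex's own means
#' and SDs), runs [kmeansRestarts()] separately for female and male
#' participants, then aligns the two sets of cluster labels by optimal
#' 1-to-1 matching of the scaled cluster centers so that label \code{j}
#' refers to the same phenotype in both sexes. Global labels follow the
#' male stratum's ordering by cluster size (largest = 1).
#'
#' @param records Cohort data.frame with a \code{sex} column.
#' @param k Number of clusters per sex (default 2).
#' @param nRestarts,seed Passed to [kmeansRestarts()].
#' @param featureOrder Clustering features.
#'
#' @return List with \code{labels} (global aligned labels, in the row order
#'   of \code{records}), \code{bySex} (per-sex partitions), and
#'   \code{alignment} (permutation applied to the female labels).
#' @export
sexStratifiedDenovo <- function(records, k = 2L, nRestarts = 100L,
                                seed = 1L,
                                featureOrder = clusteringFeatures()) {
  sexes <- intersect(c("male", "female"), unique(records$sex))
  if (length(sexes) < 2L)
    warning("only one sex present; running a single stratum")
  X <- buildFeatureMatrix(records, featureOrder)
  parts <- list()
  Zs <- list()
  for (s in sexes) {
    idx <- records$sex == s
    if (sum(idx) < k) stop("sex stratum '", s, "' smaller than k")
    Xs <- X[idx, , drop = FALSE]
    Z <- scaleFeatures(Xs, selfScalingParams(Xs))
    # per-sex seed stream
    sSeed <- (as.integer(seed) + 31L * match(s, c("male", "female"))) %%
      .Machine$integer.max
    parts[[s]] <- kmeansRestarts(Z, k, nRestarts = nRestarts, seed = sSeed)
    Zs[[s]] <- Z
  }
  labels <- integer(nrow(records))
  alignment <- seq_len(k)
  ref <- sexes[1]
  # reference stratum: relabel by decreasing cluster size
  sz <- table(factor(parts[[ref]]$labels, levels = seq_len(k)))
  refOrder <- order(-as.integer(sz))
  refMap <- match(seq_len(k), refOrder)
  labels[records$sex == ref] <- refMap[parts[[ref]]$labels]
  refCenters <- parts[[ref]]$centers[refOrder, , drop = FALSE]
  if (length(sexes) == 2L) {
    oth <- sexes[2]
    m <- .matchCenters(refCenters, parts[[oth]]$centers)
    alignment <- m
    labels[records$sex == oth] <- m[parts[[oth]]$labels]
  }
  list(labels = labels, bySex = parts, alignment = alignment,
       sexes = sexes)
}

#' Concordance between de novo clusters and centroid subtypes
#'
#' Cross-tabulates de novo cluster labels against supervised subtype labels
#' and reports, for each de novo cluster, the best-matching subtype and the
#' percentage overlap (shared members / cluster size x 100), overall and
#' per sex.
#'
#' @param denovoLabels Integer de novo labels.
#' @param subtypeLabels Character centroid subtype labels, same participants
#'   in the same order.
#' @param sex Optional sex vector for per-sex overlaps.
#'
#' @return List with \code{crosstab} (clusters x subtypes count matrix) and
#'   \code{overlap} (data.frame: cluster, best_match, overall and per-sex
#'   overlap percentages).
#' @export
concordance <- function(denovoLabels, subtypeLabels, sex = NULL) {
  if (length(denovoLabels) != length(subtypeLabels))
    stop("label vectors must cover the same participants")
  ct <- table(cluster = denovoLabels, subtype = subtypeLabels)
  ov <- data.frame(cluster = rownames(ct), stringsAsFactors = FALSE)
  ov$best_match <- colnames(ct)[apply(ct, 1, which.max)]
  ov$overlap_pct <- 100 * apply(ct, 1, max) / rowSums(ct)
  if (!is.null(sex)) {
    for (s in c("male", "female")) {
      idx <- sex == s
      if (!any(idx)) { ov[[paste0("overlap_pct_", s)]] <- NA_real_; next }
      cts <- table(factor(denovoLabels[idx], levels = rownames(ct)),
                   factor(subtypeLabels[idx], levels = colnames(ct)))
      # overlap with the overall best match, within this sex
      ov[[paste0("overlap_pct_", s)]] <- vapply(seq_len(nrow(ct)),
        function(i) {
          tot <- sum(cts[i, ])
          if (tot == 0) return(NA_real_)
          100 * cts[i, ov$best_match[i]] / tot
        }, 0)
    }
  }
  list(crosstab = ct, overlap = ov)
}
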