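# Independent oracles used across the suite. Each reimplements a quantity
# by a different route than the package (closed form, enumeration, or
# hand-rolled iteration) so agreement is a real check, not a tautology.

# Closed-form algebraic inversion of the fasting steady-state model:
# beta-cell fraction from the secretion equation, sensitivity from the
# positive root of the quadratic glucose-balance equation. The package
# solver uses damped Newton on the forward model instead.
homa2Oracle <- function(G, C) {
  p <- diabclust:::.homa2Params()
  c_rel <- C / p$C_ref
  sig <- (G^2 / (G^2 + p$K_B^2)) / (p$G_ref^2 / (p$G_ref^2 + p$K_B^2))
  b <- c_rel / sig
  phi <- G * (p$G_ref + p$K_U) / (p$G_ref * (G + p$K_U))
  r <- p$rho * pmax(0, G - p$G_renal) / p$G_ref
  A <- p$kappa * p$d1 * phi
  B <- p$kappa * (p$d0 * phi + r) + p$d1 * phi
  Cc <- p$d0 * phi + r - 1 - p$kappa
  x <- (-B + sqrt(B^2 - 4 * A * Cc)) / (2 * A)
  data.frame(homa2_b = 100 * b, homa2_ir = c_rel / x)
}

# Exhaustive k=2 partition search: minimal total within-cluster SS over all
# 2^(n-1) - 1 nonempty bipartitions.
bruteForceKmeans2 <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 12)
  best <- Inf
  wss <- function(M) {
    if (nrow(M) == 0) return(0)
    sum(sweep(M, 2, colMeans(M))^2)
  }
  for (mask in 1:(2^(n - 1) - 1)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!any(inA) || all(inA)) next
    tot <- wss(X[inA, , drop = FALSE]) + wss(X[!inA, , drop = FALSE])
    if (tot < best) best <- tot
  }
  best
}

# Naive silhouette: double loop over points and clusters with explicit
# pairwise distances.
naiveSilhouette <- function(labels, X) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (!length(mates)) { s[i] <- 0; next }
    a <- mean(vapply(mates, function(j) d(i, j), 0))
    b <- min(vapply(setdiff(unique(labels), own), function(cl) {
      mean(vapply(which(labels == cl), function(j) d(i, j), 0))
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Hand-rolled iteratively reweighted least squares for logistic regression,
# independent of stats::glm.
irlsLogistic <- function(x, y, maxit = 100, tol = 1e-12) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    betaNew <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  se <- sqrt(diag(solve(t(X) %*% (W * X))))
  list(coef = drop(beta), se = se)
}

# Minimal valid cohort data.frame for tests.
makeRecords <- function(n, sex = rep("male", n), age = 37, bmi = 26,
                        hba1c = 72, glucose = 9.2, cpep = 0.76, ...) {
  df <- data.frame(
    participant_id = sprintf("T%04d", seq_len(n)),
    sex = rep_len(sex, n),
    age_at_diagnosis = rep_len(age, n),
    bmi = rep_len(bmi, n),
    hba1c = rep_len(hba1c, n),
    fasting_glucose = rep_len(glucose, n),
    fasting_cpeptide = rep_len(cpep, n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df
}

# A small centroid model with geometrically simple centroids for exact
# tie-break and distance tests.
toyModel <- function() {
  cent <- rbind(SIDD = c(1, 0, 0, 0, 0),
                SIRD = c(0, 3, 0, 0, 0),
                MOD  = c(-1, 0, 0, 0, 0),
                MARD = c(0, 0, 3, 0, 0))
  CentroidModel(cent, center = rep(0, 5), scale = rep(1, 5))
}
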