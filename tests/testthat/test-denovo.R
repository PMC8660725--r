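test_that("k-means recovers two well-separated Gaussian blobs", {
  withr::with_seed(51, {
    X <- rbind(matrix(rnorm(100 * 2, -5, 0.5), 100, 2),
               matrix(rnorm(100 * 2, 5, 0.5), 100, 2))
  })
  truth <- rep(1:2, each = 100)
  fit <- kmeansRestarts(X, 2, nRestarts = 10, seed = 1)
  agree <- max(mean(fit$labels == truth), mean(fit$labels == 3 - truth))
  expect_equal(agree, 1)
})

test_that("k-means optimum matches exhaustive bipartition enumeration", {
  withr::with_seed(52, {
    for (rep in 1:5) {
      n <- sample(5:8, 1)
      X <- matrix(rnorm(n * 2), n, 2)
      fit <- kmeansRestarts(X, 2, nRestarts = 25, seed = rep)
      expect_equal(fit$tot_withinss, bruteForceKmeans2(X),
                   tolerance = 1e-9)
    }
  })
})

test_that("k-means agrees with the reference implementation's optimum", {
  withr::with_seed(53, {
    X <- matrix(rnorm(150 * 4), 150, 4)
    ours <- kmeansRestarts(X, 3, nRestarts = 20, seed = 9)
    ref <- kmeans(X, 3, nstart = 20, iter.max = 100,
                  algorithm = "Lloyd")
    expect_equal(ours$tot_withinss, ref$tot.withinss, tolerance = 0.02)
  })
})

test_that("duplicated identical points give zero within-SS", {
  X <- rbind(matrix(1, 3, 2), matrix(9, 3, 2))
  fit <- kmeansRestarts(X, 2, nRestarts = 5, seed = 1)
  expect_equal(fit$tot_withinss, 0)
})

test_that("k-means is reproducible from its seed and errors when n < k", {
  withr::with_seed(54, X <- matrix(rnorm(50 * 3), 50, 3))
  f1 <- kmeansRestarts(X, 4, nRestarts = 8, seed = 77)
  f2 <- kmeansRestarts(X, 4, nRestarts = 8, seed = 77)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$tot_withinss, f2$tot_withinss)
  expect_error(kmeansRestarts(X[1:3, ], 4), "n < k")
})

test_that("silhouette matches a hand-computed 4-point instance", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(1, 1, 2, 2)
  # by hand: a = 1 for every point; b = mean distance to the other pair
  byHand <- mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                   (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(meanSilhouette(lab, X), byHand, tolerance = 1e-12)
})

test_that("silhouette equals naive recomputation and the cluster package", {
  skip_if_not_installed("cluster")
  withr::with_seed(55, {
    for (rep in 1:4) {
      n <- sample(5:8, 1)
      X <- matrix(rnorm(n * 2), n, 2)
      lab <- sample(1:2, n, replace = TRUE)
      if (length(unique(lab)) < 2) lab[1] <- 3 - lab[1]
      expect_equal(meanSilhouette(lab, X), naiveSilhouette(lab, X),
                   tolerance = 1e-8)
    }
    Y <- matrix(rnorm(80 * 3), 80, 3)
    labY <- kmeans(Y, 4)$cluster
    expect_equal(meanSilhouette(labY, Y),
                 mean(cluster::silhouette(labY, dist(Y))[, 3]),
                 tolerance = 1e-8)
  })
})

test_that("silhouette approaches 1 for extreme separation and 0 under
           random labels", {
  withr::with_seed(56, {
    X <- rbind(matrix(rnorm(50 * 2, -100, 0.1), 50, 2),
               matrix(rnorm(50 * 2, 100, 0.1), 50, 2))
    expect_gt(meanSilhouette(rep(1:2, each = 50), X), 0.99)
    Y <- matrix(rnorm(500 * 2), 500, 2)
    expect_lt(abs(meanSilhouette(sample(1:2, 500, TRUE), Y)), 0.1)
  })
  expect_error(meanSilhouette(rep(1, 10), matrix(rnorm(20), 10, 2)),
               "2 clusters")
})

test_that("silhouette-based selection finds three planted blobs", {
  withr::with_seed(57, {
    X <- rbind(matrix(rnorm(60 * 2, -8, 0.6), 60, 2),
               matrix(rnorm(60 * 2, 0, 0.6), 60, 2),
               matrix(rnorm(60 * 2, 8, 0.6), 60, 2))
  })
  sel <- selectK(X, kRange = 2:6, nRestarts = 10, seed = 4)
  expect_equal(sel$best_k, 3L)
  expect_equal(nrow(sel$silhouettes), 5L)
})

test_that("selectK handles trivial ranges and rejects invalid ones", {
  withr::with_seed(58, X <- matrix(rnorm(30 * 2), 30, 2))
  expect_equal(selectK(X, kRange = 2, nRestarts = 5, seed = 1)$best_k, 2)
  expect_error(selectK(X, kRange = integer(0)), "empty")
  expect_error(selectK(X, kRange = c(2, 40)), "kRange")
})

test_that("selectK is invariant to row permutation on separated data", {
  withr::with_seed(59, {
    X <- rbind(matrix(rnorm(40 * 2, -6, 0.5), 40, 2),
               matrix(rnorm(40 * 2, 6, 0.5), 40, 2))
    perm <- sample(nrow(X))
  })
  s1 <- selectK(X, kRange = 2:4, nRestarts = 10, seed = 3)
  s2 <- selectK(X[perm, ], kRange = 2:4, nRestarts = 10, seed = 3)
  expect_equal(s1$best_k, s2$best_k)
  # the winning k's optimum is found regardless of row order
  expect_equal(s1$silhouettes$tot_withinss[1],
               s2$silhouettes$tot_withinss[1], tolerance = 1e-6)
  expect_equal(max(s1$silhouettes$mean_silhouette),
               max(s2$silhouettes$mean_silhouette), tolerance = 1e-6)
})

test_that("sex-stratified clustering aligns matching phenotypes across
           sexes", {
  withr::with_seed(60, {
    # same two phenotype blobs in both sexes, different sampling
    blob <- function(n, mu) {
      cbind(age_at_diagnosis = rnorm(n, 37, 1),
            bmi = rnorm(n, mu[1], 0.5),
            hba1c = rnorm(n, mu[2], 2),
            homa2_b = rnorm(n, mu[3], 4),
            homa2_ir = rnorm(n, 2, 0.2))
    }
    mkSex <- function(s, n1, n2) {
      M <- rbind(blob(n1, c(24, 90, 40)), blob(n2, c(30, 58, 90)))
      df <- as.data.frame(M)
      df$participant_id <- paste0(s, seq_len(nrow(M)))
      df$sex <- s
      df$fasting_glucose <- 9; df$fasting_cpeptide <- 0.7
      df$truth <- rep(1:2, c(n1, n2))
      df
    }
    rec <- rbind(mkSex("male", 80, 40), mkSex("female", 30, 60))
  })
  fit <- sexStratifiedDenovo(rec, k = 2, nRestarts = 10, seed = 2)
  # within each sex the partition is exact, and cross-sex labels refer to
  # the same underlying phenotype
  m1 <- fit$labels[rec$sex == "male" & rec$truth == 1]
  f1 <- fit$labels[rec$sex == "female" & rec$truth == 1]
  expect_equal(length(unique(m1)), 1L)
  expect_equal(length(unique(f1)), 1L)
  expect_equal(unique(m1), unique(f1))
  m2 <- unique(fit$labels[rec$sex == "male" & rec$truth == 2])
  expect_false(unique(m1) == m2)
  # reference stratum labels ordered by size: male blob 1 is larger
  expect_equal(unique(m1), 1L)
})

test_that("stratum smaller than k errors; single sex warns", {
  withr::with_seed(62, {
    jitter5 <- function(rec) {
      for (f in clusteringFeatures()[1:3])
        rec[[f]] <- rec[[f]] + rnorm(nrow(rec))
      rec$fasting_glucose <- rec$fasting_glucose + runif(nrow(rec))
      rec$fasting_cpeptide <- rec$fasting_cpeptide + runif(nrow(rec), 0, 0.3)
      rec
    }
    rec <- jitter5(makeRecords(10, sex = c(rep("male", 9), "female")))
    expect_error(sexStratifiedDenovo(rec, k = 2), "smaller than k")
    rec2 <- jitter5(makeRecords(12, sex = "male"))
    expect_warning(
      sexStratifiedDenovo(rec2, k = 2, nRestarts = 3, seed = 1),
      "one sex")
  })
})

test_that("concordance is 100% for identical labellings and near the modal
           share under independence", {
  lab <- sample(1:2, 300, replace = TRUE)
  sub <- c("SIDD", "MOD")[lab]
  cc <- concordance(lab, sub)
  expect_true(all(cc$overlap$overlap_pct == 100))
  withr::with_seed(61, {
    d <- sample(1:2, 4000, replace = TRUE)
    s <- sample(subtypeLabels(), 4000, replace = TRUE,
                prob = c(0.5, 0.1, 0.3, 0.1))
  })
  cc2 <- concordance(d, s)
  # independent labels: best overlap tracks the largest subtype share (50%)
  expect_true(all(abs(cc2$overlap$overlap_pct - 50) < 5))
  expect_equal(unname(rowSums(cc2$crosstab)),
               as.integer(table(d)))
  expect_error(concordance(1:5, c("A", "B")), "same participants")
})
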