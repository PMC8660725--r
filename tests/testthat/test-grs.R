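test_that("score is the weighted dosage sum plus the haplotype term", {
  cfg <- exampleGRSConfig()
  rs <- grsSNPs(cfg)
  # hand-chosen dosages: only the first three additive SNPs nonzero,
  # haplotype pair (0, 0) has weight 0 in the example table
  D <- matrix(0, 1, 9, dimnames = list("S1", rs))
  D[1, cfg@snps$rsid[1:3]] <- c(1, 2, 0)
  got <- computeGRS(D, cfg)
  want <- sum(cfg@snps$weight[1:3] * c(1, 2, 0))
  expect_equal(got$score, want)
  expect_equal(got$n_imputed, 0L)

  # all-zero dosages with zero-weight combination -> score 0
  D0 <- matrix(0, 1, 9, dimnames = list("S1", rs))
  expect_equal(computeGRS(D0, cfg)$score, 0)
})

test_that("the DR3/DR4-equivalent heterozygote gets the combination
           weight, not an additive one", {
  cfg <- exampleGRSConfig()
  rs <- grsSNPs(cfg)
  D <- matrix(0, 3, 9, dimnames = list(paste0("S", 1:3), rs))
  D[1, cfg@haplotypeA] <- 1; D[1, cfg@haplotypeB] <- 1  # DR3/DR4
  D[2, cfg@haplotypeA] <- 1                             # DR3/X
  D[3, cfg@haplotypeB] <- 1                             # DR4/X
  sc <- computeGRS(D, cfg)$score
  expect_equal(sc[1], cfg@haplotypeWeights["1", "1"])
  expect_gt(sc[1], sc[2] + sc[3])  # super-additive heterozygote risk
})

test_that("score is linear in additive dosages", {
  cfg <- exampleGRSConfig()
  rs <- grsSNPs(cfg)
  withr::with_seed(71, {
    d1 <- runif(7); d2 <- runif(7)
  })
  mk <- function(d) {
    D <- matrix(0, 1, 9, dimnames = list("S", rs))
    D[1, cfg@snps$rsid] <- d
    D
  }
  s1 <- computeGRS(mk(d1), cfg)$score
  s2 <- computeGRS(mk(d2), cfg)$score
  s12 <- computeGRS(mk(d1 + d2), cfg)$score
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("tabular dosages counting the other allele are flipped", {
  cfg <- exampleGRSConfig()
  path <- withr::local_tempfile(fileext = ".csv")
  s <- cfg@snps[1, ]
  writeLines(c(
    "rsid,counted_allele,other_allele,S1,S2",
    paste(s$rsid, s$other_allele, s$effect_allele, "0.4", "2", sep = ",")
  ), path)
  out <- suppressWarnings(readDosages(path, cfg))  # other rsids absent
  expect_equal(unname(out$dosages[, s$rsid]), c(1.6, 0))
})

test_that("allele-flip invariance: flipped file encoding leaves scores
           unchanged", {
  cfg <- exampleGRSConfig()
  rs <- grsSNPs(cfg)
  withr::with_seed(72, d <- round(runif(9) * 2, 2))
  mkFile <- function(flip) {
    path <- tempfile(fileext = ".csv")
    rows <- vapply(seq_along(rs), function(i) {
      eff <- diabclust:::.effectAllele(cfg, rs[i])
      oth <- if (rs[i] %in% cfg@snps$rsid)
        cfg@snps$other_allele[match(rs[i], cfg@snps$rsid)] else "G"
      if (flip[i])
        paste(rs[i], oth, eff, format(2 - d[i]), sep = ",")
      else
        paste(rs[i], eff, oth, format(d[i]), sep = ",")
    }, "")
    writeLines(c("rsid,counted_allele,other_allele,S1", rows), path)
    path
  }
  withr::with_seed(73, flip <- runif(9) < 0.5)
  a <- readDosages(mkFile(rep(FALSE, 9)), cfg)
  b <- readDosages(mkFile(flip), cfg)
  expect_length(a$unusable, 0L)
  expect_equal(a$dosages, b$dosages, tolerance = 1e-9)
  expect_equal(computeGRS(a$dosages, cfg)$score,
               computeGRS(b$dosages, cfg)$score, tolerance = 1e-9)
})

test_that("VCF ingestion counts ALT copies and round-trips the writer", {
  cfg <- exampleGRSConfig()
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "S1\tS2"),
    paste0("1\t100\t", cfg@snps$rsid[1], "\t",
           cfg@snps$other_allele[1], "\t", cfg@snps$effect_allele[1],
           "\t.\tPASS\t.\tGT\t0/1\t1/1")
  ), path)
  out <- suppressWarnings(readDosages(path, cfg))  # single-variant file
  expect_equal(unname(out$dosages[, cfg@snps$rsid[1]]), c(1, 2))

  freqs <- grsConfigFrequencies(cfg)
  g <- generateGenotypes(20, freqs, seed = 5)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  rs <- colnames(g$dosages)
  al <- data.frame(
    rsid = rs,
    ref = vapply(rs, function(r) {
      i <- match(r, cfg@snps$rsid)
      if (!is.na(i)) cfg@snps$other_allele[i] else "G"
    }, ""),
    alt = vapply(rs, function(r) diabclust:::.effectAllele(cfg, r), ""))
  writeVCF(g$dosages, vcf, alleles = al)
  back <- readDosages(vcf, cfg)
  expect_equal(back$dosages[, rs], g$dosages, tolerance = 1e-6)
})

test_that("missing loci are imputed from allele frequency and flagged;
           absent haplotype needs a fallback", {
  cfg <- exampleGRSConfig()
  rs <- grsSNPs(cfg)
  D <- matrix(1, 2, 9, dimnames = list(c("S1", "S2"), rs))
  D[1, cfg@snps$rsid[2]] <- NA
  got <- computeGRS(D, cfg)
  expect_equal(got$n_imputed, c(1L, 0L))
  delta <- got$score[2] - got$score[1]
  expect_equal(delta,
               cfg@snps$weight[2] * (1 - 2 * cfg@snps$eaf[2]),
               tolerance = 1e-12)
  D[, cfg@haplotypeA] <- NA
  expect_error(computeGRS(D, cfg), "fallback")
  withFb <- computeGRS(D, cfg, haplotypeFallback = 0.5)
  expect_true(all(withFb$haplotype_fallback))
})

test_that("HWE genotype scores match the analytic expectation", {
  cfg <- exampleGRSConfig()
  freqs <- grsConfigFrequencies(cfg, haplotypeFreqs = c(0.15, 0.2))
  g <- generateGenotypes(20000, freqs, seed = 6)
  sc <- computeGRS(g$dosages, cfg)$score
  hweP <- function(p) dbinom(0:2, 2, p)
  eHap <- drop(hweP(0.15) %*% cfg@haplotypeWeights %*% hweP(0.2))
  want <- sum(cfg@snps$weight * 2 * cfg@snps$eaf) + eHap
  expect_equal(mean(sc), want, tolerance = 0.02)
})

test_that("percentile proportions follow their definition", {
  withr::with_seed(74, ref <- rnorm(1000))
  cuts <- referenceCutoffs(ref, c(80, 90))
  pp <- percentileProportions(ref, cuts)
  expect_equal(pp$pct[pp$percentile == "90"], 10, tolerance = 1)
  expect_equal(pp$pct[pp$percentile == "80"], 20, tolerance = 1)
  low <- percentileProportions(ref - 100, cuts)
  expect_equal(low$pct, c(0, 0))
  expect_error(percentileProportions(numeric(0), cuts), "empty")
  # a high-risk group exceeds a control group above the 90th cut-off
  withr::with_seed(75, {
    t1d <- rnorm(500, 2)
    ctrl <- rnorm(500, 0)
  })
  cut90 <- referenceCutoffs(t1d, 90)
  expect_gt(percentileProportions(t1d, cut90)$pct,
            percentileProportions(ctrl, cut90)$pct)
})

test_that("logistic discrimination matches an independent IRLS fit to
           1e-6 and flags separation", {
  withr::with_seed(76, {
    x <- rnorm(50)
    y <- rbinom(50, 1, plogis(0.5 + 1.2 * x))
  })
  got <- grsDiscrimination(x, y)
  want <- irlsLogistic(x, y)
  expect_equal(got$slope, unname(want$coef[2]), tolerance = 1e-6)
  expect_equal(got$se, unname(want$se[2]), tolerance = 1e-6)
  expect_false(got$separation)
  # constant shift between groups -> positive slope
  withr::with_seed(77, {
    s <- c(rnorm(100), rnorm(100) + 1)
    grp <- rep(0:1, each = 100)
  })
  expect_gt(grsDiscrimination(s, grp)$slope, 0)
  # perfect separation flagged, not fatal
  sep <- grsDiscrimination(c(rnorm(30), rnorm(30) + 100),
                           rep(0:1, each = 30))
  expect_true(sep$separation)
  expect_error(grsDiscrimination(1:10, rep(1, 10)), "two groups")
})

test_that("identical score distributions give a near-zero slope", {
  withr::with_seed(78, {
    zs <- replicate(40, {
      s <- rnorm(200)
      g <- rep(0:1, 100)
      grsDiscrimination(s, g)$z
    })
  })
  expect_gt(mean(abs(zs) < 2), 0.85)
})
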