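test_that("MDRD eGFR evaluates the published formula", {
  g <- egfrMDRD(1.0, 40, "male")
  expect_equal(g, 175 * 40^-0.203, tolerance = 1e-9)
  expect_equal(g, 82.8, tolerance = 0.1)
  expect_equal(ckdStage(g), factor("early",
               levels = c("normal", "early", "moderate", "severe")))
  expect_equal(egfrMDRD(1.0, 40, "female"), g * 0.742, tolerance = 1e-12)
  expect_equal(egfrMDRD(1.0, 40, "male", black = TRUE), g * 1.212,
               tolerance = 1e-12)
  # monotone decreasing in creatinine
  crea <- seq(0.5, 4, by = 0.25)
  expect_true(all(diff(egfrMDRD(crea, 40, "male")) < 0))
  expect_error(egfrMDRD(0, 40, "male"), "positive")
  expect_equal(egfrMDRD(1.0, 40, "male", constant = 186),
               g * 186 / 175, tolerance = 1e-12)
})

test_that("CKD staging bands assign boundaries downward", {
  got <- as.character(ckdStage(c(95, 90, 75, 60, 45, 30, 10)))
  expect_equal(got, c("normal", "early", "early", "moderate", "moderate",
                      "severe", "severe"))
  expect_error(ckdStage(-5), "non-negative")
})

test_that("complication profile derives composites with unknown
           propagation", {
  rec <- makeRecords(5,
    serum_creatinine = c(0.9, 2.5, NA, 0.9, 0.9),
    diabetes_duration = 5,
    macroalbuminuria = c(TRUE, FALSE, FALSE, NA, NA),
    coronary_event = c(TRUE, FALSE, NA, FALSE, NA),
    stroke = c(FALSE, FALSE, TRUE, FALSE, NA),
    retinopathy_grade = c("NPDR", "none", "PDR", NA, "none"))
  prof <- complicationProfile(rec)
  expect_true(prof$nephropathy[1])             # macroalbuminuria alone
  expect_true(prof$nephropathy[2])             # CKD from high creatinine
  expect_true(is.na(prof$nephropathy[4]) || prof$nephropathy[4])
  expect_true(prof$cvd[1])
  expect_true(prof$cvd[3])                     # stroke despite unknown CAD
  expect_true(is.na(prof$cvd[5]))
  expect_equal(prof$retinopathy[1:3], c(TRUE, FALSE, TRUE))
  expect_true(is.na(prof$retinopathy[4]))
  expect_true(is.na(prof$ckd_stage[3]))
  # stage consistent with egfr thresholds
  ok <- !is.na(prof$egfr)
  expect_equal(as.character(prof$ckd_stage[ok]),
               as.character(ckdStage(prof$egfr[ok])))
})

test_that("prevalence tables use available-data denominators", {
  rec <- makeRecords(10,
    neuropathy = c(TRUE, TRUE, FALSE, NA, NA, FALSE, TRUE, NA, TRUE, NA))
  grp <- rep(c("A", "B"), each = 5)
  tab <- prevalenceTable(rec, grp, outcomes = "neuropathy")
  a <- tab[tab$group == "A", ]
  expect_equal(a$n_available, 3L)
  expect_equal(a$n_cases, 2L)
  expect_equal(a$pct, 100 * 2 / 3)
  rec2 <- makeRecords(3, neuropathy = NA)
  tab2 <- prevalenceTable(rec2, rep("A", 3), outcomes = "neuropathy")
  expect_true(is.na(tab2$pct))
})

test_that("treatment table categories partition each group", {
  rec <- makeRecords(6, treatment = "diet_only")
  tab <- treatmentTable(rec, rep("A", 6))
  expect_equal(tab$pct[tab$treatment == "diet_only"], 100)
  expect_equal(sum(tab$pct), 100)
  withr::with_seed(81, {
    rec2 <- makeRecords(200, treatment = sample(
      c("diet_only", "oha_only", "insulin_only", "oha_plus_insulin"),
      200, replace = TRUE))
    grp <- sample(c("X", "Y"), 200, replace = TRUE)
  })
  tab2 <- treatmentTable(rec2, grp)
  for (g in c("X", "Y"))
    expect_equal(sum(tab2$pct[tab2$group == g]), 100, tolerance = 1e-9)
})

test_that("chi-square matches the 2x2 closed form and handles edge cases", {
  got <- chiSquare(matrix(c(10, 20, 20, 10), 2))
  expect_equal(got$statistic, 60 * (10 * 10 - 20 * 20)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-9)
  expect_equal(got$df, 1)
  same <- chiSquare(matrix(c(30, 60, 10, 20), 2))  # identical proportions
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)
  withr::with_seed(82, {
    for (rep in 1:10) {
      m <- matrix(rpois(4, 30) + 1, 2)
      cf <- sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
        prod(rowSums(m), colSums(m))
      expect_equal(chiSquare(m)$statistic, cf, tolerance = 1e-9)
    }
  })
  expect_error(chiSquare(matrix(c(1, 2, 3), 3, 1)), "2 x 2")
  expect_error(chiSquare(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("group comparisons reproduce hand-computed statistics", {
  x <- c(5.1, 4.9, 5.6, 4.8, 5.2)
  y <- c(6.0, 6.4, 5.8, 6.1)
  got <- groupCompare(c(x, y), rep(c("a", "b"), c(5, 4)))
  # pooled-variance t by hand
  sp2 <- (4 * var(x) + 3 * var(y)) / 7
  tHand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(got$statistic, tHand, tolerance = 1e-9)
  expect_equal(got$df2, 7)
  # F = t^2 for two groups
  gotF <- groupCompare(c(x, y), rep(c("a", "b"), c(5, 4)), mode = "anova")
  expect_equal(gotF$statistic, tHand^2, tolerance = 1e-9)
  expect_equal(gotF$p, got$p, tolerance = 1e-9)
  # identical groups -> t = 0, p = 1
  same <- groupCompare(c(x, x), rep(c("a", "b"), each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # degenerate variance flagged
  dg <- groupCompare(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5))
  expect_true(dg$degenerate)
})

test_that("duration adjustment removes a pure-duration artefact", {
  withr::with_seed(83, {
    dur <- c(rnorm(100, 4, 1), rnorm(100, 10, 1))  # group 2 longer duration
    grp <- rep(c("a", "b"), each = 100)
    y <- 2 * dur + rnorm(200, 0, 0.5)  # outcome driven by duration only
  })
  raw <- groupCompare(y, grp)
  adj <- groupCompare(y, grp, adjustForDuration = TRUE, duration = dur)
  expect_lt(raw$p, 1e-10)     # confounded comparison looks significant
  expect_gt(adj$p, 0.01)      # adjustment absorbs it
  expect_equal(adj$method, "anova_duration_adjusted")
})

test_that("covariate-free adjusted OR reduces to the 2x2 closed form", {
  counts <- c(a = 30, b = 70, c = 55, d = 45)  # cases/non in two groups
  rec <- makeRecords(200,
    neuropathy = c(rep(TRUE, 30), rep(FALSE, 70),
                   rep(TRUE, 55), rep(FALSE, 45)))
  sub <- rep(c("MOD", "SIDD"), each = 100)
  got <- adjustedComplicationOR(rec, "neuropathy", sub,
                                pair = c("MOD", "SIDD"),
                                covariates = character(0))
  expect_equal(got$or, (55 / 45) / (30 / 70), tolerance = 1e-6)
  expect_false(got$separation)
})

test_that("adjusted OR detects a planted subtype effect", {
  spec <- wellgenCohortSpec(n = 4000)
  coh <- generateCohort(spec, seed = 19)
  coh <- attachOutcomes(coh, spec, seed = 19)
  rec <- complicationProfile(coh$records)
  truth <- coh$truth$label
  got <- adjustedComplicationOR(rec, "retinopathy", truth,
                                pair = c("MOD", "SIDD"))
  # generating prevalences: 36.8% in SIDD vs 18.0% in MOD
  expect_gt(got$or, 1)
  expect_lt(got$p, 0.001)
})

test_that("Bonferroni flags use alpha over m", {
  expect_true(bonferroni(0.04, 0.05)$flags)
  b <- bonferroni(c(0.01, rep(0.5, 9)))
  expect_false(b$flags[1])          # 0.01 > 0.005
  expect_equal(b$threshold, 0.005)
  expect_false(any(bonferroni(rep(1, 5))$flags))
  expect_error(bonferroni(numeric(0)), "at least one")
})
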