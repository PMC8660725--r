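## Complication phenotypes and subgroup comparison statistics: MDRD eGFR,
## CKD staging, composite outcomes, prevalence/treatment tables with
## available-data denominators, and the chi-square / t-test / ANOVA /
## logistic-regression comparisons with Bonferroni flags.

#' Estimated GFR by the 4-variable MDRD equation
#'
#' IDMS-traceable MDRD study equation:
#' \deqn{175 \times \mathrm{Scr}^{-1.154} \times \mathrm{age}^{-0.203}
#' \times 0.742\ \mathrm{if\ female} \times 1.212\ \mathrm{if\ black}}
#' with serum creatinine in mg/dl and age in years. The pre-IDMS constant
#' 186 is available via \code{constant}.
#'
#' @param creatinine Serum creatinine, mg/dl (positive).
#' @param age Age, years (positive).
#' @param sex \code{"male"} or \code{"female"}.
#' @param black Black ethnicity indicator (default FALSE).
#' @param constant 175 (IDMS, default) or 186.
#'
#' @return eGFR in ml/min per 1.73 m2.
#' @examples
#' egfrMDRD(1.0, 40, "male")  # ~82.8
#' @export
egfrMDRD <- function(creatinine, age, sex, black = FALSE, constant = 175) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0) ||
      any(!is.finite(age)) || any(age <= 0))
    stop("creatinine and age must be positive and finite")
  stopifnot(all(sex %in% c("male", "female")))
  constant * creatinine^-1.154 * age^-0.203 *
    ifelse(sex == "female", 0.742, 1) * ifelse(black, 1.212, 1)
}

#' CKD stage from eGFR
#'
#' Bands: >90 normal; (60, 90] early (mild); (30, 60] moderate; <=30
#' severe. Boundary values are assigned to the lower (worse) stage.
#'
#' @param egfr eGFR values, ml/min per 1.73 m2 (non-negative).
#' @return factor with levels normal, early, moderate, severe.
#' @examples
#' ckdStage(c(95, 75, 45, 30))
#' @export
ckdStage <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr < 0))
    stop("eGFR must be non-negative and finite")
  cut(egfr, breaks = c(-Inf, 30, 60, 90, Inf),
      labels = c("severe", "moderate", "early", "normal"),
      right = TRUE) |>
    factor(levels = c("normal", "early", "moderate", "severe"))
}

#' Derive complication profiles for a cohort
#'
#' Computes eGFR (from serum creatinine via [egfrMDRD()] unless a
#' precomputed \code{egfr} column is present), CKD stage, and the composite
#' outcomes: CKD (stage worse than normal), nephropathy (macroalbuminuria
#' and/or CKD) and CVD (coronary event and/or stroke). Unknown components
#' propagate as NA; a composite is TRUE as soon as one known component is
#' TRUE (the paper-style "and/or" reading).
#'
#' @param records Cohort data.frame with complication fields.
#' @return \code{records} with added columns \code{egfr}, \code{ckd_stage},
#'   \code{ckd}, \code{nephropathy}, \code{cvd}, \code{retinopathy}.
#' @export
complicationProfile <- function(records) {
  rec <- records
  n <- nrow(rec)
  col <- function(nm, default = NA) {
    if (nm %in% names(rec)) rec[[nm]] else rep(default, n)
  }
  if (!"egfr" %in% names(rec)) rec$egfr <- rep(NA_real_, n)
  crea <- col("serum_creatinine", NA_real_)
  dur <- col("diabetes_duration", NA_real_)
  dur[is.na(dur)] <- 0  # current age falls back to age at diagnosis
  needs <- is.na(rec$egfr) & !is.na(crea)
  if (any(needs))
    rec$egfr[needs] <- egfrMDRD(crea[needs],
                                rec$age_at_diagnosis[needs] + dur[needs],
                                rec$sex[needs])
  rec$ckd_stage <- factor(rep(NA_character_, n),
                          levels = c("normal", "early", "moderate",
                                     "severe"))
  ok <- !is.na(rec$egfr)
  rec$ckd_stage[ok] <- ckdStage(rec$egfr[ok])
  rec$ckd <- rec$ckd_stage %in% c("early", "moderate", "severe")
  rec$ckd[is.na(rec$ckd_stage)] <- NA
  # R's three-valued OR gives the "and/or" composite directly:
  # NA | TRUE is TRUE, NA | FALSE stays NA (unknown)
  rec$nephropathy <- col("macroalbuminuria") | rec$ckd
  rec$cvd <- col("coronary_event") | col("stroke")
  rg <- col("retinopathy_grade", NA_character_)
  rec$retinopathy <- rg %in% c("NPDR", "PDR")
  rec$retinopathy[is.na(rg)] <- NA
  rec
}

#' Prevalence table with available-data denominators
#'
#' Counts and percentages of each (logical) outcome within each group. The
#' denominator of every cell is the number of participants in that group
#' with a non-missing value for that outcome, never the full group size.
#'
#' @param records Cohort data.frame (typically after
#'   [complicationProfile()]).
#' @param grouping Vector of group labels aligned with \code{records} (e.g.
#'   subtype assignments or sex).
#' @param outcomes Character vector of logical outcome columns.
#'
#' @return data.frame with one row per (group, outcome): \code{group},
#'   \code{outcome}, \code{n_cases}, \code{n_available}, \code{pct}
#'   (NA when the denominator is zero).
#' @export
prevalenceTable <- function(records, grouping,
                            outcomes = c("cvd", "coronary_event", "stroke",
                                         "nephropathy", "macroalbuminuria",
                                         "ckd", "retinopathy",
                                         "neuropathy")) {
  stopifnot(length(grouping) == nrow(records))
  outcomes <- intersect(outcomes, names(records))
  g <- factor(grouping)
  rows <- list()
  for (gr in levels(g)) {
    idx <- g == gr
    for (oc in outcomes) {
      v <- records[[oc]][idx]
      avail <- sum(!is.na(v))
      cases <- sum(v, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gr, outcome = oc, n_cases = cases, n_available = avail,
        pct = if (avail > 0) 100 * cases / avail else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Treatment-category table
#'
#' Counts and percentages of the four mutually exclusive treatment
#' categories (diet only, OHA only, insulin only, OHA + insulin) within
#' each group, with available-data denominators. Category shares sum to
#' 100\% per group (up to rounding).
#'
#' @param records Cohort data.frame with a \code{treatment} column.
#' @param grouping Group labels aligned with \code{records}.
#'
#' @return data.frame with \code{group}, \code{treatment}, \code{n},
#'   \code{n_available}, \code{pct}.
#' @export
treatmentTable <- function(records, grouping) {
  stopifnot(length(grouping) == nrow(records))
  cats <- c("diet_only", "oha_only", "insulin_only", "oha_plus_insulin")
  g <- factor(grouping)
  rows <- list()
  for (gr in levels(g)) {
    tr <- records$treatment[g == gr]
    avail <- sum(!is.na(tr))
    for (ct in cats) {
      n <- sum(tr == ct, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gr, treatment = ct, n = n, n_available = avail,
        pct = if (avail > 0) 100 * n / avail else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, with
#' \eqn{(r-1)(c-1)} degrees of freedom. Zero row or column margins are an
#' error (the statistic is undefined there).
#'
#' @param counts r x c matrix of non-negative counts (at least 2 x 2).
#' @return data.frame: \code{statistic}, \code{df}, \code{p}.
#' @examples
#' chiSquare(matrix(c(10, 20, 20, 10), 2))  # statistic 20/3
#' @export
chiSquare <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(statistic = unname(ht$statistic),
             df = unname(ht$parameter),
             p = unname(ht$p.value))
}

#' Compare a continuous variable across groups
#'
#' Two groups: classical two-sided pooled-variance t test. More groups (or
#' \code{mode = "anova"}): one-way ANOVA F test. With
#' \code{adjustForDuration}, the group effect is tested by the F test on
#' the group term of a linear model that includes diabetes duration as a
#' covariate (duration entered first).
#'
#' @param values Numeric response.
#' @param groups Group labels (each group needs n >= 2).
#' @param mode \code{"auto"}, \code{"t_test"} or \code{"anova"}.
#' @param adjustForDuration Logical.
#' @param duration Diabetes duration covariate (required when adjusting).
#'
#' @return data.frame: \code{method}, \code{statistic}, \code{df1},
#'   \code{df2}, \code{p}, \code{degenerate} (TRUE when all residual
#'   variance is zero, in which case p is NA).
#' @export
groupCompare <- function(values, groups,
                         mode = c("auto", "t_test", "anova"),
                         adjustForDuration = FALSE, duration = NULL) {
  mode <- match.arg(mode)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  if (mode == "auto") mode <- if (nlevels(g) == 2L) "t_test" else "anova"
  degen <- all(tapply(values, g, stats::var) %in% c(0, NA))
  if (degen)
    return(data.frame(method = mode, statistic = NA_real_, df1 = NA_real_,
                      df2 = NA_real_, p = NA_real_, degenerate = TRUE))
  if (adjustForDuration) {
    if (is.null(duration)) stop("duration covariate required")
    fit <- stats::lm(values ~ duration + g)
    a <- stats::anova(fit)
    return(data.frame(method = "anova_duration_adjusted",
                      statistic = a["g", "F value"],
                      df1 = a["g", "Df"], df2 = a["Residuals", "Df"],
                      p = a["g", "Pr(>F)"], degenerate = FALSE))
  }
  if (mode == "t_test" && nlevels(g) == 2L) {
    ht <- stats::t.test(values ~ g, var.equal = TRUE)
    data.frame(method = "t_test", statistic = unname(ht$statistic),
               df1 = 1, df2 = unname(ht$parameter), p = ht$p.value,
               degenerate = FALSE)
  } else {
    a <- stats::anova(stats::lm(values ~ g))
    data.frame(method = "anova", statistic = a["g", "F value"],
               df1 = a["g", "Df"], df2 = a["Residuals", "Df"],
               p = a["g", "Pr(>F)"], degenerate = FALSE)
  }
}

#' Covariate-adjusted odds ratio for a complication between two subgroups
#'
#' Logistic regression of the outcome on a subgroup indicator plus
#' covariates (default: age at diagnosis, sex, diabetes duration),
#' restricted to participants of the two subgroups with outcome data.
#' Reports the odds ratio of the second subgroup vs the first with a Wald
#' 95\% CI. Separation is flagged, not fatal.
#'
#' @param records Cohort data.frame (after [complicationProfile()]).
#' @param outcome Name of a logical outcome column.
#' @param subgroup Vector of subtype labels aligned with \code{records}.
#' @param pair Character vector of the two subgroups to compare (reference
#'   first), e.g. \code{c("MOD", "SIDD")}.
#' @param covariates Covariate column names (subset of
#'   \code{age_at_diagnosis}, \code{sex}, \code{diabetes_duration}, or any
#'   numeric columns).
#'
#' @return data.frame: \code{outcome}, \code{comparison}, \code{or},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}, \code{n}, \code{separation}.
#' @export
adjustedComplicationOR <- function(records, outcome, subgroup,
                                   pair = c("MOD", "SIDD"),
                                   covariates = c("age_at_diagnosis", "sex",
                                                  "diabetes_duration")) {
  stopifnot(length(subgroup) == nrow(records))
  keep <- subgroup %in% pair & !is.na(records[[outcome]])
  if (sum(keep & subgroup == pair[1]) == 0L ||
      sum(keep & subgroup == pair[2]) == 0L)
    stop("both subgroups need participants with outcome data")
  df <- records[keep, , drop = FALSE]
  df$.y <- as.integer(df[[outcome]])
  df$.grp <- factor(subgroup[keep], levels = pair)
  covariates <- intersect(covariates, names(df))
  form <- stats::reformulate(c(".grp", covariates), response = ".y")
  fit <- suppressWarnings(stats::glm(form, data = df,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  term <- paste0(".grp", pair[2])
  mu <- fit$fitted.values
  sep <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  est <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
  data.frame(outcome = outcome,
             comparison = paste(pair[2], "vs", pair[1]),
             or = exp(est),
             ci_lo = exp(est - 1.959964 * se),
             ci_hi = exp(est + 1.959964 * se),
             p = co[term, "Pr(>|z|)"],
             n = nrow(df), separation = sep,
             stringsAsFactors = FALSE)
}

#' Bonferroni significance flags
#'
#' @param pvals Numeric p values (m >= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with \code{flags} (logical, \code{p < alpha/m}),
#'   \code{threshold} and \code{m}.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (m < 1L) stop("at least one p value required")
  list(flags = pvals < alpha / m, threshold = alpha / m, m = m)
}
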