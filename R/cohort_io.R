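#' Unit conversion constants
#'
#' Conversion factors used during phenotype ingestion: molar mass of glucose
#' (mg per mmol, so mg/dl / 18.016 = mmol/l), molar-mass based C-peptide
#' factor (nmol/l per ng/ml) and the IFCC/NGSP master equation coefficients
#' for HbA1c (\% = slope x mmol/mol + intercept).
#'
#' @return Named list of constants (\code{glucose_mg_per_mmol},
#'   \code{cpeptide_nmol_per_ng_ml}, \code{hba1c_slope},
#'   \code{hba1c_intercept}).
#' @export
unitConstants <- function() {
  list(
    glucose_mg_per_mmol     = 18.016,
    cpeptide_nmol_per_ng_ml = 0.331,
    hba1c_slope             = 0.09148,
    hba1c_intercept         = 2.152
  )
}

#' Convert HbA1c between IFCC (mmol/mol) and NGSP (%) units
#'
#' Uses the IFCC/NGSP master equation \eqn{\%{} = 0.09148 \times
#' \mathrm{mmol/mol} + 2.152}; the inverse is its exact algebraic inverse,
#' so conversion round-trips exactly.
#'
#' @param value Positive numeric vector of HbA1c values.
#' @param from One of \code{"mmol_per_mol"} or \code{"percent"}.
#' @param constants Override for the master-equation coefficients, see
#'   [unitConstants()].
#'
#' @return data.frame with columns \code{mmol_per_mol} and \code{percent}.
#' @examples
#' convertHbA1c(73.23, "mmol_per_mol")$percent  # 8.8
#' @export
convertHbA1c <- function(value, from = c("mmol_per_mol", "percent"),
                         constants = unitConstants()) {
  from <- match.arg(from)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("HbA1c values must be positive and finite")
  a <- constants$hba1c_slope
  b <- constants$hba1c_intercept
  if (from == "mmol_per_mol") {
    data.frame(mmol_per_mol = value, percent = a * value + b)
  } else {
    if (any(value <= b))
      stop("HbA1c % must exceed the master-equation intercept (", b, ")")
    data.frame(mmol_per_mol = (value - b) / a, percent = value)
  }
}

#' Convert C-peptide between ng/ml and nmol/l
#'
#' Molar-mass based conversion, nmol/l = 0.331 x ng/ml by default. The paper
#' trail for this pipeline reports C-peptide in nmol/l but states HOMA2
#' capping limits in ng/ml, so both directions are needed.
#'
#' @param value Non-negative numeric vector.
#' @param from One of \code{"ng_per_ml"} or \code{"nmol_per_l"}.
#' @param constants See [unitConstants()].
#'
#' @return Numeric vector in the other unit (nmol/l when converting from
#'   ng/ml and vice versa).
#' @examples
#' convertCPeptide(3.5, "ng_per_ml")  # 1.1585 nmol/l
#' @export
convertCPeptide <- function(value, from = c("ng_per_ml", "nmol_per_l"),
                            constants = unitConstants()) {
  from <- match.arg(from)
  if (any(!is.finite(value)) || any(value < 0))
    stop("C-peptide values must be non-negative and finite")
  k <- constants$cpeptide_nmol_per_ng_ml
  if (from == "ng_per_ml") value * k else value / k
}

#' Convert glucose between mg/dl and mmol/l
#'
#' @param value Non-negative numeric vector.
#' @param from One of \code{"mg_per_dl"} or \code{"mmol_per_l"}.
#' @param constants See [unitConstants()].
#'
#' @return Numeric vector in the other unit.
#' @export
convertGlucose <- function(value, from = c("mg_per_dl", "mmol_per_l"),
                           constants = unitConstants()) {
  from <- match.arg(from)
  if (any(!is.finite(value)) || any(value < 0))
    stop("glucose values must be non-negative and finite")
  k <- constants$glucose_mg_per_mmol
  if (from == "mg_per_dl") value / k else value * k
}

# canonical phenotype columns and whether a record is usable without them
.phenoColumns <- function() {
  list(
    mandatory = c("participant_id", "sex", "age_at_diagnosis", "bmi",
                  "hba1c", "fasting_glucose", "fasting_cpeptide"),
    optional  = c("diabetes_duration", "serum_creatinine",
                  "treatment", "coronary_event", "stroke",
                  "macroalbuminuria", "retinopathy_grade", "neuropathy",
                  "egfr")
  )
}

#' Default column map for phenotype CSV ingestion
#'
#' Identity mapping from canonical column names to source headers, with all
#' source units assumed canonical (HbA1c mmol/mol, glucose mmol/l, C-peptide
#' nmol/l, creatinine mg/dl). Override entries to adapt to arbitrary source
#' headers and units.
#'
#' @param ... Named overrides; each is either a source column name or a list
#'   \code{list(col = "HEADER", unit = "percent")}.
#'
#' @return Named list mapping canonical names to \code{list(col, unit)}.
#' @examples
#' defaultColumnMap(hba1c = list(col = "A1C", unit = "percent"))
#' @export
defaultColumnMap <- function(...) {
  cols <- unlist(.phenoColumns(), use.names = FALSE)
  map <- lapply(cols, function(x) list(col = x, unit = NA_character_))
  names(map) <- cols
  dots <- list(...)
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (is.character(v)) v <- list(col = v, unit = NA_character_)
    if (is.null(v$unit)) v$unit <- NA_character_
    map[[nm]] <- v
  }
  map
}

.parseSex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male", "1")] <- "male"
  out[s %in% c("f", "female", "2")] <- "female"
  out
}

.num <- function(x) suppressWarnings(as.numeric(x))

#' Read and harmonise a cohort phenotype table
#'
#' Reads a comma-separated phenotype table (header row mandatory, UTF-8),
#' maps source headers to canonical names via \code{columnMap}, converts
#' units to canonical (HbA1c mmol/mol, glucose mmol/l, C-peptide nmol/l) and
#' validates each row. Ingestion is total: every input row ends up either in
#' the returned records or in the rejects table with a reason, and the counts
#' add up to the number of data rows.
#'
#' Missing complication/treatment fields are kept as \code{NA} ("unknown",
#' not "absent"); downstream prevalence tables use available-data
#' denominators.
#'
#' @param path Path to the CSV file.
#' @param columnMap See [defaultColumnMap()].
#' @param constants Unit-conversion constants, see [unitConstants()].
#'
#' @return List with elements \code{records} (data.frame in canonical
#'   columns/units) and \code{rejects} (data.frame with columns \code{row},
#'   \code{participant_id}, \code{reason}).
#' @export
readCohort <- function(path, columnMap = defaultColumnMap(),
                       constants = unitConstants()) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  spec <- .phenoColumns()

  pull <- function(canon) {
    m <- columnMap[[canon]]
    if (is.null(m)) return(NULL)
    if (!m$col %in% names(raw)) return(NULL)
    raw[[m$col]]
  }
  for (canon in spec$mandatory) {
    m <- columnMap[[canon]]
    if (is.null(m) || !m$col %in% names(raw))
      stop("mandatory column missing from file: ", canon,
           if (!is.null(m)) paste0(" (mapped to '", m$col, "')"))
  }

  n <- nrow(raw)
  unitOf <- function(canon) {
    u <- columnMap[[canon]]$unit
    if (is.null(u)) NA_character_ else u
  }

  rec <- data.frame(
    participant_id   = as.character(pull("participant_id")),
    sex              = .parseSex(pull("sex")),
    age_at_diagnosis = .num(pull("age_at_diagnosis")),
    bmi              = .num(pull("bmi")),
    hba1c            = .num(pull("hba1c")),
    fasting_glucose  = .num(pull("fasting_glucose")),
    fasting_cpeptide = .num(pull("fasting_cpeptide")),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    rec <- rec[0, , drop = FALSE]
  }
  # unit harmonisation on mapped source units
  if (n > 0) {
    if (identical(unitOf("hba1c"), "percent")) {
      pc <- rec$hba1c
      pc[!is.na(pc) & pc <= constants$hba1c_intercept] <- NA  # unphysiological
      rec$hba1c <- (pc - constants$hba1c_intercept) / constants$hba1c_slope
    }
    if (identical(unitOf("fasting_glucose"), "mg_per_dl"))
      rec$fasting_glucose <- rec$fasting_glucose /
        constants$glucose_mg_per_mmol
    if (identical(unitOf("fasting_cpeptide"), "ng_per_ml"))
      rec$fasting_cpeptide <- rec$fasting_cpeptide *
        constants$cpeptide_nmol_per_ng_ml
  }

  for (canon in spec$optional) {
    v <- pull(canon)
    if (is.null(v)) v <- rep(NA, max(n, 0L))
    rec[[canon]] <- switch(canon,
      treatment = {
        t <- tolower(trimws(as.character(v)))
        t[!t %in% c("diet_only", "oha_only", "insulin_only",
                    "oha_plus_insulin")] <- NA
        t
      },
      retinopathy_grade = {
        g <- toupper(trimws(as.character(v)))
        g[g == "NONE"] <- "none"
        g[!g %in% c("none", "NPDR", "PDR")] <- NA
        g
      },
      coronary_event = , stroke = , macroalbuminuria = , neuropathy =
        as.logical(.num(v) > 0 | tolower(as.character(v)) %in%
                     c("true", "yes")),
      .num(v)
    )
  }
  if (identical(unitOf("serum_creatinine"), "umol_per_l"))
    rec$serum_creatinine <- rec$serum_creatinine / 88.42

  # row validation
  reasons <- rep(NA_character_, n)
  clusterNum <- c("age_at_diagnosis", "bmi", "hba1c",
                  "fasting_glucose", "fasting_cpeptide")
  if (n > 0) {
    missFeat <- Reduce(`|`, lapply(clusterNum, function(f) is.na(rec[[f]])))
    reasons[missFeat] <- "missing clustering feature"
    bad <- !missFeat & (rec$age_at_diagnosis <= 0 | rec$bmi <= 0 |
                          rec$hba1c <= 0 | rec$fasting_glucose <= 0 |
                          rec$fasting_cpeptide < 0)
    reasons[bad] <- "non-positive clinical value"
    reasons[is.na(rec$sex)] <- "unrecognised sex"
    reasons[is.na(rec$participant_id) | rec$participant_id == ""] <-
      "missing participant id"
  }

  keep <- is.na(reasons)
  rejects <- data.frame(row = which(!keep),
                        participant_id = rec$participant_id[!keep],
                        reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  stopifnot(nrow(records) + nrow(rejects) == n)
  list(records = records, rejects = rejects)
}

#' Write a rejects table as CSV
#'
#' @param rejects data.frame from [readCohort()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeRejects <- function(rejects, path) {
  utils::write.csv(rejects, path, row.names = FALSE)
  invisible(path)
}

#' Read a CentroidModel from a YAML config
#'
#' The config carries \code{feature_order}, \code{labels}, per-feature
#' \code{scaling} (\code{center}, \code{scale}, optional \code{transform})
#' and one coordinate vector per label under \code{centroids}.
#'
#' @param path YAML file path.
#' @return A [CentroidModel-class] object.
#' @seealso [writeCentroidModel()], [exampleCentroidModel()]
#' @export
readCentroidModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  feats <- unlist(cfg$feature_order)
  labels <- unlist(cfg$labels)
  cent <- do.call(rbind, lapply(labels, function(l)
    unlist(cfg$centroids[[l]])))
  transform <- if (is.null(cfg$scaling$transform))
    rep("none", length(feats)) else unlist(cfg$scaling$transform)
  CentroidModel(cent,
                center = unlist(cfg$scaling$center),
                scale = unlist(cfg$scaling$scale),
                labels = labels, featureOrder = feats,
                transform = transform)
}

#' Write a CentroidModel to a YAML config
#'
#' @param model A [CentroidModel-class].
#' @param path Output YAML path.
#' @return Invisibly, the path.
#' @export
writeCentroidModel <- function(model, path) {
  cent <- centroidCoords(model)
  yaml::write_yaml(list(
    feature_order = as.list(featureOrder(model)),
    labels = as.list(centroidLabels(model)),
    scaling = list(center = as.list(unname(model@center)),
                   scale = as.list(unname(model@scale)),
                   transform = as.list(unname(model@transform))),
    centroids = stats::setNames(
      lapply(seq_len(nrow(cent)), function(i) as.list(unname(cent[i, ]))),
      centroidLabels(model))
  ), path)
  invisible(path)
}

#' Read a GRSConfig from a YAML config
#'
#' @param path YAML file path.
#' @return A [GRSConfig-class] object.
#' @seealso [exampleGRSConfig()]
#' @export
readGRSConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  snps <- do.call(rbind, lapply(cfg$snps, function(s)
    data.frame(rsid = s$rsid, effect_allele = s$effect_allele,
               other_allele = s$other_allele, weight = s$weight,
               eaf = s$eaf, stringsAsFactors = FALSE)))
  hw <- matrix(unlist(cfg$haplotype$weights), 3, 3, byrow = TRUE)
  cut <- numeric()
  if (!is.null(cfg$reference_percentiles)) {
    cut <- vapply(cfg$reference_percentiles, function(p) p$cutoff, 0)
    names(cut) <- vapply(cfg$reference_percentiles,
                         function(p) as.character(p$percentile), "")
  }
  hea <- if (is.null(cfg$haplotype$effect_alleles)) c("A", "A")
    else unlist(cfg$haplotype$effect_alleles)
  GRSConfig(snps, haplotypeA = cfg$haplotype$snp_a,
            haplotypeB = cfg$haplotype$snp_b,
            haplotypeWeights = hw, haplotypeEffectAlleles = hea,
            referenceCutoffs = cut)
}
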