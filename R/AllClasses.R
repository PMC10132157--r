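#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Canonical vocabulary shared across the package ---------------------------

.ANATOMIC_SITES <- c("liver", "lymph_node", "bone_vertebral",
                     "bone_nonvertebral", "adrenal", "prostate",
                     "lung", "other")

.SUBTYPES <- c("AR+/NE-", "AR+/NE+", "AR-/NE+", "AR-/NE-")

.PSMA_STATUS <- c("low_negative", "positive")

.PATTERNS <- c("uniform_low_negative", "heterogeneous", "uniform_high")

.COHORT_COLUMNS <- c("patient_id", "site_id", "anatomic_site", "marker",
                     "core_id", "pct_level0", "pct_level1", "pct_level2",
                     "h_score", "death_year")

## IHCCohort ------------------------------------------------------------------

#' IHCCohort: core-level immunohistochemistry measurements
#'
#' An `IHCCohort` stores one row per tissue core per marker in long format:
#' the hierarchy patient -> metastatic site -> core is encoded by the
#' `patient_id` and `site_id` columns. H-scores use the 3-level convention
#' (intensity 0/1/2 weighted by the percentage of cells at each level),
#' giving a 0--200 range. Missing H-scores are `NA` and are excluded from
#' all downstream denominators, never imputed.
#'
#' @slot cores A [S4Vectors::DataFrame] with columns `patient_id`,
#'   `site_id`, `anatomic_site`, `marker`, `core_id`, `h_score` and
#'   optionally `pct_level0..2` and `death_year`.
#'
#' @seealso [readCohortTable()], [siteHScores()], [classifyPatientPattern()]
#' @export
setClass("IHCCohort", representation(cores = "DataFrame"))

setValidity("IHCCohort", function(object) {
  df <- object@cores
  need <- c("patient_id", "site_id", "anatomic_site", "marker", "core_id",
            "h_score")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    return(paste0("missing core columns: ", paste(missing, collapse = ", ")))
  h <- df$h_score
  if (!is.numeric(h))
    return("h_score must be numeric")
  bad <- !is.na(h) & (h < 0 | h > 200)
  if (any(bad))
    return(paste0("h_score outside [0, 200] in rows: ",
                  paste(utils::head(which(bad), 5), collapse = ", ")))
  key <- paste(df$patient_id, df$site_id, df$marker, df$core_id, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (patient, site, marker, core) rows")
  TRUE
})

#' Construct an IHCCohort from a core-level table
#'
#' @param cores data.frame or DataFrame, one row per core x marker, with
#'   columns `patient_id`, `site_id`, `anatomic_site`, `marker`, `core_id`,
#'   `h_score` (0--200 or `NA`), and optionally staining-level percentages
#'   and `death_year`.
#' @return An [IHCCohort-class] object.
#' @examples
#' df <- data.frame(patient_id = "P1", site_id = c("S1", "S1"),
#'                  anatomic_site = "liver", marker = "PSMA",
#'                  core_id = c("a", "b"), h_score = c(130, 150))
#' IHCCohort(df)
#' @export
IHCCohort <- function(cores) {
  df <- DataFrame(cores)
  for (col in c("patient_id", "site_id", "anatomic_site", "marker", "core_id"))
    if (col %in% colnames(df)) df[[col]] <- as.character(df[[col]])
  if (!"h_score" %in% colnames(df)) df$h_score <- NA_real_
  df$h_score <- as.numeric(df$h_score)
  new("IHCCohort", cores = df)
}

## ExpressionCohort ------------------------------------------------------------

#' ExpressionCohort: an FPKM expression matrix with sample labels
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `fpkm` assay (genes x samples, nonnegative) and per-sample metadata
#' columns `subtype` (one of the four AR/NE molecular subtype labels, or
#' `NA`) and `psma_group` (`"low"`/`"high"`, or `NA` before grouping).
#'
#' @slot cohortName Single string naming the data set; consensus calls are
#'   reported per cohort name.
#' @seealso [readExpressionMatrix()], [splitByMean()],
#'   [differentialExpression()]
#' @export
setClass("ExpressionCohort",
         contains = "SummarizedExperiment",
         representation(cohortName = "character"))

setValidity("ExpressionCohort", function(object) {
  if (length(object@cohortName) != 1L)
    return("cohortName must be a single string")
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'fpkm' is required")
  m <- assay(object, "fpkm")
  if (any(m < 0, na.rm = TRUE))
    return("FPKM values must be nonnegative")
  if (anyDuplicated(rownames(m)))
    return(paste0("duplicate gene symbols: ",
                  paste(unique(rownames(m)[duplicated(rownames(m))]),
                        collapse = ", ")))
  cd <- colData(object)
  if (!all(c("subtype", "psma_group") %in% colnames(cd)))
    return("colData must contain 'subtype' and 'psma_group'")
  TRUE
})

#' Construct an ExpressionCohort
#'
#' @param fpkm Numeric matrix, genes x samples, nonnegative FPKM with gene
#'   symbols as rownames and sample IDs as colnames.
#' @param sampleMeta Optional data.frame keyed by `sample_id` with columns
#'   `subtype` and optionally `psma_group`; samples absent from the metadata
#'   carry `NA` labels (a warning is emitted).
#' @param cohortName Single string identifying the data set.
#' @return An [ExpressionCohort-class].
#' @export
ExpressionCohort <- function(fpkm, sampleMeta = NULL, cohortName = "cohort") {
  fpkm <- as.matrix(fpkm)
  samples <- colnames(fpkm)
  cd <- DataFrame(subtype = rep(NA_character_, ncol(fpkm)),
                  psma_group = rep(NA_character_, ncol(fpkm)),
                  row.names = samples)
  if (!is.null(sampleMeta)) {
    sampleMeta <- as.data.frame(sampleMeta)
    if (!"sample_id" %in% colnames(sampleMeta))
      stop("sampleMeta requires a 'sample_id' column")
    idx <- match(samples, sampleMeta$sample_id)
    if (anyNA(idx))
      warning(sum(is.na(idx)), " sample(s) absent from metadata; ",
              "labels left unassigned: ",
              paste(utils::head(samples[is.na(idx)], 5), collapse = ", "))
    if ("subtype" %in% colnames(sampleMeta))
      cd$subtype <- as.character(sampleMeta$subtype)[idx]
    if ("psma_group" %in% colnames(sampleMeta))
      cd$psma_group <- as.character(sampleMeta$psma_group)[idx]
  }
  se <- SummarizedExperiment(assays = list(fpkm = fpkm), colData = cd)
  new("ExpressionCohort", se, cohortName = as.character(cohortName))
}

## HeterogeneitySummary ---------------------------------------------------------

#' HeterogeneitySummary: a pair-difference heterogeneity estimate with BCa CI
#'
#' Point estimate of the probability that a randomly chosen pair of units'
#' members (sites within a patient, or cores within a site) carry different
#' labels, with bias-corrected and accelerated bootstrap confidence limits.
#'
#' @slot level `"intertumoral"` (across sites within patients) or
#'   `"intratumoral"` (across cores within sites).
#' @slot labeling `"psma_status"` or `"subtype"`.
#' @slot estimate,ciLow,ciHigh Probabilities in `[0, 1]`.
#' @slot nPairs,nBoot,seed,nUnitsUsed Run parameters; `nUnitsUsed` counts
#'   units with at least two labelled members (units with fewer are
#'   excluded).
#' @slot unitD Named numeric vector of per-unit closed-form pair-difference
#'   probabilities.
#' @export
setClass("HeterogeneitySummary",
         representation(level = "character", labeling = "character",
                        estimate = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", nPairs = "integer",
                        nBoot = "integer", alpha = "numeric",
                        seed = "integer", nUnitsUsed = "integer",
                        unitD = "numeric"))

setValidity("HeterogeneitySummary", function(object) {
  e <- object@estimate
  if (!is.na(e) && (e < 0 || e > 1)) return("estimate outside [0, 1]")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("ciLow exceeds ciHigh")
  TRUE
})

## show methods ----------------------------------------------------------------

setMethod("show", "IHCCohort", function(object) {
  df <- object@cores
  cat("IHCCohort:", length(unique(df$patient_id)), "patients,",
      length(unique(paste(df$patient_id, df$site_id))), "sites,",
      nrow(df), "core measurements\n")
  cat("  markers:", paste(sort(unique(df$marker)), collapse = ", "), "\n")
})

setMethod("show", "ExpressionCohort", function(object) {
  cat("ExpressionCohort '", object@cohortName, "': ", nrow(object),
      " genes x ", ncol(object), " samples\n", sep = "")
  gr <- table(colData(object)$psma_group, useNA = "ifany")
  cat("  psma_group:", paste(names(gr), gr, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "HeterogeneitySummary", function(object) {
  cat(sprintf("%s heterogeneity (%s): %.3f (%d%% CI %.3f-%.3f)\n",
              object@level, object@labeling, object@estimate,
              round(100 * (1 - object@alpha)), object@ciLow, object@ciHigh))
  cat(sprintf("  n_units_used=%d, n_pairs=%d, n_boot=%d, seed=%d\n",
              object@nUnitsUsed, object@nPairs, object@nBoot, object@seed))
})

## accessors -------------------------------------------------------------------

#' Core-level measurement table of an IHCCohort
#' @param x An [IHCCohort-class].
#' @return A [S4Vectors::DataFrame], one row per core x marker.
#' @export
coreData <- function(x) {
  stopifnot(is(x, "IHCCohort"))
  x@cores
}

#' Cohort name of an ExpressionCohort
#' @param x An [ExpressionCohort-class].
#' @return Single string.
#' @export
cohortName <- function(x) {
  stopifnot(is(x, "ExpressionCohort"))
  x@cohortName
}

#' FPKM assay of an ExpressionCohort
#' @param x An [ExpressionCohort-class].
#' @return Numeric matrix, genes x samples.
#' @export
fpkm <- function(x) {
  stopifnot(is(x, "ExpressionCohort"))
  assay(x, "fpkm")
}

#' Heterogeneity estimate and confidence limits
#' @param x A [HeterogeneitySummary-class].
#' @return Named numeric vector `estimate`, `ci_low`, `ci_high`.
#' @export
hetEstimate <- function(x) {
  stopifnot(is(x, "HeterogeneitySummary"))
  c(estimate = x@estimate, ci_low = x@ciLow, ci_high = x@ciHigh)
}

#' Per-unit pair-difference probabilities backing a heterogeneity summary
#' @param x A [HeterogeneitySummary-class].
#' @return Named numeric vector (one entry per eligible unit).
#' @export
unitD <- function(x) {
  stopifnot(is(x, "HeterogeneitySummary"))
  x@unitD
}
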