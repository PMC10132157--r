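## Readers and writers for the package's plain-text interchange formats.
## All tables are UTF-8 TSV; genomic coordinates are 1-based inclusive
## throughout, and any 0-based dialect is converted at the reader boundary.

#' Read a long-format cohort table
#'
#' One row per tissue core per marker. H-scores may be supplied directly in
#' an `h_score` column, or as staining-level percentages `pct_level0`,
#' `pct_level1`, `pct_level2` (which must sum to 100 within +/- 0.5), in
#' which case the 3-level H-score is derived. Duplicate
#' (patient, site, marker, core) rows are rejected; duplicate-core
#' averaging happens later, in [siteHScores()].
#'
#' @param path Path to a TSV file with a header row.
#' @param config Optional named character vector mapping the canonical
#'   column names (`patient_id`, `site_id`, ...) to the file's column
#'   names, for tables using different headers.
#' @param tol Tolerance on the percentage sum (default 0.5).
#' @return An [IHCCohort-class].
#' @export
readCohortTable <- function(path, config = NULL, tol = 0.5) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(config)) {
    for (canon in names(config)) {
      src <- config[[canon]]
      if (src %in% colnames(df)) colnames(df)[colnames(df) == src] <- canon
    }
  }
  required <- c("patient_id", "site_id", "anatomic_site", "marker")
  for (col in required)
    if (!col %in% colnames(df))
      stop("cohort table schema error: missing required column '", col, "'")
  pctCols <- c("pct_level0", "pct_level1", "pct_level2")
  hasPct <- all(pctCols %in% colnames(df))
  hasH <- "h_score" %in% colnames(df)
  if (!hasPct && !hasH)
    stop("cohort table schema error: need either columns ",
         paste(pctCols, collapse = ", "), " or column 'h_score'")
  if (!"core_id" %in% colnames(df)) df$core_id <- "core1"
  if (nrow(df) == 0L) {
    df$h_score <- numeric(0)
    return(IHCCohort(df))
  }
  if (hasPct) {
    for (col in pctCols) df[[col]] <- as.numeric(df[[col]])
    supplied <- !is.na(df$pct_level0) | !is.na(df$pct_level1) |
      !is.na(df$pct_level2)
    if (any(supplied)) {
      s <- df$pct_level0 + df$pct_level1 + df$pct_level2
      bad <- supplied & (is.na(s) | abs(s - 100) > tol)
      if (any(bad))
        stop("staining-level percentages do not sum to 100 +/- ", tol,
             " in row(s): ", paste(utils::head(which(bad), 5), collapse = ", "))
    }
    derived <- computeHScore(df$pct_level0, df$pct_level1, df$pct_level2,
                             tol = tol)
    if (hasH) {
      df$h_score <- as.numeric(df$h_score)
      df$h_score[is.na(df$h_score)] <- derived[is.na(df$h_score)]
    } else df$h_score <- derived
  } else {
    df$h_score <- as.numeric(df$h_score)
  }
  key <- paste(df$patient_id, df$site_id, df$marker, df$core_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (patient, site, marker, core) rows at: ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  IHCCohort(df)
}

#' Write a cohort table
#'
#' Inverse of [readCohortTable()]: the written file reads back to the same
#' cohort up to row order and floating-point formatting.
#'
#' @param cohort An [IHCCohort-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  df <- as.data.frame(coreData(cohort))
  keep <- intersect(.COHORT_COLUMNS, colnames(df))
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FPKM expression matrix with sample metadata
#'
#' @param path TSV whose first column holds gene symbols and remaining
#'   columns one sample each (nonnegative FPKM).
#' @param metaPath Optional metadata TSV with columns `sample_id`,
#'   `subtype`, and optionally `psma_group`. Samples missing from the
#'   metadata load with unassigned labels and a warning.
#' @param cohortName Data-set name attached to the cohort.
#' @return An [ExpressionCohort-class].
#' @export
readExpressionMatrix <- function(path, metaPath = NULL,
                                 cohortName = basename(path)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE))
    stop("negative FPKM values in expression matrix")
  rownames(m) <- genes
  meta <- if (!is.null(metaPath))
    utils::read.delim(metaPath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  else NULL
  ExpressionCohort(m, sampleMeta = meta, cohortName = cohortName)
}

#' Read a gene list (one symbol per line)
#'
#' Lines starting with `#` (and trailing `#` comments) are ignored, as are
#' blank lines.
#'
#' @param path Plain-text file path.
#' @return Character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Parse a genomic region string
#'
#' Accepts `"chrom:start-end"` with optional thousands separators
#' (commas) in the coordinates. Coordinates are 1-based inclusive.
#'
#' @param text Region string, e.g. `"chr11:49228686-49228864"`.
#' @return A length-1 [GenomicRanges::GRanges].
#' @examples
#' parseRegion("chr11:49228686-49228864")  # 179 bp FOLH1 intron-2 amplicon
#' @export
parseRegion <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region '", text, "'; expected 'chrom:start-end'")
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (is.na(start) || is.na(end))
    stop("non-numeric coordinates in region '", text, "'")
  if (start > end)
    stop("region start exceeds end in '", text, "'")
  GenomicRanges::GRanges(m[2], IRanges::IRanges(start = start, end = end))
}
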