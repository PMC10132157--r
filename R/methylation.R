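## COMPARE-MS methylation indices from qPCR Ct values, Bismark-dialect
## coverage I/O, region-level methylation summaries, and the
## methylation--expression association.

#' COMPARE-MS methylation index from qPCR Ct values
#'
#' Normalizes a sample's Ct against a fully methylated positive control
#' under the standard doubling model (amplification efficiency 1 per
#' cycle): `MI = 100 * 2^(ct_control - ct_sample) * efficiency-adjusted`,
#' clipped to `[0, 100]`. An undetermined sample Ct (NA) means no
#' amplification of methylated template and yields MI = 0 with a flag.
#'
#' @param ctSample Numeric vector of sample Ct values (cycles, > 0; `NA`
#'   for undetermined).
#' @param ctControl Fully methylated control Ct values (recycled; must be
#'   determined).
#' @param efficiency Per-cycle amplification factor (default 2, the
#'   doubling model).
#' @return data.frame: `mi` (percent, 0--100), `clipped` (TRUE where the
#'   raw index exceeded 100), `undetermined` (TRUE where `ctSample` was
#'   `NA`).
#' @examples
#' methylationIndex(23, 22)$mi  # 50
#' @export
methylationIndex <- function(ctSample, ctControl, efficiency = 2) {
  ctSample <- as.numeric(ctSample); ctControl <- as.numeric(ctControl)
  n <- max(length(ctSample), length(ctControl))
  ctSample <- rep_len(ctSample, n); ctControl <- rep_len(ctControl, n)
  if (anyNA(ctControl)) stop("undetermined control Ct")
  if (any(ctControl <= 0) || any(ctSample <= 0, na.rm = TRUE))
    stop("Ct values must be positive cycles")
  raw <- 100 * efficiency^(ctControl - ctSample)
  undet <- is.na(ctSample)
  raw[undet] <- 0
  data.frame(mi = pmin(raw, 100), clipped = !undet & raw > 100,
             undetermined = undet)
}

#' Read a Bismark-dialect coverage file
#'
#' Tab-separated columns: chrom, start, end, percent methylated, count
#' methylated, count unmethylated; positions 1-based (use
#' `zeroBased = TRUE` for bedGraph-style input, converted at the
#' boundary). The file's percentage is checked against the counts (within
#' 0.1) and then recomputed from the counts.
#'
#' @param path Coverage file path (`.cov` dialect; plain text).
#' @param zeroBased Set `TRUE` for 0-based half-open start coordinates.
#' @return A [GenomicRanges::GRanges] with metadata columns `methylated`,
#'   `unmethylated` and `fraction` (`NA` at zero coverage; zero-coverage
#'   positions are retained but excluded from summaries).
#' @export
readBismarkCoverage <- function(path, zeroBased = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges(methylated = integer(0),
                                  unmethylated = integer(0),
                                  fraction = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad))
    stop("malformed coverage line ", bad[1], ": expected 6 tab-separated ",
         "fields, got ", lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  meth <- suppressWarnings(as.numeric(m[, 5]))
  unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start) | is.na(end) | is.na(pct) | is.na(meth) |
                 is.na(unmeth))
  if (length(bad))
    stop("malformed coverage line ", bad[1], ": non-numeric field")
  bad <- which(meth < 0 | unmeth < 0)
  if (length(bad))
    stop("negative count on coverage line ", bad[1])
  cov <- meth + unmeth
  frac <- ifelse(cov > 0, meth / cov, NA_real_)
  bad <- which(cov > 0 & abs(pct - 100 * frac) > 0.1)
  if (length(bad))
    stop("percent inconsistent with counts on coverage line ", bad[1],
         " (stated ", pct[bad[1]], ", counts give ",
         round(100 * frac[bad[1]], 4), ")")
  if (zeroBased) start <- start + 1
  GenomicRanges::GRanges(m[, 1], IRanges::IRanges(start = start, end = end),
                         methylated = as.integer(meth),
                         unmethylated = as.integer(unmeth),
                         fraction = frac)
}

#' Write CpG calls in Bismark coverage dialect
#'
#' @param calls A `GRanges` with `methylated`/`unmethylated` metadata
#'   columns (as from [readBismarkCoverage()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBismarkCoverage <- function(calls, path) {
  meth <- calls$methylated; unmeth <- calls$unmethylated
  cov <- meth + unmeth
  pct <- ifelse(cov > 0, round(100 * meth / cov, 4), 0)
  df <- data.frame(as.character(GenomicRanges::seqnames(calls)),
                   GenomicRanges::start(calls), GenomicRanges::end(calls),
                   pct, meth, unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coverage-weighted region methylation
#'
#' Summarizes CpG calls over a genomic region (e.g. a differentially
#' methylated region) as `sum(methylated) / sum(methylated + unmethylated)`
#' over CpGs inside the region with coverage at or above `minCoverage`.
#'
#' @param calls A `GRanges` of CpG calls (see [readBismarkCoverage()]).
#' @param region A length-1 `GRanges` or a region string accepted by
#'   [parseRegion()].
#' @param minCoverage Minimum per-CpG coverage (default 5).
#' @return List: `fraction` (in `[0, 1]`, `NA` with a warning when no CpG
#'   qualifies) and `n_cpgs_used`.
#' @export
regionMethylation <- function(calls, region, minCoverage = 5) {
  if (is.character(region)) region <- parseRegion(region)
  hits <- IRanges::overlapsAny(calls, region)
  sub <- calls[hits]
  cov <- sub$methylated + sub$unmethylated
  sub <- sub[cov >= minCoverage]
  if (length(sub) == 0L) {
    warning("no CpG in region with coverage >= ", minCoverage)
    return(list(fraction = NA_real_, n_cpgs_used = 0L))
  }
  list(fraction = sum(sub$methylated) /
         sum(sub$methylated + sub$unmethylated),
       n_cpgs_used = length(sub))
}

#' Methylation--expression association
#'
#' Linear regression of expression on a methylation measure (COMPARE-MS
#' index or region methylation fraction), sharing the OLS/Pearson contract
#' of [regressProteinMrna()].
#'
#' @param methylation Per-sample methylation values (predictor).
#' @param expr Per-sample log2 FPKM (response).
#' @return As [regressProteinMrna()].
#' @export
methylationExpressionAssociation <- function(methylation, expr) {
  regressProteinMrna(methylation, expr)
}
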