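## H-score computation, PSMA status, AR/NE subtype calls and per-patient
## expression-pattern classification.

#' Compute a 3-level H-score
#'
#' H-score = 0 x pct_level0 + 1 x pct_level1 + 2 x pct_level2, where the
#' three percentages are the fractions of cells at chromogen intensity
#' levels 0 (none), 1 (faint) and 2 (prominent). The score ranges 0--200.
#'
#' @param pctLevel0,pctLevel1,pctLevel2 Numeric vectors of percentages in
#'   `[0, 100]`; each triple must sum to 100 within `tol`.
#' @param tol Tolerance on the percentage sum (default 0.5).
#' @return Numeric vector of H-scores in `[0, 200]`; `NA` where all three
#'   percentages are `NA`.
#' @examples
#' computeHScore(20, 30, 50)  # 130
#' @export
computeHScore <- function(pctLevel0, pctLevel1, pctLevel2, tol = 0.5) {
  p0 <- as.numeric(pctLevel0); p1 <- as.numeric(pctLevel1)
  p2 <- as.numeric(pctLevel2)
  n <- max(length(p0), length(p1), length(p2))
  p0 <- rep_len(p0, n); p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  out <- rep(NA_real_, n)
  supplied <- !(is.na(p0) & is.na(p1) & is.na(p2))
  if (!any(supplied)) return(out)
  s <- p0 + p1 + p2
  if (any(supplied & (is.na(s) | p0 < 0 | p1 < 0 | p2 < 0 |
                      abs(s - 100) > tol)))
    stop("staining-level percentages must be nonnegative and sum to 100 +/- ",
         tol)
  out[supplied] <- (p1 + 2 * p2)[supplied]
  out
}

#' Average duplicate-core H-scores
#'
#' Site-level H-scores are the arithmetic mean of that site's core scores;
#' missing cores are excluded from the denominator.
#'
#' @param hScores Numeric vector of core H-scores (may contain `NA`).
#' @return Mean of the non-missing scores; `NA` with a warning if all are
#'   missing.
#' @export
aggregateCores <- function(hScores) {
  x <- hScores[!is.na(hScores)]
  if (length(x) == 0L) {
    warning("all core H-scores missing; site score is NA")
    return(NA_real_)
  }
  mean(x)
}

#' Classify PSMA status from an H-score
#'
#' Sites with H-score at or below the cutoff (default 20) are
#' low/negative; strictly above is positive. Ties at the cutoff are
#' low/negative.
#'
#' @param hScore Numeric vector of H-scores in `[0, 200]`.
#' @param cutoff Low/negative threshold (default 20).
#' @return Character vector, `"low_negative"` or `"positive"`, `NA` where
#'   the score is missing.
#' @export
classifyPsmaStatus <- function(hScore, cutoff = 20) {
  ifelse(is.na(hScore), NA_character_,
         ifelse(hScore <= cutoff, "low_negative", "positive"))
}

#' Thresholds for AR/NE molecular subtype calls
#'
#' The four mCRPC subtypes are defined by positivity on an AR-signaling
#' axis and a neuroendocrine axis. An axis is positive when (per `rule`)
#' any or all of its markers have H-score strictly above the axis cutoff.
#' The defaults mirror the PSMA low/negative cutoff of 20 and are fully
#' configurable because the source classification's exact IHC thresholds
#' are not standardised.
#'
#' @param arCutoff,neCutoff Axis cutoffs on the 0--200 H-score scale.
#' @param arMarkers,neMarkers Marker symbols per axis.
#' @param rule `"any_marker"` (default) or `"all_markers"`.
#' @return A list of class `subtypeThresholds`.
#' @export
subtypeThresholds <- function(arCutoff = 20, neCutoff = 20,
                              arMarkers = c("AR", "NKX3.1"),
                              neMarkers = c("SYP", "INSM1"),
                              rule = c("any_marker", "all_markers")) {
  rule <- match.arg(rule)
  stopifnot(arCutoff >= 0, arCutoff <= 200, neCutoff >= 0, neCutoff <= 200)
  structure(list(arCutoff = arCutoff, neCutoff = neCutoff,
                 arMarkers = arMarkers, neMarkers = neMarkers, rule = rule),
            class = "subtypeThresholds")
}

.axisPositive <- function(scores, markers, cutoff, rule) {
  x <- scores[names(scores) %in% markers]
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  if (rule == "any_marker") any(x > cutoff) else all(x > cutoff)
}

#' Call the AR/NE subtype of one site from marker H-scores
#'
#' @param markerScores Named numeric vector of site-level (duplicate-core
#'   averaged) H-scores, names are marker symbols.
#' @param thresholds A [subtypeThresholds()] object.
#' @return One of `"AR+/NE-"`, `"AR+/NE+"`, `"AR-/NE+"`, `"AR-/NE-"`, or
#'   `NA` (with a warning) when an axis has no measured marker.
#' @examples
#' callSubtype(c(AR = 150, NKX3.1 = 100, SYP = 0, INSM1 = 0))  # "AR+/NE-"
#' @export
callSubtype <- function(markerScores, thresholds = subtypeThresholds()) {
  ar <- .axisPositive(markerScores, thresholds$arMarkers,
                      thresholds$arCutoff, thresholds$rule)
  ne <- .axisPositive(markerScores, thresholds$neMarkers,
                      thresholds$neCutoff, thresholds$rule)
  if (is.na(ar) || is.na(ne)) {
    warning("no measured marker on the AR and/or NE axis; subtype unassigned")
    return(NA_character_)
  }
  paste0("AR", if (ar) "+" else "-", "/NE", if (ne) "+" else "-")
}

#' Site-level H-scores (duplicate-core averages)
#'
#' @param cohort An [IHCCohort-class].
#' @param marker Marker symbol (default `"PSMA"`).
#' @return data.frame with one row per site: `patient_id`, `site_id`,
#'   `anatomic_site`, `h_score` (mean of non-missing core scores, `NA` if
#'   none), and `death_year` when present.
#' @export
siteHScores <- function(cohort, marker = "PSMA") {
  df <- as.data.frame(coreData(cohort))
  df <- df[df$marker == marker, , drop = FALSE]
  key <- paste(df$patient_id, df$site_id, sep = "\r")
  idx <- !duplicated(key)
  out <- df[idx, intersect(c("patient_id", "site_id", "anatomic_site",
                             "death_year"), colnames(df)), drop = FALSE]
  means <- vapply(split(df$h_score, key), function(h) {
    h <- h[!is.na(h)]
    if (length(h)) mean(h) else NA_real_
  }, numeric(1))
  out$h_score <- unname(means[key[idx]])
  rownames(out) <- NULL
  out
}

#' Site-level subtype calls for a whole cohort
#'
#' @param cohort An [IHCCohort-class] whose table measures at least one
#'   AR-axis and one NE-axis marker per site.
#' @param thresholds A [subtypeThresholds()] object.
#' @return data.frame `patient_id`, `site_id`, `subtype` (`NA` where an
#'   axis is unmeasured).
#' @export
siteSubtypes <- function(cohort, thresholds = subtypeThresholds()) {
  df <- as.data.frame(coreData(cohort))
  panel <- c(thresholds$arMarkers, thresholds$neMarkers)
  df <- df[df$marker %in% panel, , drop = FALSE]
  key <- paste(df$patient_id, df$site_id, sep = "\r")
  groups <- split(df, key)
  calls <- vapply(groups, function(g) {
    scores <- vapply(split(g$h_score, g$marker), function(h) {
      h <- h[!is.na(h)]
      if (length(h)) mean(h) else NA_real_
    }, numeric(1))
    suppressWarnings(callSubtype(scores, thresholds))
  }, character(1))
  first <- vapply(groups, function(g)
    c(g$patient_id[1], g$site_id[1]), character(2))
  data.frame(patient_id = first[1, ], site_id = first[2, ],
             subtype = unname(calls), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify each patient's PSMA expression pattern
#'
#' Using site-level (core-averaged) H-scores: `uniform_low_negative` when
#' every scored site is at or below the cutoff, `uniform_high` when every
#' scored site is above it, `heterogeneous` otherwise (which requires at
#' least two sites). Single-site patients are retained and can only be one
#' of the two uniform classes.
#'
#' @param cohort An [IHCCohort-class].
#' @param cutoff Low/negative H-score cutoff (default 20).
#' @param marker Marker symbol (default `"PSMA"`).
#' @return data.frame with one row per patient with at least one scored
#'   site: `patient_id`, `pattern`, `n_sites`, `n_negative_sites`.
#' @export
classifyPatientPattern <- function(cohort, cutoff = 20, marker = "PSMA") {
  sites <- siteHScores(cohort, marker)
  sites <- sites[!is.na(sites$h_score), , drop = FALSE]
  groups <- split(sites$h_score, sites$patient_id)
  if (length(groups) == 0L)
    return(data.frame(patient_id = character(0), pattern = character(0),
                      n_sites = integer(0), n_negative_sites = integer(0)))
  res <- t(vapply(groups, function(h) {
    c(n = length(h), neg = sum(h <= cutoff))
  }, numeric(2)))
  pattern <- ifelse(res[, "neg"] == res[, "n"], "uniform_low_negative",
                    ifelse(res[, "neg"] == 0, "uniform_high",
                           "heterogeneous"))
  data.frame(patient_id = names(groups), pattern = pattern,
             n_sites = as.integer(res[, "n"]),
             n_negative_sites = as.integer(res[, "neg"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram of PSMA-negative metastatic sites per patient
#'
#' Counts, per patient, the metastatic sites with marker H-score at or
#' below the cutoff and bins patients at 0, 1, 2, 3, 4 and >= 5 negative
#' sites.
#'
#' @inheritParams classifyPatientPattern
#' @return Named integer vector over bins `"0" ... "4", ">=5"`; the bin
#'   counts sum to the number of classifiable patients.
#' @export
countNegativeSites <- function(cohort, cutoff = 20, marker = "PSMA") {
  pat <- classifyPatientPattern(cohort, cutoff = cutoff, marker = marker)
  bins <- c("0", "1", "2", "3", "4", ">=5")
  out <- stats::setNames(integer(length(bins)), bins)
  if (nrow(pat) == 0L) return(out)
  b <- ifelse(pat$n_negative_sites >= 5, ">=5",
              as.character(pat$n_negative_sites))
  tab <- table(factor(b, levels = bins))
  out[] <- as.integer(tab)
  out
}

#' Compare site-level H-scores across anatomic sites
#'
#' Kruskal--Wallis omnibus test across anatomic-site groups plus all
#' pairwise two-sided Wilcoxon rank-sum tests with Benjamini--Hochberg
#' adjustment. Groups with fewer than two scored sites are excluded with a
#' warning.
#'
#' @param cohort An [IHCCohort-class].
#' @param marker Marker symbol (default `"PSMA"`).
#' @param subtype Optional subtype label (e.g. `"AR+/NE-"`): restrict to
#'   sites called that subtype (requires the axis markers in the table).
#' @param thresholds A [subtypeThresholds()] used when `subtype` is given.
#' @param cutoff Unused placeholder for API symmetry.
#' @return List with `omnibus` (Kruskal--Wallis statistic, df, p),
#'   `pairwise` (data.frame group1, group2, p_value, fdr) and
#'   `group_stats` (n, mean, min, max per anatomic site).
#' @export
compareSiteHScores <- function(cohort, marker = "PSMA", subtype = NULL,
                               thresholds = subtypeThresholds(),
                               cutoff = 20) {
  sites <- siteHScores(cohort, marker)
  sites <- sites[!is.na(sites$h_score), , drop = FALSE]
  if (!is.null(subtype)) {
    st <- siteSubtypes(cohort, thresholds)
    key <- paste(st$patient_id, st$site_id, sep = "\r")
    skey <- paste(sites$patient_id, sites$site_id, sep = "\r")
    sites <- sites[st$subtype[match(skey, key)] %in% subtype, , drop = FALSE]
  }
  groups <- split(sites$h_score, sites$anatomic_site)
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    warning("excluding anatomic-site group(s) with n < 2: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2L]
  }
  if (length(groups) < 2L)
    stop("need at least 2 anatomic-site groups with >= 2 observations")
  kw <- stats::kruskal.test(groups)
  combos <- utils::combn(names(groups), 2)
  pw <- apply(combos, 2, function(g) {
    suppressWarnings(
      stats::wilcox.test(groups[[g[1]]], groups[[g[2]]],
                         alternative = "two.sided", exact = FALSE)$p.value)
  })
  pairwise <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                         p_value = pw, fdr = bhAdjust(pw),
                         stringsAsFactors = FALSE)
  stats <- data.frame(
    anatomic_site = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pairwise, group_stats = stats)
}
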