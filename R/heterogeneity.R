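## Two-level heterogeneity quantification: the exact hypergeometric
## pair-difference probability per unit (patient or metastatic site),
## Monte Carlo pair resampling across units, and cluster-bootstrap BCa
## confidence limits.

#' Tabulate category labels into counts
#'
#' @param labels Character (or factor) vector of labels; `NA` dropped.
#' @return Named integer vector of counts.
#' @export
countLabels <- function(labels) {
  labels <- labels[!is.na(labels)]
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

#' Hypergeometric pair-difference probability
#'
#' The exact probability that two members drawn without replacement from a
#' finite labelled set carry different labels:
#' `D = 1 - sum_k n_k (n_k - 1) / (N (N - 1))`. This is the heterogeneity
#' index applied to a patient's site statuses (intertumoral) or a site's
#' core statuses (intratumoral). Related to the Gini--Simpson index by
#' `D = N/(N-1) * (1 - sum p_k^2)`.
#'
#' @param counts Named or unnamed nonnegative integer vector of category
#'   counts.
#' @return Probability in `[0, 1]`; `NA` with a warning when fewer than two
#'   members are present.
#' @examples
#' pairDifferenceProbability(c(A = 2, B = 2))  # 4/6
#' pairDifferenceProbability(c(A = 5, B = 2))  # 10/21
#' @export
pairDifferenceProbability <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0))
  N <- sum(counts)
  if (N < 2) {
    warning("pair-difference probability undefined for N < 2")
    return(NA_real_)
  }
  1 - sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Shannon diversity index
#'
#' `H = -sum p_k ln p_k` with natural logarithm and `0 ln 0 = 0`.
#'
#' @inheritParams pairDifferenceProbability
#' @return Nonnegative real; 0 for a single category, `ln K` at uniform
#'   counts over K categories.
#' @export
shannonIndex <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Gini--Simpson diversity index
#'
#' `1 - sum p_k^2`: the probability that two members drawn *with*
#' replacement differ. The without-replacement analogue is
#' [pairDifferenceProbability()], equal to `N/(N-1)` times this index.
#'
#' @inheritParams pairDifferenceProbability
#' @return Probability in `[0, 1)`.
#' @export
simpsonIndex <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Per-patient site-label counts (intertumoral level)
#'
#' One label per metastatic site, from the site-mean H-score (PSMA status
#' at the cutoff) or the site subtype call.
#'
#' @param cohort An [IHCCohort-class].
#' @param labeling `"psma_status"` (binary, default) or `"subtype"`.
#' @param cutoff PSMA low/negative cutoff (default 20).
#' @param marker Marker used for status labelling (default `"PSMA"`).
#' @param thresholds [subtypeThresholds()] for subtype labelling.
#' @return Named list (patient_id -> named count vector); patients with no
#'   labelled site are dropped.
#' @export
patientIntertumoralCounts <- function(cohort,
                                      labeling = c("psma_status", "subtype"),
                                      cutoff = 20, marker = "PSMA",
                                      thresholds = subtypeThresholds()) {
  labeling <- match.arg(labeling)
  if (labeling == "psma_status") {
    sites <- siteHScores(cohort, marker)
    sites$label <- classifyPsmaStatus(sites$h_score, cutoff)
  } else {
    sites <- siteSubtypes(cohort, thresholds)
    sites$label <- sites$subtype
  }
  sites <- sites[!is.na(sites$label), , drop = FALSE]
  lapply(split(sites$label, sites$patient_id), countLabels)
}

#' Per-site core-status counts (intratumoral level)
#'
#' Each core is classified individually (before duplicate-core averaging).
#'
#' @inheritParams patientIntertumoralCounts
#' @return Named list (`patient\rsite` key -> named count vector).
#' @export
siteIntratumoralCounts <- function(cohort, cutoff = 20, marker = "PSMA") {
  df <- as.data.frame(coreData(cohort))
  df <- df[df$marker == marker & !is.na(df$h_score), , drop = FALSE]
  df$label <- classifyPsmaStatus(df$h_score, cutoff)
  key <- paste(df$patient_id, df$site_id, sep = "\r")
  lapply(split(df$label, key), countLabels)
}

.unitCounts <- function(cohort, level, labeling, cutoff, marker, thresholds) {
  if (level == "intertumoral")
    patientIntertumoralCounts(cohort, labeling = labeling, cutoff = cutoff,
                              marker = marker, thresholds = thresholds)
  else
    siteIntratumoralCounts(cohort, cutoff = cutoff, marker = marker)
}

.eligibleUnits <- function(unitCounts) {
  unitCounts[vapply(unitCounts, sum, numeric(1)) >= 2]
}

#' Monte Carlo pair-resampling heterogeneity estimate
#'
#' Repeats `nPairs` times: draw a unit (patient for intertumoral, site for
#' intratumoral; units with fewer than two members excluded), draw an
#' unordered pair of its members uniformly without replacement, and record
#' whether their labels differ. The mean indicator estimates the
#' equal-unit-weight average of the per-unit closed-form pair-difference
#' probability. With `weighting = "pair"` units are instead drawn with
#' probability proportional to their number of member pairs.
#'
#' @param cohort An [IHCCohort-class].
#' @param level `"intertumoral"` or `"intratumoral"`.
#' @param labeling `"psma_status"` or `"subtype"` (intertumoral only).
#' @param nPairs Number of sampled pairs (default 1000).
#' @param seed Integer seed (required; recorded in the result).
#' @param weighting `"unit"` (equal unit weight, default) or `"pair"`.
#' @param cutoff,marker,thresholds Passed to the labelling step.
#' @return List: `estimate`, `n_pairs`, `n_units_used`, `unit_d` (named
#'   per-unit closed-form probabilities), `seed`.
#' @export
cohortPairEstimate <- function(cohort,
                               level = c("intertumoral", "intratumoral"),
                               labeling = c("psma_status", "subtype"),
                               nPairs = 1000L, seed,
                               weighting = c("unit", "pair"),
                               cutoff = 20, marker = "PSMA",
                               thresholds = subtypeThresholds()) {
  level <- match.arg(level); labeling <- match.arg(labeling)
  weighting <- match.arg(weighting)
  if (missing(seed)) stop("an explicit integer seed is required")
  units <- .eligibleUnits(.unitCounts(cohort, level, labeling, cutoff,
                                      marker, thresholds))
  if (length(units) == 0L)
    stop("no unit with >= 2 labelled members at level '", level, "'")
  d <- vapply(units, pairDifferenceProbability, numeric(1))
  labelPools <- lapply(units, function(ct) rep(names(ct), ct))
  w <- if (weighting == "unit") rep(1, length(units))
       else vapply(units, function(ct) choose(sum(ct), 2), numeric(1))
  set.seed(seed)
  u <- sample.int(length(units), nPairs, replace = TRUE, prob = w)
  diff <- vapply(u, function(i) {
    pool <- labelPools[[i]]
    pair <- pool[sample.int(length(pool), 2L)]
    pair[1] != pair[2]
  }, logical(1))
  list(estimate = mean(diff), n_pairs = as.integer(nPairs),
       n_units_used = length(units), unit_d = d, seed = as.integer(seed))
}

## BCa machinery ---------------------------------------------------------------

.bcaQuantiles <- function(bootStats, z0, accel, alpha) {
  zlo <- stats::qnorm(alpha / 2)
  zhi <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - accel * (z0 + zlo)))
  a2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - accel * (z0 + zhi)))
  unname(stats::quantile(bootStats, c(a1, a2), type = 7, names = FALSE))
}

#' BCa bootstrap confidence interval for a mean of unit-level values
#'
#' Nonparametric bias-corrected and accelerated interval for the mean of
#' `values` (here: per-unit pair-difference probabilities; the resampled
#' unit is a whole patient or site, i.e. a cluster bootstrap). The bias
#' term `z0` comes from the fraction of bootstrap means below the observed
#' mean; the acceleration from the skewness of the jackknife
#' (leave-one-unit-out) means. A degenerate bootstrap distribution (all
#' resampled means equal) yields a zero-width interval at the point
#' estimate.
#'
#' @param values Numeric vector, one value per unit (length >= 2).
#' @param nBoot Number of bootstrap resamples (default 2000).
#' @param alpha Two-sided miss probability (default 0.05 for 95% limits).
#' @param seed Integer seed (required).
#' @return Numeric `c(low, high)` with attributes `z0` and `accel`.
#' @export
bcaInterval <- function(values, nBoot = 2000L, alpha = 0.05, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  n <- length(values)
  if (n < 2L) stop("BCa interval requires >= 2 units")
  stopifnot(alpha > 0, alpha < 1)
  theta <- mean(values)
  set.seed(seed)
  idx <- sample.int(n, n * nBoot, replace = TRUE)
  tb <- colMeans(matrix(values[idx], nrow = n))
  if (max(tb) - min(tb) < .Machine$double.eps * 8)
    return(structure(c(theta, theta), z0 = 0, accel = 0))
  propBelow <- (sum(tb < theta) + 0.5 * sum(tb == theta)) / nBoot
  propBelow <- min(max(propBelow, 0.5 / nBoot), 1 - 0.5 / nBoot)
  z0 <- stats::qnorm(propBelow)
  jack <- (sum(values) - values) / (n - 1)
  d <- mean(jack) - jack
  accel <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  structure(.bcaQuantiles(tb, z0, accel, alpha), z0 = z0, accel = accel)
}

#' Cohort heterogeneity estimate with BCa confidence limits
#'
#' Point estimate from [cohortPairEstimate()] (the mean outcome of
#' `nPairs` randomly sampled within-unit pairs) and confidence limits from
#' a cluster bootstrap over units in which the resampled statistic is the
#' equal-weight mean of the per-unit closed-form pair-difference
#' probability.
#'
#' @inheritParams cohortPairEstimate
#' @param nBoot Bootstrap resamples (default 2000).
#' @param alpha Two-sided miss probability (default 0.05).
#' @return A [HeterogeneitySummary-class].
#' @export
heterogeneitySummary <- function(cohort,
                                 level = c("intertumoral", "intratumoral"),
                                 labeling = c("psma_status", "subtype"),
                                 nPairs = 1000L, nBoot = 2000L,
                                 alpha = 0.05, seed,
                                 weighting = c("unit", "pair"),
                                 cutoff = 20, marker = "PSMA",
                                 thresholds = subtypeThresholds()) {
  level <- match.arg(level); labeling <- match.arg(labeling)
  weighting <- match.arg(weighting)
  if (missing(seed)) stop("an explicit integer seed is required")
  est <- cohortPairEstimate(cohort, level = level, labeling = labeling,
                            nPairs = nPairs, seed = seed,
                            weighting = weighting, cutoff = cutoff,
                            marker = marker, thresholds = thresholds)
  d <- est$unit_d
  ci <- if (length(d) >= 2L)
    bcaInterval(d, nBoot = nBoot, alpha = alpha, seed = seed + 1L)
  else c(NA_real_, NA_real_)
  new("HeterogeneitySummary", level = level, labeling = labeling,
      estimate = est$estimate,
      ciLow = max(0, ci[1]), ciHigh = min(1, ci[2]),
      nPairs = as.integer(nPairs), nBoot = as.integer(nBoot),
      alpha = alpha, seed = as.integer(seed),
      nUnitsUsed = est$n_units_used, unitD = d)
}

#' Compare per-patient heterogeneity between treatment eras
#'
#' Two-sample Kolmogorov--Smirnov test (asymptotic two-sided p) on
#' per-patient values split by death year, with Gaussian kernel density
#' estimates (Silverman's rule-of-thumb bandwidth) for display.
#'
#' @param values Named numeric vector of per-patient values.
#' @param deathYear Integer vector of death years, parallel to `values`.
#' @param eras List of two `c(first, last)` year ranges (inclusive),
#'   default `2003--2010` vs `2011--2019`.
#' @return List: `ks_statistic`, `p_value`, `n` (per era), `kde` (list of
#'   two [stats::density] objects).
#' @export
eraComparison <- function(values, deathYear,
                          eras = list(early = c(2003, 2010),
                                      late = c(2011, 2019))) {
  stopifnot(length(values) == length(deathYear), length(eras) == 2L)
  groups <- lapply(eras, function(r)
    values[!is.na(deathYear) & deathYear >= r[1] & deathYear <= r[2]])
  if (any(lengths(groups) < 2L))
    stop("each era needs >= 2 values; got ",
         paste(lengths(groups), collapse = ", "))
  ks <- suppressWarnings(stats::ks.test(groups[[1]], groups[[2]],
                                        alternative = "two.sided",
                                        exact = FALSE))
  kde <- lapply(groups, function(g)
    if (stats::sd(g) > 0) stats::density(g, bw = "nrd0") else NULL)
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       n = lengths(groups), kde = kde)
}
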