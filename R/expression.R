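## PSMA grouping by mean split, per-cohort two-group differential
## expression, cross-cohort consensus, target-list refinement, ranking,
## and protein--mRNA regression.

#' Split samples into PSMA-low and PSMA-high by the cohort mean
#'
#' Samples with FOLH1/PSMA FPKM strictly below the per-data-set mean are
#' `"low"`; samples at or above the mean are `"high"` (the tie-at-mean rule
#' is documented, not arbitrary: the degenerate all-identical case then
#' yields all-high with a warning). The mean is taken on the FPKM scale.
#'
#' @param folh1Fpkm Named numeric vector of per-sample FPKM (length >= 2).
#' @return Named character vector `"low"`/`"high"`.
#' @examples
#' splitByMean(c(a = 1, b = 2, c = 9))  # a, b low; c high
#' @export
splitByMean <- function(folh1Fpkm) {
  x <- as.numeric(folh1Fpkm)
  if (length(x) < 2L) stop("mean split requires >= 2 samples")
  if (anyNA(x)) stop("missing FPKM values in mean split")
  g <- ifelse(x < mean(x), "low", "high")
  if (all(g == "high"))
    warning("degenerate mean split: all samples assigned 'high'")
  stats::setNames(g, names(folh1Fpkm))
}

#' Assign PSMA groups on an ExpressionCohort
#'
#' Convenience wrapper: runs [splitByMean()] on one gene's FPKM row and
#' stores the result in `colData(x)$psma_group`.
#'
#' @param x An [ExpressionCohort-class].
#' @param gene Grouping gene symbol (default `"FOLH1"`).
#' @return `x` with `psma_group` filled in.
#' @export
assignPsmaGroups <- function(x, gene = "FOLH1") {
  stopifnot(is(x, "ExpressionCohort"))
  if (!gene %in% rownames(x)) stop("gene '", gene, "' not in matrix")
  SummarizedExperiment::colData(x)$psma_group <-
    unname(splitByMean(fpkm(x)[gene, ]))
  x
}

#' Subset an ExpressionCohort to one molecular subtype
#'
#' Samples with unassigned subtype are dropped.
#'
#' @param x An [ExpressionCohort-class].
#' @param subtype Subtype label, default `"AR+/NE-"`.
#' @return The restricted cohort.
#' @export
restrictToSubtype <- function(x, subtype = "AR+/NE-") {
  stopifnot(is(x, "ExpressionCohort"))
  keep <- !is.na(colData(x)$subtype) & colData(x)$subtype == subtype
  x[, keep]
}

#' Filter genes for a minimum expression level
#'
#' Keeps genes with FPKM at or above `minFpkm` in at least `minFrac` of
#' samples. Filter parameters are recorded in `metadata(x)$expression_filter`.
#'
#' @param x An [ExpressionCohort-class].
#' @param minFpkm Minimum FPKM (default 1).
#' @param minFrac Minimum fraction of samples (default 0.2).
#' @return Filtered cohort; error if no gene survives.
#' @export
filterMinExpression <- function(x, minFpkm = 1.0, minFrac = 0.2) {
  stopifnot(is(x, "ExpressionCohort"))
  keep <- rowMeans(fpkm(x) >= minFpkm) >= minFrac
  if (!any(keep)) stop("no gene passes the minimum-expression filter")
  out <- x[keep, ]
  metadata(out)$expression_filter <- list(min_fpkm = minFpkm,
                                          min_frac = minFrac,
                                          n_kept = sum(keep),
                                          n_total = length(keep))
  out
}

#' Benjamini--Hochberg false-discovery-rate adjustment
#'
#' Step-up BH via [stats::p.adjust()], with input validation.
#'
#' @param pValues Numeric vector of p-values in `[0, 1]`.
#' @return FDR values in input order.
#' @export
bhAdjust <- function(pValues) {
  p <- as.numeric(pValues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression (Welch t on log2(FPKM + 1))
#'
#' Per gene, a two-sided Welch t-test on `log2(FPKM + pseudocount)`
#' between the PSMA-low and PSMA-high groups, with BH adjustment over the
#' tested genes. `log2fc` is mean(low) - mean(high), so positive values are
#' up in PSMA-low/negative tumors. This is a documented simpler substitute
#' for a moderated linear-model fit; the substitution is recorded in the
#' result's attributes.
#'
#' @param x An [ExpressionCohort-class] with `psma_group` assigned (see
#'   [assignPsmaGroups()]) and the expression filter applied.
#' @param groups Optional explicit `"low"`/`"high"` vector overriding
#'   `colData(x)$psma_group`.
#' @param pseudocount Added before the log2 transform (default 1).
#' @return data.frame: `cohort`, `gene`, `log2fc`, `p_value`, `fdr`,
#'   `mean_expr_low`, `mean_expr_high`; attribute `method` documents the
#'   test.
#' @export
differentialExpression <- function(x, groups = NULL, pseudocount = 1) {
  stopifnot(is(x, "ExpressionCohort"))
  if (is.null(groups)) groups <- colData(x)$psma_group
  groups <- as.character(groups)
  n1 <- sum(groups == "low", na.rm = TRUE)
  n2 <- sum(groups == "high", na.rm = TRUE)
  if (n1 < 3L || n2 < 3L)
    stop("each group needs >= 3 samples; got low=", n1, ", high=", n2)
  L <- log2(fpkm(x) + pseudocount)
  lo <- L[, which(groups == "low"), drop = FALSE]
  hi <- L[, which(groups == "high"), drop = FALSE]
  m1 <- rowMeans(lo); m2 <- rowMeans(hi)
  v1 <- matrixStats::rowVars(lo); v2 <- matrixStats::rowVars(hi)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zeroSe <- se2 == 0
  p[zeroSe] <- ifelse(m1[zeroSe] == m2[zeroSe], 1, 0)
  out <- data.frame(cohort = cohortName(x), gene = rownames(L),
                    log2fc = m1 - m2, p_value = p, fdr = bhAdjust(p),
                    mean_expr_low = m1, mean_expr_high = m2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "method") <- paste("two-sided Welch t-test on",
                               sprintf("log2(FPKM + %g);", pseudocount),
                               "substitute for a moderated linear model")
  out
}

.significantCalls <- function(res, fdrMax, fcMin) {
  sig <- res$fdr <= fdrMax & 2^abs(res$log2fc) > fcMin
  data.frame(cohort = res$cohort[sig], gene = res$gene[sig],
             direction = ifelse(res$log2fc[sig] > 0, "up_in_low",
                                "up_in_high"),
             fold_change = 2^abs(res$log2fc[sig]),
             stringsAsFactors = FALSE)
}

#' Cross-cohort consensus differential-expression calls
#'
#' A gene is a consensus call when it passes `fdr <= fdrMax` and
#' `fold change > fcMin` with the *same* direction in at least
#' `minCohorts` data sets. Genes significant in opposite directions in
#' different cohorts are excluded and reported in `$conflicts`.
#'
#' @param results List of per-cohort [differentialExpression()] results
#'   (>= 2 cohorts unless `minCohorts = 1`).
#' @param fdrMax FDR ceiling (default 0.05).
#' @param fcMin Linear fold-change floor, strict (default 2).
#' @param minCohorts Minimum supporting data sets (default 2).
#' @return List with data.frames `up_in_low` and `up_in_high` (columns
#'   `gene`, `direction`, `n_supporting`, `mean_fold_change`, sorted by
#'   decreasing `mean_fold_change`) and character vector `conflicts`.
#' @export
consensusGenes <- function(results, fdrMax = 0.05, fcMin = 2.0,
                           minCohorts = 2L) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (length(results) < minCohorts)
    stop("need >= minCohorts (", minCohorts, ") cohorts; got ",
         length(results))
  calls <- do.call(rbind, lapply(results, .significantCalls,
                                 fdrMax = fdrMax, fcMin = fcMin))
  empty <- data.frame(gene = character(0), direction = character(0),
                      n_supporting = integer(0),
                      mean_fold_change = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L)
    return(list(up_in_low = empty, up_in_high = empty,
                conflicts = character(0)))
  perGene <- split(calls, calls$gene)
  conflicts <- names(perGene)[vapply(perGene, function(g)
    length(unique(g$direction)) > 1L, logical(1))]
  if (length(conflicts))
    message("excluding ", length(conflicts),
            " gene(s) with conflicting significant directions: ",
            paste(utils::head(conflicts, 10), collapse = ", "))
  keep <- perGene[!names(perGene) %in% conflicts]
  keep <- keep[vapply(keep, nrow, integer(1)) >= minCohorts]
  rows <- lapply(keep, function(g)
    data.frame(gene = g$gene[1], direction = g$direction[1],
               n_supporting = nrow(g),
               mean_fold_change = mean(g$fold_change),
               stringsAsFactors = FALSE))
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else empty
  ord <- order(-tab$mean_fold_change, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(up_in_low = tab[tab$direction == "up_in_low", , drop = FALSE],
       up_in_high = tab[tab$direction == "up_in_high", , drop = FALSE],
       conflicts = conflicts)
}

#' Refine differential-expression results to a target gene list
#'
#' Applies the consensus rule with a (laxer) `minCohorts` default of 1,
#' restricted to a curated list (druggable-genome tier 1 or surfaceome).
#' Symbol matching is case-insensitive; list symbols with no counterpart
#' among the tested genes are reported in `$unmatched`.
#'
#' @inheritParams consensusGenes
#' @param geneList Character vector of target symbols (nonempty).
#' @return List: `targets` (a consensus table restricted to the list,
#'   both directions combined, sorted by decreasing mean fold change) and
#'   `unmatched` (list symbols absent from every cohort's tested genes).
#' @export
filterTargetLists <- function(results, geneList, fdrMax = 0.05,
                              fcMin = 2.0, minCohorts = 1L) {
  if (length(geneList) == 0L) stop("empty target gene list")
  cons <- consensusGenes(results, fdrMax = fdrMax, fcMin = fcMin,
                         minCohorts = minCohorts)
  tab <- rbind(cons$up_in_low, cons$up_in_high)
  tested <- unique(toupper(unlist(lapply(results, `[[`, "gene"))))
  unmatched <- geneList[!toupper(geneList) %in% tested]
  if (length(unmatched))
    message(length(unmatched), " target symbol(s) not present in any ",
            "expression matrix: ",
            paste(utils::head(unmatched, 10), collapse = ", "))
  tab <- tab[toupper(tab$gene) %in% toupper(geneList), , drop = FALSE]
  ord <- order(-tab$mean_fold_change, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(targets = tab, unmatched = unmatched)
}

#' Rank consensus genes by mean fold change
#'
#' Descending by absolute mean fold change; ties broken by gene symbol
#' (lexicographic). The top `k` rows are returned.
#'
#' @param genes A consensus table with columns `gene` and
#'   `mean_fold_change`.
#' @param k Number of genes to keep (default 20; fewer returned if fewer
#'   exist).
#' @return The ranked head of `genes`.
#' @export
rankByMeanFC <- function(genes, k = 20L) {
  if (k <= 0) stop("k must be positive")
  stopifnot(all(c("gene", "mean_fold_change") %in% colnames(genes)))
  ord <- order(-abs(genes$mean_fold_change), genes$gene)
  out <- genes[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear regression of expression on protein H-score
#'
#' Ordinary least squares of `expr` on `hScores`; `r` is the Pearson
#' correlation, `r_squared = r^2`, and the two-sided p-value comes from the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param hScores Per-sample predictor values (H-scores).
#' @param expr Per-sample response (log2 FPKM).
#' @return List: `slope`, `slope_se`, `intercept`, `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
regressProteinMrna <- function(hScores, expr) {
  ok <- !is.na(hScores) & !is.na(expr)
  x <- as.numeric(hScores[ok]); y <- as.numeric(expr[ok])
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired non-missing observations; got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in predictor or response")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), n - 2)
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) /
               sum((x - mean(x))^2))
  list(slope = unname(stats::coef(fit)[2]), slope_se = se,
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2, p_value = p, n = n)
}
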