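test_that("mean split assigns low strictly below the mean, ties high", {
  expect_equal(unname(splitByMean(c(1, 2, 9))), c("low", "low", "high"))
  expect_warning(g <- splitByMean(c(5, 5)), "degenerate")
  expect_equal(unname(g), c("high", "high"))
  expect_equal(unname(splitByMean(c(0, 10))), c("low", "high"))
  # invariant under positive rescaling
  set.seed(2)
  x <- rexp(30, 0.2)
  expect_equal(splitByMean(x), splitByMean(7.3 * x))
  expect_error(splitByMean(5), ">= 2")
})

test_that("minimum-expression filter applies the fraction rule", {
  m <- rbind(high = rep(5, 10),
             zero = rep(0, 10),
             rare = c(2, rep(0, 9)))    # FPKM >= 1 in 10% < 20%
  colnames(m) <- sprintf("s%d", 1:10)
  x <- ExpressionCohort(m, cohortName = "toy")
  f <- filterMinExpression(x, minFpkm = 1, minFrac = 0.2)
  expect_equal(rownames(f), "high")
  expect_equal(S4Vectors::metadata(f)$expression_filter$min_fpkm, 1)
  expect_error(filterMinExpression(x, minFpkm = 100), "no gene")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p), tolerance = 1e-12)
  }
  # monotone along sorted p-values, invariant to input order
  p <- runif(40)
  q <- bhAdjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(40)
  expect_equal(bhAdjust(p[perm]), q[perm])
})

test_that("differential expression recovers planted effects and nulls", {
  set.seed(23)
  n <- 30
  groups <- rep(c("low", "high"), each = n)
  L <- matrix(rnorm(2000 * 2 * n, 5, 0.5), nrow = 2000)
  rownames(L) <- sprintf("G%04d", 1:2000)
  # plant a clean 4-fold change in gene 1
  L[1, groups == "low"] <- L[1, groups == "low"] + 2
  m <- 2^L
  colnames(m) <- sprintf("s%d", seq_len(2 * n))
  x <- ExpressionCohort(m, cohortName = "sim")
  res <- differentialExpression(x, groups = groups)
  expect_equal(nrow(res), 2000L)
  expect_lt(abs(res$log2fc[1] - 2), 0.3)
  expect_lt(res$fdr[1], 1e-6)
  # under the null, p-values are near-uniform
  expect_lt(abs(mean(res$p_value[-1] < 0.05) - 0.05), 0.02)
  # identical values in both groups: log2fc 0, p 1
  mEq <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 2), nrow = 2,
                dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  rEq <- differentialExpression(ExpressionCohort(mEq),
                                groups = rep(c("low", "high"), 3))
  expect_equal(rEq$log2fc, c(0, 0))
  expect_equal(rEq$p_value, c(1, 1))
  expect_error(differentialExpression(x, groups = c(rep("low", 2),
                                                    rep("high", 58))),
               "low=2")
})

test_that("consensus rule requires same-direction support in >= 2 cohorts", {
  r1 <- makeDeRows("c1", c("A", "B", "C"), c(2, 2, 1.5), c(0.01, 0.01, 0.01))
  r2 <- makeDeRows("c2", c("A", "B", "C"), c(2, -2, 1.5), c(0.01, 0.2, 0.01))
  r3 <- makeDeRows("c3", c("A", "B", "C"), c(0.1, 2, 1.5), c(0.9, 0.01, 0.01))
  cons <- consensusGenes(list(r1, r2, r3))
  # A: significant up_in_low in c1 and c2 -> included with n_supporting 2;
  # B's non-significant opposite fold change in c2 is not a conflict
  expect_equal(cons$up_in_low$gene, c("A", "B", "C"))
  expect_equal(cons$up_in_low$n_supporting[cons$up_in_low$gene == "A"], 2L)
  expect_equal(cons$up_in_low$mean_fold_change[cons$up_in_low$gene == "A"], 4)
  # C: |FC| = 2^1.5 about 2.83 > 2 in all three cohorts
  expect_equal(cons$up_in_low$n_supporting[cons$up_in_low$gene == "C"], 3L)

  # B is up_in_low in c1 but up_in_high in c3: conflict, excluded
  r3b <- makeDeRows("c3", "B", -2, 0.01)
  expect_message(cons2 <- consensusGenes(list(r1, r3b)), "conflict")
  expect_equal(cons2$conflicts, "B")
  expect_false("B" %in% c(cons2$up_in_low$gene, cons2$up_in_high$gene))

  # significant in one cohort only: excluded at min_cohorts 2
  r4 <- makeDeRows("c2", "A", 0.1, 0.9)
  cons3 <- consensusGenes(list(r1, r4))
  expect_false("A" %in% cons3$up_in_low$gene)
})

test_that("consensus matches an independent set-logic oracle on a sim run", {
  ex <- simulateExpression(simConfig(nGenes = 400, nDeGenes = 30),
                           seed = 31)
  res <- lapply(ex$cohorts, function(x)
    differentialExpression(filterMinExpression(assignPsmaGroups(x))))
  cons <- suppressMessages(consensusGenes(res))
  # oracle: per-gene boolean table -> set operations
  sig <- lapply(res, function(r)
    data.frame(gene = r$gene,
               up = r$fdr <= 0.05 & r$log2fc > 0 & 2^abs(r$log2fc) > 2,
               dn = r$fdr <= 0.05 & r$log2fc < 0 & 2^abs(r$log2fc) > 2))
  genes <- unique(unlist(lapply(sig, `[[`, "gene")))
  nUp <- rowSums(sapply(sig, function(s) s$up[match(genes, s$gene)]),
                 na.rm = TRUE)
  nDn <- rowSums(sapply(sig, function(s) s$dn[match(genes, s$gene)]),
                 na.rm = TRUE)
  oracleLow <- sort(genes[nUp >= 2 & nDn == 0])
  oracleHigh <- sort(genes[nDn >= 2 & nUp == 0])
  expect_equal(sort(cons$up_in_low$gene), oracleLow)
  expect_equal(sort(cons$up_in_high$gene), oracleHigh)
})

test_that("target-list refinement restricts and reports unmatched symbols", {
  r1 <- makeDeRows("c1", c("ERBB2", "XYZ1"), c(2, 3), c(0.01, 0.01))
  r2 <- makeDeRows("c2", c("ERBB2", "XYZ1"), c(0.1, 0.1), c(0.9, 0.9))
  expect_message(
    out <- filterTargetLists(list(r1, r2), c("erbb2", "CDK6")),
    "CDK6")
  # ERBB2 significant in 1 cohort: retained at min_cohorts 1,
  # case-insensitive matching
  expect_equal(out$targets$gene, "ERBB2")
  expect_equal(out$unmatched, "CDK6")
  # planted gene absent from the list is dropped
  expect_false("XYZ1" %in% out$targets$gene)
  expect_error(filterTargetLists(list(r1, r2), character(0)), "empty")
})

test_that("ranking is by absolute mean fold change with alphabetical ties", {
  tab <- data.frame(gene = c("Z", "A", "M", "B"),
                    mean_fold_change = c(8, 4, 2, 4))
  top2 <- rankByMeanFC(tab, k = 2)
  expect_equal(top2$gene, c("Z", "A"))          # tie at 4 -> A before B
  expect_equal(rankByMeanFC(tab, k = 10)$gene, c("Z", "A", "B", "M"))
  expect_error(rankByMeanFC(tab, k = 0), "positive")
})

test_that("protein-mRNA regression recovers exact and planted relations", {
  x <- 1:5
  fit <- regressProteinMrna(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 5L)
  expect_error(regressProteinMrna(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(regressProteinMrna(1:2, 1:2), ">= 3")

  # planted slope recovered within 3 SE in nearly all replicates
  set.seed(29)
  hits <- replicate(300, {
    h <- runif(50, 0, 200)
    y <- 0.05 * h + rnorm(50, 0, 1.5)
    f <- regressProteinMrna(h, y)
    abs(f$slope - 0.05) <= 3 * f$slope_se
  })
  expect_gte(mean(hits), 0.95)

  # permutation destroys the association
  set.seed(30)
  h <- runif(100, 0, 200)
  y <- 0.05 * h + rnorm(100, 0, 1)
  pPerm <- replicate(100, regressProteinMrna(h, sample(y))$p_value)
  expect_gt(mean(pPerm > 0.05), 0.85)
  expect_lt(regressProteinMrna(h, y)$p_value, 1e-6)
})
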