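test_that("pair-difference probability matches hand-enumerated cases", {
  expect_equal(pairDifferenceProbability(c(A = 2, B = 2)), 4 / 6)
  expect_equal(pairDifferenceProbability(c(A = 5, B = 2)), 10 / 21)
  expect_equal(pairDifferenceProbability(c(A = 3)), 0)
  expect_equal(pairDifferenceProbability(c(A = 1, B = 1)), 1)
  expect_warning(res <- pairDifferenceProbability(c(A = 1)), "N < 2")
  expect_true(is.na(res))
})

test_that("pair-difference probability equals brute-force enumeration", {
  set.seed(3)
  for (i in 1:50) {
    counts <- rpois(sample(2:4, 1), 3) + 1
    expect_equal(pairDifferenceProbability(counts),
                 bruteForcePairDiff(counts))
  }
})

test_that("diversity indices match their closed forms and vegan", {
  expect_equal(shannonIndex(c(A = 2, B = 2)), log(2))
  expect_equal(shannonIndex(c(A = 7)), 0)
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4))
  expect_equal(simpsonIndex(c(A = 2, B = 2)), 0.5)
  expect_equal(simpsonIndex(c(A = 9)), 0)
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:20) {
    counts <- rpois(sample(2:5, 1), 4) + 1
    expect_equal(shannonIndex(counts),
                 unname(vegan::diversity(counts, index = "shannon")))
    expect_equal(simpsonIndex(counts),
                 unname(vegan::diversity(counts, index = "simpson")))
  }
})

test_that("D equals N/(N-1) times the Gini-Simpson index", {
  set.seed(5)
  for (i in 1:200) {
    counts <- rpois(sample(1:6, 1), 3) + 1
    N <- sum(counts)
    if (N < 2) next
    expect_equal(pairDifferenceProbability(counts),
                 N / (N - 1) * simpsonIndex(counts), tolerance = 1e-12)
  }
})

test_that("D attains its extremes exactly at the boundary compositions", {
  expect_equal(pairDifferenceProbability(c(4)), 0)
  expect_equal(pairDifferenceProbability(c(1, 1, 1, 1)), 1)
  # Shannon maximal at uniform counts
  expect_lt(shannonIndex(c(3, 1)), shannonIndex(c(2, 2)))
})

test_that("unit counting separates intertumoral and intratumoral levels", {
  # P1: site statuses neg, pos, pos; P2: single site (excluded downstream)
  cohort <- makeCohort(list(P1 = c(10, 150, 180), P2 = 50))
  counts <- patientIntertumoralCounts(cohort)
  expect_equal(counts$P1, c(low_negative = 1L, positive = 2L))
  expect_equal(sum(counts$P2), 1L)

  # intratumoral: cores classified individually, before averaging
  site <- makeSingleSiteCohort(c(10, 150))
  ic <- siteIntratumoralCounts(site)
  expect_equal(unname(ic[[1]]), c(1L, 1L))
  expect_equal(pairDifferenceProbability(ic[[1]]), 1)
  hom <- siteIntratumoralCounts(makeSingleSiteCohort(c(150, 160)))
  expect_equal(pairDifferenceProbability(hom[[1]]), 0)
})

test_that("subtype labeling yields multi-category counts", {
  rows <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(patient_id = "P1", site_id = paste0("S", s),
               anatomic_site = "liver",
               marker = c("AR", "SYP"), core_id = "c1",
               h_score = if (s == 1) c(150, 0) else c(0, 150))
  }))
  counts <- patientIntertumoralCounts(IHCCohort(rows), labeling = "subtype")
  expect_equal(sort(names(counts$P1)), c("AR+/NE-", "AR-/NE+"))
  expect_equal(unname(counts$P1), c(1L, 1L))
})

test_that("pair-resampling estimate converges to the closed form", {
  cohort <- makeCohort(list(P1 = c(10, 10, 150, 150)))  # D = 2/3
  est <- cohortPairEstimate(cohort, "intertumoral", nPairs = 10000,
                            seed = 1)
  expect_lt(abs(est$estimate - 2 / 3), 0.02)

  # two patients with D = 0 and D = 1 weighted equally
  cohort2 <- makeCohort(list(P1 = c(10, 150), P2 = c(100, 120)))
  est2 <- cohortPairEstimate(cohort2, "intertumoral", nPairs = 20000,
                             seed = 2)
  expect_lt(abs(est2$estimate - 0.5), 0.02)

  # all units homogeneous: estimate is exactly zero
  cohort3 <- makeCohort(list(P1 = c(100, 120), P2 = c(1, 2)))
  est3 <- cohortPairEstimate(cohort3, "intertumoral", nPairs = 500,
                             seed = 3)
  expect_identical(est3$estimate, 0)

  # pair-uniform weighting shifts mass toward the larger unit
  cohort4 <- makeCohort(list(P1 = c(10, 150),            # D = 1, 1 pair
                             P2 = rep(c(100, 120), 5)))  # D = 0, 45 pairs
  estU <- cohortPairEstimate(cohort4, "intertumoral", nPairs = 20000,
                             seed = 4)
  estP <- cohortPairEstimate(cohort4, "intertumoral", nPairs = 20000,
                             seed = 4, weighting = "pair")
  expect_lt(abs(estU$estimate - 0.5), 0.02)
  expect_lt(abs(estP$estimate - 1 / 46), 0.01)
})

test_that("estimator error shrinks as the number of sampled pairs grows", {
  sim <- simulateCohort(simConfig(nPatients = 30), seed = 9)
  d <- cohortPairEstimate(sim$cohort, "intertumoral", nPairs = 10,
                          seed = 1)$unit_d
  truth <- mean(d)
  errs <- vapply(c(1e3, 1e4, 1e5), function(np) {
    abs(cohortPairEstimate(sim$cohort, "intertumoral", nPairs = np,
                           seed = 5)$estimate - truth)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 0.01)
})

test_that("BCa reduces to percentile limits when z0 and accel are zero", {
  set.seed(8)
  tb <- rnorm(4000)
  bca <- PSMAhet:::.bcaQuantiles(tb, z0 = 0, accel = 0, alpha = 0.05)
  perc <- unname(quantile(tb, c(0.025, 0.975), type = 7))
  expect_equal(bca, perc)
})

test_that("BCa interval endpoints are monotone in alpha", {
  set.seed(10)
  x <- rbeta(40, 2, 5)
  ci95 <- bcaInterval(x, nBoot = 2000, alpha = 0.05, seed = 1)
  ci80 <- bcaInterval(x, nBoot = 2000, alpha = 0.20, seed = 1)
  expect_lte(ci95[1], ci80[1])
  expect_gte(ci95[2], ci80[2])
  expect_lte(ci95[1], mean(x))
  expect_gte(ci95[2], mean(x))
})

test_that("degenerate bootstrap distributions give zero-width intervals", {
  ci <- bcaInterval(rep(0.4, 10), nBoot = 200, alpha = 0.05, seed = 2)
  expect_equal(as.numeric(ci), c(0.4, 0.4))
})

test_that("hand-rolled BCa agrees with boot::boot.ci", {
  skip_if_not_installed("boot")
  set.seed(21)
  x <- rbeta(60, 2, 5)
  ours <- bcaInterval(x, nBoot = 8000, alpha = 0.05, seed = 3)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 8000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_lt(max(abs(unname(ours) - ref)), 0.02)
})

test_that("heterogeneitySummary assembles a valid S4 result", {
  sim <- simulateCohort(simConfig(nPatients = 25), seed = 13)
  h <- heterogeneitySummary(sim$cohort, "intertumoral", nPairs = 1000,
                            nBoot = 500, seed = 13)
  expect_s4_class(h, "HeterogeneitySummary")
  e <- hetEstimate(h)
  expect_true(e["ci_low"] <= e["ci_high"])
  expect_true(all(e >= 0 & e <= 1))
  expect_equal(h@nUnitsUsed, length(unitD(h)))
  # cohort of identical homogeneous patients: interval (0, 0)
  hom <- makeCohort(list(P1 = c(100, 110), P2 = c(120, 130),
                         P3 = c(140, 150)))
  h0 <- heterogeneitySummary(hom, "intertumoral", nPairs = 100,
                             nBoot = 200, seed = 1)
  expect_equal(unname(hetEstimate(h0)), c(0, 0, 0))
})

test_that("era comparison computes the KS statistic on split years", {
  v <- c(1, 2, 3, 4, 5, 6)
  yr <- c(2004, 2006, 2009, 2012, 2015, 2018)
  same <- eraComparison(c(v[1:3], v[1:3]), yr)
  expect_equal(same$ks_statistic, 0)
  apart <- eraComparison(v, yr)
  expect_equal(apart$ks_statistic, 1)
  expect_error(eraComparison(v[1:3], c(2004, 2012, 2015)), ">= 2")
})

test_that("era KS test has near-nominal null rejection", {
  set.seed(17)
  rej <- replicate(200, {
    v <- rnorm(40)
    yr <- rep(c(2005, 2015), each = 20)
    eraComparison(v, yr)$p_value < 0.05
  })
  expect_lt(mean(rej), 0.12)
})
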