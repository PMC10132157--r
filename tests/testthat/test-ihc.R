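test_that("H-score is the intensity-weighted percentage sum, bounded 0-200", {
  expect_equal(computeHScore(20, 30, 50), 130)
  expect_equal(computeHScore(0, 0, 100), 200)
  expect_equal(computeHScore(100, 0, 0), 0)
  expect_error(computeHScore(20, 30, 30), "sum to 100")
  # linear in the percentage vector: midpoint of two valid triples
  a <- computeHScore(60, 30, 10); b <- computeHScore(20, 30, 50)
  expect_equal(computeHScore(40, 30, 30), (a + b) / 2)
  # vectorized with NA pass-through
  expect_equal(computeHScore(c(100, NA), c(0, NA), c(0, NA)),
               c(0, NA))
})

test_that("duplicate-core aggregation averages non-missing scores", {
  expect_equal(aggregateCores(c(130, 150)), 140)
  expect_equal(aggregateCores(88), 88)
  expect_equal(aggregateCores(c(NA, 60)), 60)
  expect_warning(res <- aggregateCores(c(NA_real_, NA_real_)), "missing")
  expect_true(is.na(res))
  # invariant under permutation
  expect_equal(aggregateCores(c(10, 50, 90)), aggregateCores(c(90, 10, 50)))
})

test_that("PSMA status uses <= cutoff as low/negative, ties low", {
  expect_equal(classifyPsmaStatus(20), "low_negative")
  expect_equal(classifyPsmaStatus(20.5), "positive")
  expect_equal(classifyPsmaStatus(0), "low_negative")
  expect_true(is.na(classifyPsmaStatus(NA)))
  # monotone in the cutoff: raising it never moves a site to positive
  h <- seq(0, 200, by = 5)
  for (c1 in c(10, 20, 50)) {
    lowAt1 <- classifyPsmaStatus(h, c1) == "low_negative"
    lowAt2 <- classifyPsmaStatus(h, c1 + 30) == "low_negative"
    expect_true(all(lowAt2 >= lowAt1))
  }
})

test_that("AR/NE subtype calls follow the any-marker axis rule", {
  expect_equal(callSubtype(c(AR = 150, NKX3.1 = 100, SYP = 0, INSM1 = 0)),
               "AR+/NE-")
  expect_equal(callSubtype(c(AR = 0, NKX3.1 = 0, SYP = 180, INSM1 = 120)),
               "AR-/NE+")
  expect_equal(callSubtype(c(AR = 0, NKX3.1 = 0, SYP = 0, INSM1 = 0)),
               "AR-/NE-")
  expect_equal(callSubtype(c(AR = 100, SYP = 100)), "AR+/NE+")
  # any_marker: one positive marker suffices on an axis
  expect_equal(callSubtype(c(AR = 0, NKX3.1 = 30, SYP = 0, INSM1 = 0)),
               "AR+/NE-")
  # all_markers requires every measured axis marker positive
  th <- subtypeThresholds(rule = "all_markers")
  expect_equal(callSubtype(c(AR = 0, NKX3.1 = 30, SYP = 0, INSM1 = 0), th),
               "AR-/NE-")
  expect_warning(res <- callSubtype(c(AR = 100)), "unassigned")
  expect_true(is.na(res))
})

test_that("patient patterns partition patients into the three classes", {
  cohort <- makeCohort(list(P1 = c(10, 150), P2 = c(5, 0, 18), P3 = 190))
  pat <- classifyPatientPattern(cohort)
  pat <- pat[order(pat$patient_id), ]
  expect_equal(pat$pattern,
               c("heterogeneous", "uniform_low_negative", "uniform_high"))
  expect_equal(pat$n_sites, c(2L, 3L, 1L))
  expect_equal(pat$n_negative_sites, c(1L, 3L, 0L))
  # single-site patients can never be heterogeneous; classes sum to cohort
  expect_equal(sum(table(pat$pattern)), 3L)
})

test_that("pattern classification uses site-mean H-scores over cores", {
  # cores 10 and 40 average to 25 > 20: the site is positive
  cohort <- makeSingleSiteCohort(c(10, 40))
  expect_equal(classifyPatientPattern(cohort)$pattern, "uniform_high")
})

test_that("negative-site histogram bins patients at 0..4 and >=5", {
  cohort <- makeCohort(list(
    P1 = rep(100, 3),                  # 0 negative sites
    P2 = c(5, 10, 100, 100),           # 2
    P3 = c(rep(0, 7), 100)))           # 7 -> >=5
  bins <- countNegativeSites(cohort)
  expect_equal(bins, c("0" = 1L, "1" = 0L, "2" = 1L, "3" = 0L, "4" = 0L,
                       ">=5" = 1L))
  expect_equal(sum(bins), 3L)
  # all-positive cohort: all mass in bin 0
  allPos <- makeCohort(list(P1 = c(100, 150), P2 = 80))
  expect_equal(unname(countNegativeSites(allPos)["0"]), 2L)
  # empty cohort: all-zero histogram
  empty <- IHCCohort(data.frame(patient_id = character(0),
                                site_id = character(0),
                                anatomic_site = character(0),
                                marker = character(0),
                                core_id = character(0),
                                h_score = numeric(0)))
  expect_equal(sum(countNegativeSites(empty)), 0L)
})

test_that("identical anatomic-site groups give a null-centered rank test", {
  rows <- rbind(
    data.frame(patient_id = sprintf("P%d", 1:3), site_id = "S1",
               anatomic_site = "liver", marker = "PSMA", core_id = "c1",
               h_score = c(1, 2, 3)),
    data.frame(patient_id = sprintf("P%d", 4:6), site_id = "S1",
               anatomic_site = "bone_vertebral", marker = "PSMA",
               core_id = "c1", h_score = c(1, 2, 3)))
  res <- compareSiteHScores(IHCCohort(rows))
  expect_equal(res$pairwise$p_value, 1)
  expect_equal(res$group_stats$mean, c(2, 2))
})

test_that("a planted anatomic-site shift is detected after BH adjustment", {
  set.seed(42)
  n <- 25
  rows <- rbind(
    data.frame(patient_id = sprintf("P%d", 1:n), site_id = "S1",
               anatomic_site = "liver", marker = "PSMA", core_id = "c1",
               h_score = pmax(rnorm(n, 60, 15), 0)),   # planted -40 offset
    data.frame(patient_id = sprintf("P%d", n + 1:n), site_id = "S1",
               anatomic_site = "bone_vertebral", marker = "PSMA",
               core_id = "c1", h_score = pmin(rnorm(n, 100, 15), 200)))
  res <- compareSiteHScores(IHCCohort(rows))
  i <- which(res$pairwise$group1 == "bone_vertebral" &
               res$pairwise$group2 == "liver" |
               res$pairwise$group1 == "liver" &
               res$pairwise$group2 == "bone_vertebral")
  expect_lt(res$pairwise$fdr[i], 0.05)
  expect_lt(res$omnibus$p_value, 0.05)
})

test_that("rank-test type-I error is near nominal under the null", {
  set.seed(7)
  reject <- replicate(200, {
    g1 <- rnorm(15, 100, 20); g2 <- rnorm(15, 100, 20)
    suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE)$p.value) < 0.05
  })
  expect_gt(mean(reject), 0.005)
  expect_lt(mean(reject), 0.12)
})

test_that("degenerate groups are excluded with a warning", {
  rows <- rbind(
    data.frame(patient_id = sprintf("P%d", 1:3), site_id = "S1",
               anatomic_site = "liver", marker = "PSMA", core_id = "c1",
               h_score = c(10, 20, 30)),
    data.frame(patient_id = sprintf("P%d", 4:6), site_id = "S1",
               anatomic_site = "lung", marker = "PSMA", core_id = "c1",
               h_score = c(40, 50, 60)),
    data.frame(patient_id = "P7", site_id = "S1",
               anatomic_site = "adrenal", marker = "PSMA", core_id = "c1",
               h_score = 100))
  expect_warning(res <- compareSiteHScores(IHCCohort(rows)), "adrenal")
  expect_false("adrenal" %in% res$group_stats$anatomic_site)
})
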