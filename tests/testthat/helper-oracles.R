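# Independent oracles and small fixture builders shared across tests.

# Brute-force pair-difference probability: enumerate all C(N, 2) unordered
# pairs of a label vector and count differing pairs.
bruteForcePairDiff <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  if (length(labels) < 2) return(NA_real_)
  pairs <- utils::combn(labels, 2)
  mean(pairs[1, ] != pairs[2, ])
}

# All ordered count tuples (n1..nK), nonnegative, summing to N.
allCompositions <- function(N, K) {
  if (K == 1) return(matrix(N, ncol = 1))
  out <- list()
  for (n1 in 0:N) {
    rest <- allCompositions(N - n1, K - 1)
    out[[length(out) + 1]] <- cbind(n1, rest)
  }
  do.call(rbind, out)
}

# Brute-force BH step-up, independent of stats::p.adjust.
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

# Minimal long-format cohort: one marker, site-level H-scores expanded to
# one core each.
makeCohort <- function(patientSites, marker = "PSMA") {
  rows <- do.call(rbind, lapply(names(patientSites), function(p) {
    h <- patientSites[[p]]
    data.frame(patient_id = p,
               site_id = sprintf("S%d", seq_along(h)),
               anatomic_site = "liver", marker = marker,
               core_id = "c1", h_score = h,
               stringsAsFactors = FALSE)
  }))
  IHCCohort(rows)
}

# One patient, one site, arbitrary core scores.
makeSingleSiteCohort <- function(coreScores, marker = "PSMA") {
  IHCCohort(data.frame(patient_id = "P1", site_id = "S1",
                       anatomic_site = "liver", marker = marker,
                       core_id = sprintf("c%d", seq_along(coreScores)),
                       h_score = coreScores, stringsAsFactors = FALSE))
}

# Fabricated per-cohort DE result rows for consensus-rule tests.
makeDeRows <- function(cohort, genes, log2fc, fdr) {
  data.frame(cohort = cohort, gene = genes, log2fc = log2fc,
             p_value = fdr, fdr = fdr,
             mean_expr_low = 0, mean_expr_high = 0,
             stringsAsFactors = FALSE)
}
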