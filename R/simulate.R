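## Synthetic-cohort generator with planted, recorded ground truth.
## Defaults emulate a published rapid-autopsy study design: ~52 rapid-autopsy patients,
## median 7 metastatic sites each (range 1-21), 2 duplicate cores per
## site, a bimodal PSMA H-score distribution with three patient-level
## patterns, four AR/NE subtypes, FOLH1 mRNA coupled linearly to the
## H-score, a shared planted DE gene set across three cohorts, and qPCR
## Ct values inversely coupled to expression.

#' Simulation configuration
#'
#' All planted parameters of the generator, with defaults chosen to
#' emulate the rapid-autopsy study conditions. Every artifact of a run is
#' a pure function of `(config, seed)`.
#'
#' @param nPatients Number of patients (default 52).
#' @param sitesNBSize,sitesNBMu Negative-binomial size/mean for the
#'   per-patient site count, truncated to `sitesRange` (defaults give
#'   median 7).
#' @param sitesRange Inclusive truncation bounds (default `c(1, 21)`).
#' @param coresPerSite Duplicate cores per site (default 2).
#' @param subtypeMix Named probabilities over the four AR/NE subtypes.
#' @param patternMix Named probabilities over the three patient PSMA
#'   patterns (defaults at the observed study frequencies 0.25/0.44/0.31).
#' @param exactPatternCounts If `TRUE`, plant pattern counts by
#'   largest-remainder rounding of `patternMix * nPatients` instead of
#'   multinomial sampling (13/23/16 at the defaults).
#' @param thetaHet Per-site probability of the high component within a
#'   heterogeneous patient (default 0.5); heterogeneous patients always
#'   receive at least one site of each component.
#' @param hLow,hHigh `c(mean, sd)` of the low and high H-score mixture
#'   components, truncated to `[0, 20]` and `(20, 200]`.
#' @param coreNoiseSd SD of core-level noise around the site's true
#'   H-score (default 8; cores are clipped to `[0, 200]`).
#' @param intraHetFrac Fraction of multi-core sites whose cores are
#'   planted on opposite components (intratumoral heterogeneity;
#'   default 0.05).
#' @param nGenes,nDeGenes Genes per expression matrix and planted DE genes
#'   (defaults 2000 / 100).
#' @param deLog2fc Planted log2 fold change (default 2, i.e. 4-fold).
#' @param baselineMean,baselineSd Per-gene baseline log2 FPKM
#'   distribution (defaults 5, 1.5).
#' @param exprNoiseSd Per-sample log2 noise SD (default 0.5).
#' @param nSamplesPerCohort Samples per expression cohort (default 60).
#' @param mixtureLow Fraction of expression samples drawn from the PSMA-low
#'   H-score component (default 0.5; counts are exact, not sampled).
#' @param folh1Intercept,folh1Slope,folh1NoiseSd Linear coupling of FOLH1
#'   log2 FPKM to the sample's H-score (defaults 1, 0.02, 0.3).
#' @param methIntercept,methSlope,methNoiseSd Linear coupling of delta-Ct
#'   to FOLH1 log2 FPKM (defaults 0.5, 0.8, 0.3; positive slope means
#'   higher expression gives a lower methylation index).
#' @param ctControl Fully methylated control Ct (default 22 cycles).
#' @param seed Integer seed; required by the simulate functions if not set
#'   here.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(nPatients = 52L,
                      sitesNBSize = 2.2, sitesNBMu = 8.5,
                      sitesRange = c(1L, 21L),
                      coresPerSite = 2L,
                      subtypeMix = c("AR+/NE-" = 0.70, "AR+/NE+" = 0.08,
                                     "AR-/NE+" = 0.15, "AR-/NE-" = 0.07),
                      patternMix = c(uniform_low_negative = 0.25,
                                     heterogeneous = 0.44,
                                     uniform_high = 0.31),
                      exactPatternCounts = FALSE,
                      thetaHet = 0.5,
                      hLow = c(mean = 4, sd = 4),
                      hHigh = c(mean = 120, sd = 45),
                      coreNoiseSd = 8,
                      intraHetFrac = 0.05,
                      nGenes = 2000L, nDeGenes = 100L, deLog2fc = 2,
                      baselineMean = 5, baselineSd = 1.5,
                      exprNoiseSd = 0.5,
                      nSamplesPerCohort = 60L, mixtureLow = 0.5,
                      folh1Intercept = 1, folh1Slope = 0.02,
                      folh1NoiseSd = 0.3,
                      methIntercept = 0.5, methSlope = 0.8,
                      methNoiseSd = 0.3, ctControl = 22,
                      seed = NULL) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$patternMix) - 1) > 1e-8 ||
      abs(sum(cfg$subtypeMix) - 1) > 1e-8)
    stop("pattern/subtype probability vectors must sum to 1")
  if (any(cfg$patternMix < 0) || any(cfg$subtypeMix < 0))
    stop("mixture probabilities must be nonnegative")
  stopifnot(cfg$coreNoiseSd >= 0, cfg$exprNoiseSd > 0,
            cfg$hLow[["sd"]] > 0, cfg$hHigh[["sd"]] > 0,
            cfg$nDeGenes <= cfg$nGenes,
            cfg$thetaHet > 0, cfg$thetaHet < 1,
            cfg$intraHetFrac >= 0, cfg$intraHetFrac <= 1)
  structure(cfg, class = "simConfig")
}

## largest-remainder apportionment of n among probabilities p
.apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## truncated normal by rejection (vectorized refill)
.rtrunc <- function(n, mean, sd, lo, hi, loOpen = FALSE) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- if (loOpen) x > lo & x <= hi else x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

.rSiteCount <- function(n, cfg, atLeast = rep(1L, n)) {
  lo <- pmax(cfg$sitesRange[1], rep_len(atLeast, n))
  hi <- cfg$sitesRange[2]
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnbinom(length(todo), size = cfg$sitesNBSize,
                        mu = cfg$sitesNBMu)
    ok <- x >= lo[todo] & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

.ANATOMIC_PROBS <- c(bone_vertebral = 0.25, bone_nonvertebral = 0.25,
                     lymph_node = 0.20, liver = 0.12, adrenal = 0.06,
                     prostate = 0.05, lung = 0.04, other = 0.03)

#' Simulate a multi-site IHC cohort with planted truth
#'
#' Draws a PSMA pattern per patient; uniform patients take all site
#' scores from one H-score mixture component, heterogeneous patients mix
#' components per site (at least one site of each). Core scores are the
#' site's true score plus Gaussian noise, clipped to `[0, 200]`. A small
#' fraction of multi-core sites plants intratumoral heterogeneity by
#' putting cores on opposite components. AR and SYP marker cores
#' consistent with each site's subtype are emitted so the subtype-calling
#' pipeline can run end to end.
#'
#' @param config A [simConfig()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: `cohort` (an [IHCCohort-class]) and `truth` (planted
#'   per-patient patterns, per-site true H-scores/statuses/subtypes, the
#'   exact equal-weight intertumoral and intratumoral pair-difference
#'   means `true_d_inter` / `true_d_intra`, the config and the seed).
#' @export
simulateCohort <- function(config = simConfig(), seed = config$seed) {
  if (is.null(seed)) stop("a seed is required (argument or config$seed)")
  cfg <- config
  set.seed(seed)
  patterns <- if (cfg$exactPatternCounts) {
    counts <- .apportion(cfg$nPatients, cfg$patternMix)
    sample(rep(names(cfg$patternMix), counts))
  } else {
    sample(names(cfg$patternMix), cfg$nPatients, replace = TRUE,
           prob = cfg$patternMix)
  }
  patientIds <- sprintf("P%03d", seq_len(cfg$nPatients))
  deathYear <- sample(2003:2019, cfg$nPatients, replace = TRUE)
  nSites <- .rSiteCount(cfg$nPatients, cfg,
                        atLeast = ifelse(patterns == "heterogeneous", 2L, 1L))
  siteRows <- vector("list", cfg$nPatients)
  for (i in seq_len(cfg$nPatients)) {
    k <- nSites[i]
    comp <- switch(patterns[i],
                   uniform_low_negative = rep("low", k),
                   uniform_high = rep("high", k),
                   heterogeneous = {
                     c0 <- ifelse(stats::runif(k) < cfg$thetaHet,
                                  "high", "low")
                     if (length(unique(c0)) == 1L)
                       c0[sample.int(k, 1L)] <-
                         setdiff(c("low", "high"), c0[1])
                     c0
                   })
    trueH <- numeric(k)
    trueH[comp == "low"] <- .rtrunc(sum(comp == "low"), cfg$hLow[["mean"]],
                                    cfg$hLow[["sd"]], 0, 20)
    trueH[comp == "high"] <- .rtrunc(sum(comp == "high"),
                                     cfg$hHigh[["mean"]], cfg$hHigh[["sd"]],
                                     20, 200, loOpen = TRUE)
    subtype <- sample(names(cfg$subtypeMix), 1, prob = cfg$subtypeMix)
    siteSubtype <- ifelse(stats::runif(k) < 0.9, subtype,
                          sample(names(cfg$subtypeMix), k, replace = TRUE,
                                 prob = cfg$subtypeMix))
    siteRows[[i]] <- data.frame(
      patient_id = patientIds[i],
      site_id = sprintf("S%02d", seq_len(k)),
      anatomic_site = sample(names(.ANATOMIC_PROBS), k, replace = TRUE,
                             prob = .ANATOMIC_PROBS),
      component = comp, true_h = trueH, subtype = siteSubtype,
      death_year = deathYear[i], stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, siteRows)
  nSite <- nrow(sites)
  nc <- cfg$coresPerSite
  intraHet <- nc >= 2L & stats::runif(nSite) < cfg$intraHetFrac
  coreComp <- matrix(rep(sites$component, each = nc), nrow = nc)
  for (j in which(intraHet)) {
    flip <- sample.int(nc, max(1L, floor(nc / 2)))
    coreComp[flip, j] <- setdiff(c("low", "high"), sites$component[j])
  }
  coreTrueH <- matrix(rep(sites$true_h, each = nc), nrow = nc)
  nFlip <- sum(coreComp != rep(sites$component, each = nc))
  if (nFlip) {
    flipped <- coreComp != matrix(rep(sites$component, each = nc), nrow = nc)
    lowFlip <- flipped & coreComp == "low"
    highFlip <- flipped & coreComp == "high"
    coreTrueH[lowFlip] <- .rtrunc(sum(lowFlip), cfg$hLow[["mean"]],
                                  cfg$hLow[["sd"]], 0, 20)
    coreTrueH[highFlip] <- .rtrunc(sum(highFlip), cfg$hHigh[["mean"]],
                                   cfg$hHigh[["sd"]], 20, 200, loOpen = TRUE)
  }
  coreObs <- pmin(pmax(coreTrueH +
                         stats::rnorm(length(coreTrueH), 0,
                                      cfg$coreNoiseSd), 0), 200)
  psmaCores <- data.frame(
    patient_id = rep(sites$patient_id, each = nc),
    site_id = rep(sites$site_id, each = nc),
    anatomic_site = rep(sites$anatomic_site, each = nc),
    marker = "PSMA",
    core_id = rep(sprintf("c%d", seq_len(nc)), nSite),
    h_score = as.vector(coreObs),
    death_year = rep(sites$death_year, each = nc),
    stringsAsFactors = FALSE)
  markerCores <- do.call(rbind, lapply(c("AR", "SYP"), function(mk) {
    pos <- if (mk == "AR") grepl("AR\\+", sites$subtype)
           else grepl("NE\\+", sites$subtype)
    trueM <- ifelse(pos,
                    .rtrunc(nSite, 150, 30, 20, 200, loOpen = TRUE),
                    .rtrunc(nSite, 5, 5, 0, 20))
    obs <- pmin(pmax(rep(trueM, each = nc) +
                       stats::rnorm(nSite * nc, 0, cfg$coreNoiseSd),
                     0), 200)
    data.frame(patient_id = rep(sites$patient_id, each = nc),
               site_id = rep(sites$site_id, each = nc),
               anatomic_site = rep(sites$anatomic_site, each = nc),
               marker = mk,
               core_id = rep(sprintf("c%d", seq_len(nc)), nSite),
               h_score = as.vector(obs),
               death_year = rep(sites$death_year, each = nc),
               stringsAsFactors = FALSE)
  }))
  cohort <- IHCCohort(rbind(psmaCores, markerCores))

  sites$true_status <- ifelse(sites$component == "low",
                              "low_negative", "positive")
  dInter <- vapply(split(sites$true_status, sites$patient_id), function(s) {
    if (length(s) < 2) NA_real_
    else pairDifferenceProbability(countLabels(s))
  }, numeric(1))
  coreStatus <- ifelse(coreComp == "low", "low_negative", "positive")
  dIntra <- if (nc >= 2)
    apply(coreStatus, 2, function(s)
      pairDifferenceProbability(countLabels(s)))
  else rep(NA_real_, nSite)
  truth <- list(
    patterns = stats::setNames(patterns, patientIds),
    sites = sites,
    core_status = coreStatus,
    true_d_inter = mean(dInter, na.rm = TRUE),
    true_d_intra = if (all(is.na(dIntra))) NA_real_
                   else mean(dIntra, na.rm = TRUE),
    config = cfg, seed = as.integer(seed))
  list(cohort = cohort, truth = truth)
}

#' Simulate three expression cohorts with a shared planted DE gene set
#'
#' Each cohort draws `nSamplesPerCohort` samples: an exact
#' `mixtureLow` fraction from the PSMA-low H-score component and the rest
#' from the high component. FOLH1 log2 FPKM is linear in the latent
#' H-score plus noise; all other genes get a per-gene baseline plus
#' sample noise, and each planted DE gene is shifted by `deLog2fc/2` in
#' opposite directions in the two groups (a total between-group log2
#' difference of `deLog2fc`; direction random per gene, shared across the
#' three cohorts).
#'
#' @param config A [simConfig()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param cohortNames Names of the generated data sets.
#' @return List: `cohorts` (list of three [ExpressionCohort-class] with
#'   subtype `"AR+/NE-"` and `psma_group` left unassigned) and `truth`
#'   (planted DE genes with directions, per-cohort true groups and latent
#'   H-scores, coupling parameters, config, seed).
#' @export
simulateExpression <- function(config = simConfig(), seed = config$seed,
                               cohortNames = c("pdx", "rapid_autopsy",
                                               "clinical_met")) {
  if (is.null(seed)) stop("a seed is required (argument or config$seed)")
  cfg <- config
  if (cfg$nDeGenes > cfg$nGenes - 1L)
    stop("nDeGenes must leave room for FOLH1 among nGenes")
  set.seed(seed)
  genes <- c("FOLH1", sprintf("GENE%04d", seq_len(cfg$nGenes - 1L)))
  deGenes <- sample(genes[-1L], cfg$nDeGenes)
  deDir <- stats::setNames(sample(c(1, -1), cfg$nDeGenes, replace = TRUE),
                           deGenes)
  n <- cfg$nSamplesPerCohort
  nLow <- as.integer(round(n * cfg$mixtureLow))
  cohorts <- list(); truthGroups <- list(); truthH <- list()
  for (cn in cohortNames) {
    comp <- sample(rep(c("low", "high"), c(nLow, n - nLow)))
    H <- numeric(n)
    H[comp == "low"] <- .rtrunc(sum(comp == "low"), cfg$hLow[["mean"]],
                                cfg$hLow[["sd"]], 0, 20)
    H[comp == "high"] <- .rtrunc(sum(comp == "high"), cfg$hHigh[["mean"]],
                                 cfg$hHigh[["sd"]], 20, 200, loOpen = TRUE)
    folh1 <- cfg$folh1Intercept + cfg$folh1Slope * H +
      stats::rnorm(n, 0, cfg$folh1NoiseSd)
    baseline <- stats::rnorm(length(genes) - 1L, cfg$baselineMean,
                             cfg$baselineSd)
    L <- matrix(baseline, nrow = length(genes) - 1L, ncol = n) +
      matrix(stats::rnorm((length(genes) - 1L) * n, 0, cfg$exprNoiseSd),
             ncol = n)
    rownames(L) <- genes[-1L]
    isLow <- comp == "low"
    L[deGenes, isLow] <- L[deGenes, isLow] + deDir * cfg$deLog2fc / 2
    L[deGenes, !isLow] <- L[deGenes, !isLow] - deDir * cfg$deLog2fc / 2
    mat <- rbind(FOLH1 = 2^folh1, 2^L)
    colnames(mat) <- sprintf("%s_s%03d", cn, seq_len(n))
    meta <- data.frame(sample_id = colnames(mat), subtype = "AR+/NE-",
                       stringsAsFactors = FALSE)
    cohorts[[cn]] <- ExpressionCohort(mat, sampleMeta = meta,
                                      cohortName = cn)
    truthGroups[[cn]] <- stats::setNames(comp, colnames(mat))
    truthH[[cn]] <- stats::setNames(H, colnames(mat))
  }
  list(cohorts = cohorts,
       truth = list(de_genes = deGenes, de_direction = deDir,
                    groups = truthGroups, h_scores = truthH,
                    folh1 = c(intercept = cfg$folh1Intercept,
                              slope = cfg$folh1Slope,
                              noise_sd = cfg$folh1NoiseSd),
                    config = cfg, seed = as.integer(seed)))
}

#' Simulate COMPARE-MS Ct values inversely coupled to expression
#'
#' For each sample of the first expression cohort, delta-Ct =
#' `methIntercept + methSlope * FOLH1 log2 FPKM + noise` with a positive
#' slope, so higher expression gives a larger delta-Ct and hence a lower
#' methylation index (the planted inverse methylation--expression
#' relation).
#'
#' @param config A [simConfig()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param expression Result of [simulateExpression()]; generated at
#'   `seed` when omitted.
#' @return List: `ct` (data.frame `sample_id`, `ct_sample`, `ct_control`),
#'   `expr` (the FOLH1 log2 FPKM used), and `truth` (planted slope terms,
#'   config, seed).
#' @export
simulateMethylation <- function(config = simConfig(), seed = config$seed,
                                expression = NULL) {
  if (is.null(seed)) stop("a seed is required (argument or config$seed)")
  cfg <- config
  if (is.null(expression))
    expression <- simulateExpression(cfg, seed = seed)
  set.seed(seed + 1L)
  x <- expression$cohorts[[1L]]
  expr <- log2(fpkm(x)["FOLH1", ] + 1)
  dCt <- cfg$methIntercept + cfg$methSlope * expr +
    stats::rnorm(length(expr), 0, cfg$methNoiseSd)
  dCt <- pmax(dCt, 0)  # sample cannot amplify before the fully methylated control
  ct <- data.frame(sample_id = names(expr),
                   ct_sample = cfg$ctControl + dCt,
                   ct_control = cfg$ctControl,
                   stringsAsFactors = FALSE)
  list(ct = ct, expr = expr,
       truth = list(meth_intercept = cfg$methIntercept,
                    meth_slope = cfg$methSlope,
                    meth_noise_sd = cfg$methNoiseSd,
                    config = cfg, seed = as.integer(seed)))
}

#' Emit per-CpG coverage consistent with a methylation index
#'
#' Writes CpG calls whose coverage-weighted region methylation matches the
#' given index up to binomial noise — useful for exercising the coverage
#' reader and region summarizer against a known truth.
#'
#' @param mi Methylation index in percent (0--100).
#' @param region A `GRanges` or region string; CpGs are placed evenly
#'   inside it.
#' @param nCpgs Number of CpGs (default 10).
#' @param coverage Per-CpG read coverage (default 30).
#' @param seed Integer seed.
#' @return A `GRanges` of CpG calls (see [readBismarkCoverage()]).
#' @export
simulateCoverage <- function(mi, region, nCpgs = 10L, coverage = 30L, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (is.character(region)) region <- parseRegion(region)
  set.seed(seed)
  pos <- unique(round(seq(GenomicRanges::start(region),
                          GenomicRanges::end(region),
                          length.out = nCpgs)))
  meth <- stats::rbinom(length(pos), coverage, mi / 100)
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(region)),
    IRanges::IRanges(start = pos, end = pos),
    methylated = meth, unmethylated = coverage - meth,
    fraction = meth / coverage)
}
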