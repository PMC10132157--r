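## Cohort summary report and the end-to-end pipeline driver.

#' Summarize a scored cohort
#'
#' Counts and percentages of the three patient PSMA patterns, the
#' negative-site histogram, per-anatomic-site H-score means and ranges,
#' and per-subtype H-score means.
#'
#' @param cohort An [IHCCohort-class].
#' @param cutoff Low/negative H-score cutoff (default 20).
#' @param marker Marker symbol (default `"PSMA"`).
#' @param thresholds [subtypeThresholds()] for the subtype summary (used
#'   only when the axis markers are present in the table).
#' @return A list of class `cohortSummary`: `patterns` (data.frame
#'   pattern, count, percent), `negative_sites` (named histogram),
#'   `site_stats`, `subtype_stats` (or `NULL`), `n_patients`.
#' @export
summarizeCohort <- function(cohort, cutoff = 20, marker = "PSMA",
                            thresholds = subtypeThresholds()) {
  pat <- classifyPatientPattern(cohort, cutoff = cutoff, marker = marker)
  if (nrow(pat) == 0L) warning("no classifiable patient in cohort")
  counts <- table(factor(pat$pattern, levels = .PATTERNS))
  patterns <- data.frame(
    pattern = .PATTERNS, count = as.integer(counts),
    percent = if (nrow(pat)) round(100 * as.integer(counts) / nrow(pat), 1)
              else rep(NA_real_, 3L),
    stringsAsFactors = FALSE)
  sites <- siteHScores(cohort, marker)
  sites <- sites[!is.na(sites$h_score), , drop = FALSE]
  groups <- split(sites$h_score, sites$anatomic_site)
  siteStats <- data.frame(
    anatomic_site = names(groups), n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  markers <- unique(coreData(cohort)$marker)
  subtypeStats <- NULL
  if (any(thresholds$arMarkers %in% markers) &&
      any(thresholds$neMarkers %in% markers)) {
    st <- siteSubtypes(cohort, thresholds)
    key <- paste(st$patient_id, st$site_id, sep = "\r")
    skey <- paste(sites$patient_id, sites$site_id, sep = "\r")
    sites$subtype <- st$subtype[match(skey, key)]
    bySub <- split(sites$h_score, sites$subtype)
    subtypeStats <- data.frame(
      subtype = names(bySub), n = lengths(bySub),
      mean = vapply(bySub, mean, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(patterns = patterns,
                 negative_sites = countNegativeSites(cohort, cutoff, marker),
                 site_stats = siteStats, subtype_stats = subtypeStats,
                 n_patients = nrow(pat), cutoff = cutoff, marker = marker),
            class = "cohortSummary")
}

#' @export
print.cohortSummary <- function(x, ...) {
  cat("Cohort summary (", x$marker, ", cutoff ", x$cutoff, "): ",
      x$n_patients, " classifiable patients\n", sep = "")
  p <- x$patterns
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-22s %3d (%s%%)\n", p$pattern[i], p$count[i],
                format(p$percent[i])))
  cat("  negative-site histogram:",
      paste(names(x$negative_sites), x$negative_sites, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic or file-driven analysis pipeline
#'
#' Executes scoring, pattern classification, the cohort summary,
#' inter- and intratumoral heterogeneity estimation, three-cohort
#' differential expression with consensus (and optional target
#' refinement), and the methylation--expression association; writes every
#' stage's tables plus a run manifest to `outDir`. With
#' `config$simulate = TRUE` (default) all inputs come from the package's
#' generator under `config$sim`; otherwise `config$cohort_table`,
#' `config$expression` (paths) and `config$expression_meta` are read.
#'
#' @param config List: `seed` (required), `simulate` (default TRUE),
#'   `sim` (a [simConfig()]), `cutoff` (default 20), `fdr_max`, `fc_min`,
#'   `min_cohorts`, `n_pairs`, `n_boot`, `alpha`, optional `targets`
#'   (named list of gene-list paths), and input paths when
#'   `simulate = FALSE`.
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly. Stage failure aborts with the stage name
#'   and cause.
#' @export
runPipeline <- function(config, outDir) {
  if (is.null(config$seed)) stop("config$seed is required")
  defaults <- list(simulate = TRUE, cutoff = 20, fdr_max = 0.05,
                   fc_min = 2.0, min_cohorts = 2L, n_pairs = 1000L,
                   n_boot = 2000L, alpha = 0.05)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config[["sim"]])) config[["sim"]] <- simConfig()
  if (!isTRUE(config$simulate)) {
    for (p in c(config$cohort_table, unlist(config$expression),
                config$expression_meta))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- as.integer(config$seed)
  outputs <- character(0)

  cohortStage <- stage("cohort", {
    if (isTRUE(config$simulate)) {
      sim <- simulateCohort(config[["sim"]], seed = seed)
      outputs <- c(outputs, writeCohortTable(sim$cohort,
                                             file.path(outDir, "cohort.tsv")))
      sim$cohort
    } else readCohortTable(config$cohort_table)
  })

  stage("scoring", {
    scored <- siteHScores(cohortStage)
    scored$psma_status <- classifyPsmaStatus(scored$h_score, config$cutoff)
    outputs <- c(outputs, .writeTsv(scored, file.path(outDir, "scored.tsv")))
    patterns <- classifyPatientPattern(cohortStage, cutoff = config$cutoff)
    outputs <- c(outputs,
                  .writeTsv(patterns, file.path(outDir, "patterns.tsv")))
    summ <- summarizeCohort(cohortStage, cutoff = config$cutoff)
    outputs <- c(outputs,
                  .writeTsv(summ$patterns,
                            file.path(outDir, "pattern_summary.tsv")))
    hist <- data.frame(bin = names(summ$negative_sites),
                       count = as.integer(summ$negative_sites))
    outputs <- c(outputs,
                  .writeTsv(hist, file.path(outDir, "negative_sites.tsv")))
  })

  hetTab <- stage("heterogeneity", {
    rows <- lapply(c("intertumoral", "intratumoral"), function(lv) {
      h <- heterogeneitySummary(cohortStage, level = lv,
                                nPairs = config$n_pairs,
                                nBoot = config$n_boot,
                                alpha = config$alpha,
                                seed = seed + match(lv, c("intertumoral",
                                                          "intratumoral")),
                                cutoff = config$cutoff)
      data.frame(level = lv, estimate = h@estimate, ci_low = h@ciLow,
                 ci_high = h@ciHigh, n_units_used = h@nUnitsUsed,
                 n_pairs = h@nPairs, n_boot = h@nBoot, seed = h@seed)
    })
    tab <- do.call(rbind, rows)
    outputs <- c(outputs, .writeTsv(tab, file.path(outDir, "het.tsv")))
    tab
  })

  deStage <- stage("differential_expression", {
    cohorts <- if (isTRUE(config$simulate)) {
      simulateExpression(config[["sim"]], seed = seed + 10L)$cohorts
    } else {
      mapply(readExpressionMatrix, config$expression,
             MoreArgs = list(metaPath = config$expression_meta),
             SIMPLIFY = FALSE)
    }
    results <- lapply(cohorts, function(x) {
      x <- restrictToSubtype(x, "AR+/NE-")
      x <- assignPsmaGroups(x)
      x <- filterMinExpression(x)
      differentialExpression(x)
    })
    for (r in results)
      outputs <- c(outputs,
                    .writeTsv(r, file.path(outDir,
                                           paste0("de_", r$cohort[1],
                                                  ".tsv"))))
    cons <- consensusGenes(results, fdrMax = config$fdr_max,
                           fcMin = config$fc_min,
                           minCohorts = config$min_cohorts)
    consTab <- rbind(cons$up_in_low, cons$up_in_high)
    outputs <- c(outputs,
                  .writeTsv(consTab, file.path(outDir, "consensus.tsv")))
    if (!is.null(config$targets)) {
      for (nm in names(config$targets)) {
        gl <- readGeneList(config$targets[[nm]])
        tg <- filterTargetLists(results, gl, fdrMax = config$fdr_max,
                                fcMin = config$fc_min)
        ranked <- rankByMeanFC(tg$targets, k = 20L)
        outputs <- c(outputs,
                      .writeTsv(ranked,
                                file.path(outDir,
                                          paste0("targets_", nm, ".tsv"))))
      }
    }
    list(results = results, consensus = cons)
  })

  stage("methylation", {
    meth <- simulateMethylation(config[["sim"]], seed = seed + 20L)
    mi <- methylationIndex(meth$ct$ct_sample, meth$ct$ct_control)
    miTab <- cbind(meth$ct, mi)
    outputs <- c(outputs, .writeTsv(miTab, file.path(outDir, "mi.tsv")))
    assoc <- methylationExpressionAssociation(mi$mi, meth$expr)
    outputs <- c(outputs,
                  .writeTsv(as.data.frame(assoc),
                            file.path(outDir, "meth_expr_association.tsv")))
  })

  stage("manifest", {
    manifest <- list(
      package = "PSMAhet",
      version = as.character(utils::packageVersion("PSMAhet")),
      seed = seed,
      config = config[setdiff(names(config), "sim")],
      sim_config = unclass(config[["sim"]]),
      outputs = stats::setNames(
        as.character(tools::md5sum(sort(outputs))),
        basename(sort(outputs))),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  })
  invisible(outDir)
}
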