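## Orchestration of the full stepwise analysis and the structured report.

defaultConfig <- function() {
  list(meth_threshold = "derive", age_cutoff = 65, alpha = 0.05,
       include_sex = FALSE, ties = "efron",
       outlier_action = "flag_only", outlier_quantile = 0.975,
       site_ids = 72:83)
}

#' Resolve an analysis configuration
#'
#' Merges user keys over the defaults, rejecting unknown keys and invalid
#' values. Recognised keys: \code{meth_threshold} (integer or "derive"),
#' \code{age_cutoff}, \code{alpha}, \code{include_sex}, \code{ties}
#' (efron|breslow), \code{outlier_action} (flag_only|exclude_and_rerun),
#' \code{outlier_quantile}, \code{site_ids}.
#'
#' @param config Named list of overrides (possibly empty).
#' @return Validated configuration list.
#' @export
resolveConfig <- function(config = list()) {
  base <- defaultConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    gzConfigError("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  if (!(identical(cfg$meth_threshold, "derive") ||
        (is.numeric(cfg$meth_threshold) && length(cfg$meth_threshold) == 1 &&
         cfg$meth_threshold == round(cfg$meth_threshold) && cfg$meth_threshold >= 1)))
    gzConfigError("meth_threshold must be a positive integer or \"derive\"")
  if (!is.numeric(cfg$age_cutoff) || length(cfg$age_cutoff) != 1)
    gzConfigError("age_cutoff must be a single number")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    gzConfigError("alpha must lie strictly between 0 and 1")
  if (!cfg$ties %in% c("efron", "breslow"))
    gzConfigError("ties must be \"efron\" or \"breslow\"")
  if (!cfg$outlier_action %in% c("flag_only", "exclude_and_rerun"))
    gzConfigError("outlier_action must be \"flag_only\" or \"exclude_and_rerun\"")
  if (!is.numeric(cfg$outlier_quantile) || cfg$outlier_quantile <= 0 ||
      cfg$outlier_quantile >= 1)
    gzConfigError("outlier_quantile must lie strictly between 0 and 1")
  cfg$site_ids <- as.integer(cfg$site_ids)
  if (!length(cfg$site_ids) || anyNA(cfg$site_ids))
    gzConfigError("site_ids must be a non-empty integer vector")
  cfg$include_sex <- isTRUE(cfg$include_sex)
  cfg
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (is.null(attr(e, "gzStage"))) {
      e$message <- sprintf("[stage: %s] %s", stage, conditionMessage(e))
      attr(e, "gzStage") <- stage
    }
    stop(e)
  })
}

## core analysis on aggregated samples + clinical (shared by the main pass
## and the exclude_and_rerun pass)
analyzeAggregated <- function(samples, clinical, cfg) {
  data <- assembleCohort(samples, clinical)
  if (nrow(data) < 2) gzDataError("fewer than 2 samples with clinical records")
  M <- if (identical(cfg$meth_threshold, "derive")) {
    withStage("derive_threshold", deriveBinaryThreshold(samples))
  } else as.integer(cfg$meth_threshold)
  screen <- withStage("univariate_screen",
                      univariateScreen(data, M, cfg$age_cutoff, cfg$ties))
  decision <- withStage("candidate_sweep",
                        sweepCandidates(data, M, cfg$age_cutoff,
                                        cfg$include_sex, cfg$alpha, cfg$ties))
  list(data = data, M = M, screen = screen, decision = decision)
}

decisionSection <- function(core) {
  dec <- core$decision
  list(
    meth_threshold = core$M,
    optimal = if (is.null(dec@optimal)) "none" else dec@optimal,
    n_candidates = sum(!is.na(vapply(dec@candidates, function(cr) cr@g, integer(1)))),
    rationale = dec@rationale,
    candidate_table = candidateTable(dec))
}

#' Run the full gray-zone analysis
#'
#' Executes the stepwise method end to end: read the two input tables,
#' exclude failed runs, aggregate replicates, summarise per-CpG
#' distributions and replicate variability, flag multivariate outliers,
#' resolve the methylated threshold (given or derived by the 50/50 rule),
#' assess replicate discordance under the binary and (if found) optimal
#' classification, run the univariate screen, sweep the candidate gray
#' zones, and select the optimum. The result is a deterministic structured
#' report; with \code{outDir} set, the JSON report, the candidate TSV and
#' per-category Kaplan-Meier curves are written there.
#'
#' @param pyroPath Path to the pyrosequencing run table.
#' @param clinicalPath Path to the clinical table.
#' @param config Named list of configuration overrides (see
#'   \code{\link{resolveConfig}}).
#' @param outDir Optional output directory.
#' @return The report, invisibly a list; see the package vignette for the
#'   section layout.
#' @export
runGrayZoneAnalysis <- function(pyroPath, clinicalPath, config = list(),
                                outDir = NULL) {
  cfg <- resolveConfig(config)
  runs <- withStage("read_pyro", readPyroRuns(pyroPath, cfg$site_ids))
  clinical <- withStage("read_clinical", readClinical(clinicalPath))
  split <- withStage("exclude_failed_runs", excludeFailedRuns(runs))
  if (!nrow(split$kept)) gzDataError("all runs failed QC; nothing to analyse")
  samples <- withStage("aggregate_replicates", aggregateReplicates(split$kept))
  qc <- withStage("qc_summary", cpgSummary(samples))
  d2 <- withStage("mahalanobis", mahalanobisDistances(samples))
  outliers <- withStage("flag_outliers",
                        flagOutliers(d2, length(cfg$site_ids),
                                     cfg$outlier_quantile, cfg$outlier_action))
  core <- analyzeAggregated(samples, clinical, cfg)
  repSd <- withStage("replicate_sd",
                     tryCatch(replicateSdSummary(samples, core$M),
                              gzDataError = function(e) list(
                                mean_sd_all = NA_real_,
                                mean_sd_below_threshold = NA_real_)))
  discBinary <- detectDiscordant(split$kept, M = core$M)
  optim <- core$decision@optimal
  discOptimal <- if (!is.null(optim))
    detectDiscordant(split$kept, M = optim$M, g = optim$g) else character()

  rerun <- NULL
  if (cfg$outlier_action == "exclude_and_rerun" && length(outliers$flagged)) {
    keepSamples <- samples[!samples$sample_id %in% outliers$flagged, , drop = FALSE]
    cfg2 <- cfg
    cfg2$meth_threshold <- core$M   # compare like for like: same threshold
    core2 <- withStage("rerun_without_outliers",
                       analyzeAggregated(keepSamples, clinical, cfg2))
    rerun <- decisionSection(core2)
  }

  report <- list(
    meta = list(
      tool = "grayzone",
      version = as.character(utils::packageVersion("grayzone")),
      config = cfg,
      n_runs_total = nrow(runs),
      n_runs_excluded = nrow(split$excluded),
      excluded_run_ids = paste(split$excluded$sample_id,
                               split$excluded$run_id, sep = ":"),
      n_samples = nrow(samples),
      n_analysed = nrow(core$data),
      dropped_no_clinical = attr(core$data, "droppedSamples"),
      dropped_no_methylation = attr(core$data, "droppedClinical")),
    qc = list(
      per_site = qc$per_site,
      correlation = list(sites = colnames(qc$correlation),
                         matrix = qc$correlation),
      cohort_mean_methylation = qc$cohort_mean,
      cohort_sd_methylation = qc$cohort_sd,
      replicate_sd = repSd,
      discordant_binary = discBinary,
      discordant_optimal = discOptimal),
    outliers = list(
      cutoff = outliers$cutoff, quantile = outliers$quantile,
      action = outliers$action, flagged = outliers$flagged,
      n_flagged = length(outliers$flagged),
      distances = as.list(outliers$distances)),
    univariate = core$screen,
    decision = decisionSection(core),
    rerun_without_outliers = rerun)

  if (!is.null(outDir)) writeReport(report, core, outDir)
  invisible(structure(report, core = core))
}

## matrix -> row-major list with labels for JSON
matrixToJSON <- function(m) {
  lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
}

#' Write the analysis report to disk
#'
#' Emits \code{report.json} (the full structured report, with non-finite
#' numbers serialised as "-inf"/"inf" tokens), \code{candidates.tsv}, and
#' \code{km_curves.tsv} holding the per-category Kaplan-Meier step
#' functions (time, survival, confidence bands) under the selected (or
#' binary, when none selected) classification. No timestamps are written,
#' so identical inputs yield byte-identical files.
#'
#' @param report Report list from \code{\link{runGrayZoneAnalysis}}.
#' @param core Internal core results (attribute of the report).
#' @param outDir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, core, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jr <- report
  jr$qc$correlation$matrix <- matrixToJSON(jr$qc$correlation$matrix)
  jsonPath <- file.path(outDir, "report.json")
  jsonlite::write_json(sanitizeForJSON(jr), jsonPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", null = "null")

  tsvPath <- file.path(outDir, "candidates.tsv")
  writeCandidateTable(core$decision, tsvPath)

  optim <- core$decision@optimal
  data <- core$data
  cats <- if (is.null(optim)) {
    categorize(data$mean_methylation, M = core$M)
  } else {
    categorize(data$mean_methylation, M = optim$M, g = optim$g)
  }
  kmRows <- lapply(levels(cats), function(lv) {
    idx <- cats == lv
    if (!any(idx)) return(NULL)
    km <- kmFit(data$os_months[idx], data$event[idx])
    data.frame(category = lv, time = km@time, n_risk = km@nRisk,
               n_event = km@nEvent, survival = km@surv,
               lower = km@lower, upper = km@upper)
  })
  kmPath <- file.path(outDir, "km_curves.tsv")
  utils::write.table(do.call(rbind, kmRows), kmPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(jsonPath, tsvPath, kmPath))
}

#' Run the QC-only pipeline
#'
#' Reads the run table, excludes failed runs, aggregates replicates, and
#' reports per-CpG distribution summaries, the correlation matrix,
#' replicate variability and the Mahalanobis outlier flags -- stopping
#' before any survival modelling.
#'
#' @inheritParams runGrayZoneAnalysis
#' @return The QC report list, invisibly; written to
#'   \code{outDir/qc_report.json} when \code{outDir} is given.
#' @export
runQC <- function(pyroPath, config = list(), outDir = NULL) {
  cfg <- resolveConfig(config)
  runs <- withStage("read_pyro", readPyroRuns(pyroPath, cfg$site_ids))
  split <- withStage("exclude_failed_runs", excludeFailedRuns(runs))
  if (!nrow(split$kept)) gzDataError("all runs failed QC; nothing to analyse")
  samples <- withStage("aggregate_replicates", aggregateReplicates(split$kept))
  qc <- withStage("qc_summary", cpgSummary(samples))
  d2 <- withStage("mahalanobis", mahalanobisDistances(samples))
  outliers <- withStage("flag_outliers",
                        flagOutliers(d2, length(cfg$site_ids),
                                     cfg$outlier_quantile, cfg$outlier_action))
  repSd <- tryCatch({
    M <- if (identical(cfg$meth_threshold, "derive"))
      deriveBinaryThreshold(samples) else as.integer(cfg$meth_threshold)
    c(replicateSdSummary(samples, M), list(threshold = M))
  }, gzDataError = function(e) list(mean_sd_all = NA_real_,
                                    mean_sd_below_threshold = NA_real_,
                                    threshold = NA_integer_))
  report <- list(
    meta = list(tool = "grayzone-qc",
                version = as.character(utils::packageVersion("grayzone")),
                config = cfg,
                n_runs_total = nrow(runs),
                n_runs_excluded = nrow(split$excluded),
                n_samples = nrow(samples)),
    qc = list(per_site = qc$per_site,
              correlation = list(sites = colnames(qc$correlation),
                                 matrix = matrixToJSON(qc$correlation)),
              cohort_mean_methylation = qc$cohort_mean,
              cohort_sd_methylation = qc$cohort_sd,
              replicate_sd = repSd),
    outliers = list(cutoff = outliers$cutoff, quantile = outliers$quantile,
                    action = outliers$action, flagged = outliers$flagged,
                    n_flagged = length(outliers$flagged),
                    distances = as.list(outliers$distances)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(sanitizeForJSON(report),
                         file.path(outDir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", null = "null")
  }
  invisible(report)
}
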