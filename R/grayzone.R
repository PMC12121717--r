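## The survival-supervised gray-zone search: categorisation, candidate
## enumeration, univariate screen, per-candidate multivariate Cox fits with
## the gray zone as reference, nested LRT against the binary model, and
## optimal-gray-zone selection.

#' Classify average methylation into categories
#'
#' Half-open partition of the percent scale: unmethylated [0, g), gray zone
#' [g, M), methylated [M, 100]. With \code{g = NA} the classification is
#' binary: unmethylated [0, M), methylated [M, 100]. Values are compared
#' without rounding; the boundary conventions (unmethylated strictly below
#' g, methylated at or above M) make the gray zone lower bound inclusive.
#'
#' @param x Numeric vector of average methylation percentages in [0, 100].
#' @param M Methylated threshold (integer percent).
#' @param g Gray-zone lower bound, or NA for binary classification.
#' @return Factor with levels unmethylated, gray (three-category only),
#'   methylated.
#' @export
categorize <- function(x, M, g = NA) {
  if (any(x < 0 | x > 100, na.rm = TRUE))
    gzRangeError("methylation values must lie in [0, 100]")
  if (is.na(g)) {
    factor(ifelse(x >= M, "methylated", "unmethylated"),
           levels = c("unmethylated", "methylated"))
  } else {
    if (g < 1 || g >= M)
      gzConfigError("gray-zone lower bound g must satisfy 1 <= g < M")
    factor(ifelse(x >= M, "methylated", ifelse(x >= g, "gray", "unmethylated")),
           levels = c("unmethylated", "gray", "methylated"))
  }
}

#' Enumerate candidate gray zones
#'
#' One candidate per integer lower bound g with 1 <= g <= M - 1: the
#' classification unmethylated [0, g), gray [g, M), methylated [M, 100].
#' With M = 12 this gives the 11 candidate classifications; M = 1 admits
#' none.
#'
#' @param M Methylated threshold (integer percent, >= 1).
#' @return data.frame with columns g and M, ascending in g (zero rows when
#'   M = 1).
#' @export
enumerateCandidates <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1) gzConfigError("methylated threshold M must be >= 1")
  if (M == 1L) return(data.frame(g = integer(0), M = integer(0)))
  data.frame(g = 1:(M - 1L), M = M)
}

#' Assemble per-sample analysis data
#'
#' Joins aggregated methylation with clinical records on sample_id. Samples
#' lacking a clinical record (and clinical records without a surviving
#' sample) are dropped with logged counts; the retained set is what every
#' downstream model is fitted on.
#'
#' @param samples Output of \code{\link{aggregateReplicates}}.
#' @param clinical Output of \code{\link{readClinical}}.
#' @return data.frame with sample_id, mean_methylation, age_years, sex,
#'   os_months, event; attributes \code{droppedSamples} and
#'   \code{droppedClinical} hold the dropped ids.
#' @export
assembleCohort <- function(samples, clinical) {
  keep <- intersect(samples$sample_id, clinical$sample_id)
  droppedS <- setdiff(samples$sample_id, keep)
  droppedC <- setdiff(clinical$sample_id, keep)
  if (length(droppedS))
    message(length(droppedS), " sample(s) dropped: no clinical record")
  if (length(droppedC))
    message(length(droppedC), " clinical record(s) dropped: no methylation data")
  out <- merge(samples[, c("sample_id", "mean_methylation")], clinical,
               by = "sample_id", sort = FALSE)
  out <- out[match(intersect(samples$sample_id, keep), out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "droppedSamples") <- droppedS
  attr(out, "droppedClinical") <- droppedC
  out
}

## model matrix for the category model: age-group indicator, category
## indicators against the gray-zone reference, optional sex
categoryDesign <- function(data, cats, ageCutoff, includeSex) {
  X <- cbind(age_over_cutoff = as.numeric(data$age_years >= ageCutoff))
  if ("gray" %in% levels(cats)) {
    X <- cbind(X,
               methylated = as.numeric(cats == "methylated"),
               unmethylated = as.numeric(cats == "unmethylated"))
  } else {
    X <- cbind(X, methylated = as.numeric(cats == "methylated"))
  }
  if (includeSex) X <- cbind(X, male = as.numeric(data$sex == "male"))
  X
}

#' Fit the binary-classification reference model
#'
#' Multivariate Cox model with the age-group indicator and the binary
#' methylated indicator (reference: unmethylated), on the full assembled
#' cohort. All candidate models are compared against this fit.
#'
#' @param data Output of \code{\link{assembleCohort}}.
#' @param M Methylated threshold.
#' @param ageCutoff Age-group cutoff in years (default 65).
#' @param includeSex Add a male-vs-female indicator (default FALSE).
#' @param ties Tie correction passed to \code{\link{coxFit}}.
#' @return A \linkS4class{CoxPHModel}.
#' @export
fitBinaryModel <- function(data, M, ageCutoff = 65, includeSex = FALSE,
                           ties = "efron") {
  cats <- categorize(data$mean_methylation, M = M)
  X <- categoryDesign(data, cats, ageCutoff, includeSex)
  coxFit(data$os_months, data$event, X, ties = ties)
}

#' Fit one candidate three-category model
#'
#' Fits the multivariate Cox model (age group + category indicators with
#' the gray zone as reference, optional sex) for the classification
#' unmethylated [0, g) / gray [g, M) / methylated [M, 100], computes
#' per-category Kaplan-Meier medians, and tests the candidate against the
#' binary model (fitted on the identical subjects) with a 1-df nested LRT.
#' An empty category makes the contrast inestimable: the result is returned
#' with \code{qualifies = FALSE} and a note, never silently dropped.
#'
#' @inheritParams fitBinaryModel
#' @param g Gray-zone lower bound (integer percent, 1 <= g < M).
#' @param binaryModel Optional pre-fitted binary \linkS4class{CoxPHModel}
#'   (fitted once per sweep); fitted internally when NULL.
#' @param alpha Significance level for the qualification criteria.
#' @return A \linkS4class{CandidateResult}.
#' @export
fitCandidateModel <- function(data, g, M, ageCutoff = 65, includeSex = FALSE,
                              alpha = 0.05, ties = "efron",
                              binaryModel = NULL) {
  cats <- categorize(data$mean_methylation, M = M, g = g)
  counts <- table(cats)
  countsInt <- stats::setNames(as.integer(counts), names(counts))
  kmTab <- do.call(rbind, lapply(levels(cats), function(lv) {
    idx <- cats == lv
    if (!any(idx))
      return(data.frame(category = lv, n = 0L, median_os = NA_real_,
                        median_lower = NA_real_, median_upper = NA_real_))
    km <- kmFit(data$os_months[idx], data$event[idx])
    data.frame(category = lv, n = sum(idx), median_os = km@median,
               median_lower = km@medianCI[1], median_upper = km@medianCI[2])
  }))
  if (is.null(binaryModel))
    binaryModel <- fitBinaryModel(data, M, ageCutoff, includeSex, ties)

  empty <- names(counts)[counts == 0]
  naRes <- function(note) {
    new("CandidateResult", g = as.integer(g), M = as.integer(M),
        counts = countsInt, km = kmTab, model = NULL,
        hrMethVsGray = NA_real_, hrMethCI = c(NA_real_, NA_real_),
        pMethVsGray = NA_real_,
        hrUnmethVsGray = NA_real_, hrUnmethCI = c(NA_real_, NA_real_),
        pUnmethVsGray = NA_real_,
        hrAge = NA_real_, hrAgeCI = c(NA_real_, NA_real_), pAge = NA_real_,
        loglik = NA_real_, scoreStat = NA_real_, scoreP = NA_real_,
        lrtStat = NA_real_, lrtP = NA_real_, scoreDiff = NA_real_,
        qualifies = FALSE, note = note)
  }
  if (length(empty))
    return(naRes(sprintf("inestimable: empty category (%s)",
                         paste(empty, collapse = ", "))))

  X <- categoryDesign(data, cats, ageCutoff, includeSex)
  fit <- tryCatch(
    withCallingHandlers(
      coxFit(data$os_months, data$event, X, ties = ties),
      warning = function(w) invokeRestart("muffleWarning")),
    gzDegeneracyError = function(e) NULL)
  if (is.null(fit))
    return(naRes("inestimable: degenerate design"))

  lrt <- lrtNested(fit, binaryModel)
  hr <- fit@hr; ci <- fit@hrCI; p <- fit@waldP
  qualifies <- isTRUE(hr[["methylated"]] < 1 && p[["methylated"]] < alpha &&
                      hr[["unmethylated"]] > 1 && p[["unmethylated"]] < alpha &&
                      lrt$p < alpha)
  note <- if (!fit@converged) "model did not converge (monotone likelihood)" else ""
  new("CandidateResult", g = as.integer(g), M = as.integer(M),
      counts = countsInt, km = kmTab, model = fit,
      hrMethVsGray = unname(hr[["methylated"]]),
      hrMethCI = unname(ci["methylated", ]),
      pMethVsGray = unname(p[["methylated"]]),
      hrUnmethVsGray = unname(hr[["unmethylated"]]),
      hrUnmethCI = unname(ci["unmethylated", ]),
      pUnmethVsGray = unname(p[["unmethylated"]]),
      hrAge = unname(hr[["age_over_cutoff"]]),
      hrAgeCI = unname(ci["age_over_cutoff", ]),
      pAge = unname(p[["age_over_cutoff"]]),
      loglik = fit@loglikFit, scoreStat = fit@scoreStat, scoreP = fit@scoreP,
      lrtStat = lrt$statistic, lrtP = lrt$p,
      scoreDiff = fit@scoreStat - binaryModel@scoreStat,
      qualifies = qualifies, note = note)
}

## CandidateResult for the binary (no-gray-zone) row of the table
binaryResult <- function(data, M, binaryModel) {
  cats <- categorize(data$mean_methylation, M = M)
  counts <- table(cats)
  kmTab <- do.call(rbind, lapply(levels(cats), function(lv) {
    idx <- cats == lv
    km <- kmFit(data$os_months[idx], data$event[idx])
    data.frame(category = lv, n = sum(idx), median_os = km@median,
               median_lower = km@medianCI[1], median_upper = km@medianCI[2])
  }))
  hr <- binaryModel@hr; ci <- binaryModel@hrCI; p <- binaryModel@waldP
  new("CandidateResult", g = NA_integer_, M = as.integer(M),
      counts = stats::setNames(as.integer(counts), names(counts)),
      km = kmTab, model = binaryModel,
      hrMethVsGray = NA_real_, hrMethCI = c(NA_real_, NA_real_),
      pMethVsGray = NA_real_,
      # in the binary model the reported contrast is unmethylated relative
      # to methylated status absent a gray zone; keep the unmeth column as
      # 1/HR(methylated) so the table mirrors the no-gray-zone row
      hrUnmethVsGray = unname(1 / hr[["methylated"]]),
      hrUnmethCI = unname(rev(1 / ci["methylated", ])),
      pUnmethVsGray = unname(p[["methylated"]]),
      hrAge = unname(hr[["age_over_cutoff"]]),
      hrAgeCI = unname(ci["age_over_cutoff", ]),
      pAge = unname(p[["age_over_cutoff"]]),
      loglik = binaryModel@loglikFit, scoreStat = binaryModel@scoreStat,
      scoreP = binaryModel@scoreP,
      lrtStat = NA_real_, lrtP = NA_real_, scoreDiff = NA_real_,
      qualifies = FALSE, note = "binary reference model")
}

#' Univariate Cox screen
#'
#' Single-covariate Cox fits for sex, age (continuous), age group (>=
#' cutoff), and mean methylation (continuous), plus a per-candidate sweep of
#' univariate three-category fits (gray zone as reference) feeding the
#' per-category survival summaries. A constant covariate marks its row
#' inestimable without aborting the screen.
#'
#' @inheritParams fitBinaryModel
#' @return List: \code{terms} (data.frame term/hr/lower/upper/p/note) and
#'   \code{categories} (per-candidate univariate HRs).
#' @export
univariateScreen <- function(data, M, ageCutoff = 65, ties = "efron") {
  one <- function(term, x) {
    if (max(x) - min(x) == 0)
      return(data.frame(term = term, hr = NA_real_, lower = NA_real_,
                        upper = NA_real_, p = NA_real_,
                        note = "inestimable: constant covariate"))
    fit <- withCallingHandlers(
      coxFit(data$os_months, data$event, stats::setNames(data.frame(x), term),
             ties = ties),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(term = term, hr = unname(fit@hr[1]),
               lower = unname(fit@hrCI[1, 1]), upper = unname(fit@hrCI[1, 2]),
               p = unname(fit@waldP[1]),
               note = if (fit@converged) "" else "did not converge")
  }
  terms <- rbind(
    one("male_vs_female", as.numeric(data$sex == "male")),
    one("age_years", data$age_years),
    one("age_over_cutoff", as.numeric(data$age_years >= ageCutoff)),
    one("mean_methylation", data$mean_methylation))

  cands <- enumerateCandidates(M)
  catRows <- lapply(seq_len(nrow(cands)), function(i) {
    g <- cands$g[i]
    cats <- categorize(data$mean_methylation, M = M, g = g)
    if (any(table(cats) == 0))
      return(data.frame(g = g, hr_meth_vs_gray = NA_real_, p_meth = NA_real_,
                        hr_unmeth_vs_gray = NA_real_, p_unmeth = NA_real_,
                        note = "inestimable: empty category"))
    X <- cbind(methylated = as.numeric(cats == "methylated"),
               unmethylated = as.numeric(cats == "unmethylated"))
    fit <- withCallingHandlers(
      coxFit(data$os_months, data$event, X, ties = ties),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(g = g,
               hr_meth_vs_gray = unname(fit@hr[["methylated"]]),
               p_meth = unname(fit@waldP[["methylated"]]),
               hr_unmeth_vs_gray = unname(fit@hr[["unmethylated"]]),
               p_unmeth = unname(fit@waldP[["unmethylated"]]),
               note = if (fit@converged) "" else "did not converge")
  })
  list(terms = terms, categories = do.call(rbind, catRows))
}

#' Select the optimal gray zone
#'
#' A candidate qualifies iff HR(methylated:gray) < 1 with p < alpha,
#' HR(unmethylated:gray) > 1 with p < alpha, and the nested LRT against the
#' binary model has p < alpha. The optimum is the qualifying candidate with
#' the largest LRT statistic, ties broken by the smaller g (the wider
#' safety margin); when no candidate qualifies the decision is none.
#' Candidates whose hazard-ratio criteria pass but whose LRT does not are
#' recorded as near-misses in the rationale.
#'
#' @param candidates List of \linkS4class{CandidateResult} fitted on the
#'   same cohort.
#' @param alpha Significance level (default 0.05).
#' @param binaryModel The binary \linkS4class{CoxPHModel} (for the decision
#'   record); may be NULL.
#' @return A \linkS4class{GrayZoneDecision}.
#' @export
selectOptimal <- function(candidates, alpha = 0.05, binaryModel = NULL) {
  if (!length(candidates))
    gzConfigError("no candidates supplied: cannot select a gray zone")
  isCand <- vapply(candidates, function(cr) !is.na(cr@g), logical(1))
  cand <- candidates[isCand]
  if (!length(cand))
    gzConfigError("no gray-zone candidates supplied (only the binary row)")
  rationale <- do.call(rbind, lapply(cand, function(cr) {
    hrMethOK <- isTRUE(cr@hrMethVsGray < 1 && cr@pMethVsGray < alpha)
    hrUnmethOK <- isTRUE(cr@hrUnmethVsGray > 1 && cr@pUnmethVsGray < alpha)
    lrtOK <- isTRUE(cr@lrtP < alpha)
    data.frame(g = cr@g, M = cr@M,
               hr_meth_significant_below_1 = hrMethOK,
               hr_unmeth_significant_above_1 = hrUnmethOK,
               lrt_significant = lrtOK,
               qualifies = hrMethOK && hrUnmethOK && lrtOK,
               near_miss = hrMethOK && hrUnmethOK && !lrtOK,
               lrt_stat = cr@lrtStat,
               note = cr@note)
  }))
  quals <- rationale$qualifies
  M <- cand[[1]]@M
  optimal <- NULL
  if (any(quals)) {
    sub <- rationale[quals, ]
    best <- sub[order(-sub$lrt_stat, sub$g), ][1, ]
    optimal <- list(g = as.integer(best$g), M = as.integer(best$M))
  }
  tab <- do.call(rbind, lapply(candidates, candidateRow))
  new("GrayZoneDecision", optimal = optimal, M = as.integer(M),
      alpha = alpha, candidates = candidates,
      binaryModel = binaryModel %||% methods::new("CoxPHModel"),
      table = tab, rationale = rationale)
}

## one row of the candidate table (Table-analogue serialisation)
candidateRow <- function(cr) {
  km <- cr@km
  getk <- function(lv, col) {
    i <- match(lv, km$category)
    if (is.na(i)) NA_real_ else km[[col]][i]
  }
  data.frame(
    g = ifelse(is.na(cr@g), 0L, cr@g), M = cr@M,
    n_unmethylated = cr@counts[["unmethylated"]],
    n_gray = if ("gray" %in% names(cr@counts)) cr@counts[["gray"]] else NA_integer_,
    n_methylated = cr@counts[["methylated"]],
    median_os_unmethylated = getk("unmethylated", "median_os"),
    median_lo_unmethylated = getk("unmethylated", "median_lower"),
    median_hi_unmethylated = getk("unmethylated", "median_upper"),
    median_os_gray = getk("gray", "median_os"),
    median_lo_gray = getk("gray", "median_lower"),
    median_hi_gray = getk("gray", "median_upper"),
    median_os_methylated = getk("methylated", "median_os"),
    median_lo_methylated = getk("methylated", "median_lower"),
    median_hi_methylated = getk("methylated", "median_upper"),
    hr_age = cr@hrAge, hr_age_lo = cr@hrAgeCI[1], hr_age_hi = cr@hrAgeCI[2],
    p_age = cr@pAge,
    hr_meth_vs_gray = cr@hrMethVsGray,
    hr_meth_lo = cr@hrMethCI[1], hr_meth_hi = cr@hrMethCI[2],
    p_meth_vs_gray = cr@pMethVsGray,
    hr_unmeth_vs_gray = cr@hrUnmethVsGray,
    hr_unmeth_lo = cr@hrUnmethCI[1], hr_unmeth_hi = cr@hrUnmethCI[2],
    p_unmeth_vs_gray = cr@pUnmethVsGray,
    loglik = cr@loglik,
    score_stat = cr@scoreStat, score_p = cr@scoreP,
    lrt_stat = cr@lrtStat, lrt_p = cr@lrtP, score_diff = cr@scoreDiff,
    qualifies = cr@qualifies, note = cr@note,
    stringsAsFactors = FALSE)
}

#' Sweep all candidate gray zones and select the optimum
#'
#' Enumerates the integer candidates below M, fits each three-category
#' model plus the binary reference on the identical subjects, and applies
#' the selection rule of \code{\link{selectOptimal}}.
#'
#' @inheritParams fitBinaryModel
#' @param alpha Significance level.
#' @return A \linkS4class{GrayZoneDecision} (candidates list ends with the
#'   binary no-gray-zone row).
#' @export
sweepCandidates <- function(data, M, ageCutoff = 65, includeSex = FALSE,
                            alpha = 0.05, ties = "efron") {
  cands <- enumerateCandidates(M)
  if (!nrow(cands))
    gzConfigError("M = 1 admits no gray-zone candidates")
  binaryModel <- fitBinaryModel(data, M, ageCutoff, includeSex, ties)
  results <- lapply(cands$g, function(g)
    fitCandidateModel(data, g, M, ageCutoff, includeSex, alpha, ties,
                      binaryModel = binaryModel))
  results <- c(results, binaryResult(data, M, binaryModel))
  selectOptimal(results, alpha = alpha, binaryModel = binaryModel)
}
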