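#' @import methods
NULL

#' Fitted Cox proportional-hazards model
#'
#' Container for a Cox model maximised by Newton-Raphson on the Efron (or
#' Breslow) tie-corrected log partial likelihood. Standard errors come from
#' the inverse observed information at the maximum; confidence intervals are
#' Wald intervals on the log-hazard scale.
#'
#' @slot coef Named numeric vector of log hazard ratios.
#' @slot se Standard errors (inverse observed information).
#' @slot hr exp(coef), the hazard ratios.
#' @slot hrCI Two-column matrix of 95\% Wald interval bounds for the HRs.
#' @slot waldP Two-sided z-based p-value per coefficient.
#' @slot loglikNull Log partial likelihood at coef = 0.
#' @slot loglikFit Log partial likelihood at the maximum.
#' @slot scoreStat,scoreP Global score (log-rank type) test of all
#'   coefficients against zero and its chi-squared p-value.
#' @slot n,nEvents Number of subjects and observed deaths.
#' @slot converged,iterations Newton-Raphson convergence flag and count.
#' @slot ties Tie correction used, "efron" or "breslow".
#' @export
setClass("CoxPHModel", slots = c(
  coef = "numeric", se = "numeric", hr = "numeric", hrCI = "matrix",
  waldP = "numeric", loglikNull = "numeric", loglikFit = "numeric",
  scoreStat = "numeric", scoreP = "numeric",
  n = "integer", nEvents = "integer",
  converged = "logical", iterations = "integer", ties = "character"
))

setValidity("CoxPHModel", function(object) {
  msg <- character()
  if (length(object@loglikFit) && length(object@loglikNull) &&
      object@loglikFit < object@loglikNull - 1e-8)
    msg <- c(msg, "loglikFit must not be below loglikNull")
  if (length(object@coef) &&
      any(abs(object@hr - exp(object@coef)) > 1e-10 * (1 + object@hr), na.rm = TRUE))
    msg <- c(msg, "hr must equal exp(coef)")
  if (length(object@coef) != length(object@se))
    msg <- c(msg, "coef and se lengths differ")
  if (length(msg)) msg else TRUE
})

#' Kaplan-Meier product-limit estimate
#'
#' One survival curve: step values at the distinct event times, Greenwood
#' variance, 95\% pointwise confidence bands on the log(-log) scale, and the
#' median with its band-crossing confidence interval (unbounded limits are
#' +/-Inf).
#'
#' @slot time Distinct event times (increasing).
#' @slot nRisk,nEvent Numbers at risk and dying at each time.
#' @slot surv Product-limit estimate S(t) just after each event time.
#' @slot greenwoodVar Greenwood variance of S(t).
#' @slot lower,upper 95\% confidence band (log(-log) scale), NA where the
#'   transform is undefined (S = 0 or 1).
#' @slot median Smallest event time with S <= 0.5, Inf if never reached.
#' @slot medianCI Times where the confidence bands cross 0.5; -Inf/Inf where
#'   a band never crosses.
#' @slot n,nEvents Cohort size and total deaths.
#' @slot confLevel Confidence level of the bands.
#' @export
setClass("KMFit", slots = c(
  time = "numeric", nRisk = "numeric", nEvent = "numeric",
  surv = "numeric", greenwoodVar = "numeric",
  lower = "numeric", upper = "numeric",
  median = "numeric", medianCI = "numeric",
  n = "integer", nEvents = "integer", confLevel = "numeric"
))

setValidity("KMFit", function(object) {
  msg <- character()
  if (any(diff(object@surv) > 1e-12)) msg <- c(msg, "surv must be non-increasing")
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
    msg <- c(msg, "surv must lie in [0, 1]")
  ok <- !is.na(object@lower) & !is.na(object@upper)
  if (any(object@lower[ok] > object@surv[ok] + 1e-8) ||
      any(object@upper[ok] < object@surv[ok] - 1e-8))
    msg <- c(msg, "confidence band must bracket surv")
  if (length(msg)) msg else TRUE
})

#' One candidate three-category methylation classification
#'
#' Summary of a single candidate gray zone [g, M): per-category counts and
#' Kaplan-Meier medians, the multivariate Cox fit with the gray zone as
#' reference level, the nested likelihood-ratio test against the binary
#' classification, and the qualification verdict. The binary (no-gray-zone)
#' classification is represented with \code{g = NA}.
#'
#' @slot g Gray-zone lower bound (integer percent), NA for the binary model.
#' @slot M Methylated threshold (integer percent).
#' @slot counts Named integer vector: samples per category.
#' @slot km data.frame of per-category median OS with CI bounds.
#' @slot model The fitted \linkS4class{CoxPHModel}, or NULL when inestimable.
#' @slot hrMethVsGray,hrMethCI,pMethVsGray Methylated:gray hazard ratio,
#'   95\% CI, Wald p.
#' @slot hrUnmethVsGray,hrUnmethCI,pUnmethVsGray Unmethylated:gray contrast.
#' @slot hrAge,hrAgeCI,pAge Age-group (>= cutoff vs below) contrast.
#' @slot loglik Log partial likelihood of the candidate model.
#' @slot scoreStat,scoreP Global score statistic and p-value.
#' @slot lrtStat,lrtP Nested LRT against the binary model (df = 1).
#' @slot scoreDiff Secondary diagnostic: candidate score statistic minus the
#'   binary model's score statistic.
#' @slot qualifies TRUE iff HR(meth:gray) < 1 with p < alpha, HR(unmeth:gray)
#'   > 1 with p < alpha, and lrtP < alpha.
#' @slot note Inestimability or convergence annotations.
#' @export
setClass("CandidateResult", slots = c(
  g = "integer", M = "integer", counts = "integer", km = "data.frame",
  model = "ANY",
  hrMethVsGray = "numeric", hrMethCI = "numeric", pMethVsGray = "numeric",
  hrUnmethVsGray = "numeric", hrUnmethCI = "numeric", pUnmethVsGray = "numeric",
  hrAge = "numeric", hrAgeCI = "numeric", pAge = "numeric",
  loglik = "numeric", scoreStat = "numeric", scoreP = "numeric",
  lrtStat = "numeric", lrtP = "numeric", scoreDiff = "numeric",
  qualifies = "logical", note = "character"
))

#' Gray-zone selection decision
#'
#' Result of the survival-supervised sweep: all candidate results, the
#' binary reference model, the per-candidate criteria trace, and the
#' selected optimum (or none).
#'
#' @slot optimal List with elements \code{g} and \code{M}, or NULL when no
#'   candidate qualifies.
#' @slot M Methylated threshold shared by all candidates.
#' @slot alpha Significance level of the qualification criteria.
#' @slot candidates List of \linkS4class{CandidateResult}.
#' @slot binaryModel The binary-classification \linkS4class{CoxPHModel}.
#' @slot table data.frame analogue of the per-candidate results table.
#' @slot rationale data.frame: per candidate, which criterion passed/failed.
#' @export
setClass("GrayZoneDecision", slots = c(
  optimal = "ANY", M = "integer", alpha = "numeric",
  candidates = "list", binaryModel = "ANY",
  table = "data.frame", rationale = "data.frame"
))

setValidity("GrayZoneDecision", function(object) {
  if (!is.null(object@optimal)) {
    quals <- vapply(object@candidates, function(cr) isTRUE(cr@qualifies), logical(1))
    gs <- vapply(object@candidates, function(cr) as.numeric(cr@g), numeric(1))
    if (!any(quals)) return("optimal set but no candidate qualifies")
    if (!(object@optimal$g %in% gs[quals]))
      return("optimal is not a qualifying candidate")
  }
  TRUE
})

#' Pyrosequencing cohort
#'
#' Holds the run-level pyrosequencing table (one row per sequencing run per
#' tumor sample, percentage methylation per CpG site), the clinical table,
#' and the shared CpG panel.
#'
#' @slot runs data.frame with columns sample_id, run_id and one
#'   \code{cpg_<site>} column per panel site (percent scale, NA = failed).
#' @slot clinical data.frame with columns sample_id, age_years, sex,
#'   os_months, event.
#' @slot siteIds Integer vector, the cohort's CpG panel.
#' @export
setClass("PyroCohort", slots = c(
  runs = "data.frame", clinical = "data.frame", siteIds = "integer"
))

setValidity("PyroCohort", function(object) {
  msg <- character()
  need <- c("sample_id", "run_id", paste0("cpg_", object@siteIds))
  miss <- setdiff(need, names(object@runs))
  if (length(miss)) msg <- c(msg, paste("runs missing column(s):", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    vals <- as.matrix(object@runs[, paste0("cpg_", object@siteIds), drop = FALSE])
    if (any(vals < 0 | vals > 100, na.rm = TRUE))
      msg <- c(msg, "methylation values must lie in [0, 100]")
    if (anyDuplicated(object@runs[, c("sample_id", "run_id")]))
      msg <- c(msg, "(sample_id, run_id) pairs must be unique")
  }
  needc <- c("sample_id", "age_years", "sex", "os_months", "event")
  missc <- setdiff(needc, names(object@clinical))
  if (length(missc)) msg <- c(msg, paste("clinical missing column(s):", paste(missc, collapse = ", ")))
  if (!length(missc) && anyDuplicated(object@clinical$sample_id))
    msg <- c(msg, "clinical sample_id must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PyroCohort
#'
#' @param runs Run-level pyrosequencing data.frame (see
#'   \linkS4class{PyroCohort}).
#' @param clinical Clinical data.frame.
#' @param siteIds Integer CpG panel.
#' @return A \linkS4class{PyroCohort}.
#' @export
PyroCohort <- function(runs, clinical, siteIds) {
  new("PyroCohort", runs = runs, clinical = clinical,
      siteIds = as.integer(siteIds))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "CoxPHModel", function(object) {
  cat(sprintf("CoxPHModel (%s ties): n = %d, events = %d, %s in %d iter\n",
              object@ties, object@n, object@nEvents,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
  if (length(object@coef)) {
    tab <- data.frame(
      coef = object@coef, HR = object@hr,
      lower95 = object@hrCI[, 1], upper95 = object@hrCI[, 2],
      p = object@waldP, row.names = names(object@coef))
    print(format(tab, digits = 4))
  } else {
    cat("  (null model)\n")
  }
  cat(sprintf("  loglik: %0.4f (null %0.4f); score = %0.3f, p = %0.3g\n",
              object@loglikFit, object@loglikNull,
              object@scoreStat, object@scoreP))
})

setMethod("show", "KMFit", function(object) {
  cat(sprintf("KMFit: n = %d, events = %d, %d event times\n",
              object@n, object@nEvents, length(object@time)))
  cat(sprintf("  median = %s [%s, %s] (%.0f%% CI)\n",
              infToken(object@median),
              infToken(object@medianCI[1]), infToken(object@medianCI[2]),
              100 * object@confLevel))
})

setMethod("show", "CandidateResult", function(object) {
  lbl <- if (is.na(object@g)) sprintf("binary (M = %d)", object@M)
         else sprintf("gray zone %d%%-%d%%", object@g, object@M)
  cat(sprintf("CandidateResult %s: n = (%s), %s\n", lbl,
              paste(sprintf("%s %d", names(object@counts), object@counts), collapse = ", "),
              if (isTRUE(object@qualifies)) "qualifies" else "does not qualify"))
  if (length(object@hrMethVsGray) && !is.na(object@hrMethVsGray))
    cat(sprintf("  HR meth:gray %0.3f (p %0.4g); HR unmeth:gray %0.3f (p %0.4g); LRT %0.4f (p %0.4g)\n",
                object@hrMethVsGray, object@pMethVsGray,
                object@hrUnmethVsGray, object@pUnmethVsGray,
                object@lrtStat, object@lrtP))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "GrayZoneDecision", function(object) {
  nCand <- sum(vapply(object@candidates, function(cr) !is.na(cr@g), logical(1)))
  cat(sprintf("GrayZoneDecision: M = %d, alpha = %g, %d candidates + binary reference\n",
              object@M, object@alpha, nCand))
  if (is.null(object@optimal)) {
    cat("  optimal gray zone: none (no candidate met all criteria)\n")
  } else {
    cat(sprintf("  optimal gray zone: %d%%-%d%%\n",
                object@optimal$g, object@optimal$M))
  }
})

setMethod("show", "PyroCohort", function(object) {
  cat(sprintf("PyroCohort: %d runs on %d samples, %d clinical records, CpG panel %s\n",
              nrow(object@runs), length(unique(object@runs$sample_id)),
              nrow(object@clinical),
              paste(range(object@siteIds), collapse = "-")))
})

## ---- accessors ----------------------------------------------------------

#' @describeIn CoxPHModel-class Coefficient vector (log hazard ratios).
#' @param object A fitted model.
#' @export
setMethod("coef", "CoxPHModel", function(object) object@coef)

#' @describeIn CoxPHModel-class Log partial likelihood at the maximum.
#' @export
setMethod("logLik", "CoxPHModel", function(object) object@loglikFit)

#' Hazard ratios of a fitted Cox model
#' @param object A \linkS4class{CoxPHModel}.
#' @return Named numeric vector exp(coef).
#' @export
hazardRatios <- function(object) object@hr

#' Candidate results table of a gray-zone decision
#' @param object A \linkS4class{GrayZoneDecision}.
#' @return data.frame with one row per candidate plus the binary row.
#' @export
candidateTable <- function(object) object@table

#' Selected optimal gray zone
#' @param object A \linkS4class{GrayZoneDecision}.
#' @return List with elements g and M, or NULL when no candidate qualified.
#' @export
optimalGrayZone <- function(object) object@optimal

#' Run-level table of a cohort
#' @param object A \linkS4class{PyroCohort}.
#' @return data.frame of pyrosequencing runs.
#' @export
pyroRuns <- function(object) object@runs

#' Clinical table of a cohort
#' @param object A \linkS4class{PyroCohort}.
#' @return data.frame of clinical records.
#' @export
clinicalData <- function(object) object@clinical

#' CpG panel of a cohort
#' @param object A \linkS4class{PyroCohort}.
#' @return Integer vector of CpG site numbers.
#' @export
siteIds <- function(object) object@siteIds
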