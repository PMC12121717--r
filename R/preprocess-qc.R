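## Failed-run exclusion, replicate aggregation, QC summaries, Mahalanobis
## multivariate outlier flagging, binary-threshold derivation, discordance.

cpgColumns <- function(runs) grep("^cpg_", names(runs), value = TRUE)

#' Exclude failed pyrosequencing runs
#'
#' A run is a failed test iff the methylation percentage is missing at one
#' or more CpG sites of the panel; such runs are excluded in full. Order is
#' preserved and nothing is silently dropped: kept and excluded partition
#' the input.
#'
#' @param runs Run-level data.frame (see \code{\link{readPyroRuns}}).
#' @return List with elements \code{kept} and \code{excluded}.
#' @export
excludeFailedRuns <- function(runs) {
  cols <- cpgColumns(runs)
  if (!nrow(runs)) return(list(kept = runs, excluded = runs))
  bad <- rowSums(is.na(runs[, cols, drop = FALSE])) > 0
  list(kept = runs[!bad, , drop = FALSE], excluded = runs[bad, , drop = FALSE])
}

#' Aggregate replicate runs per sample
#'
#' For each sample the mean methylation at each CpG site is computed across
#' its (complete) runs, then the sample's average methylation is the mean of
#' those per-site means. Replicate variability is summarised by the sample
#' standard deviation (denominator n - 1) of the per-run mean-across-sites
#' values.
#'
#' @param runs Complete runs (after \code{\link{excludeFailedRuns}}).
#' @return data.frame with one row per sample (order of first appearance):
#'   sample_id, the per-site mean \code{cpg_*} columns, mean_methylation,
#'   n_runs, replicate_sd (NA for single-run samples). Attribute
#'   \code{runMeans} holds the per-run mean-across-sites values as a named
#'   list.
#' @export
aggregateReplicates <- function(runs) {
  cols <- cpgColumns(runs)
  if (any(is.na(runs[, cols, drop = FALSE])))
    gzValidityError("aggregateReplicates requires complete runs; call excludeFailedRuns first")
  ids <- unique(runs$sample_id)
  vals <- as.matrix(runs[, cols, drop = FALSE])
  runMean <- rowMeans(vals)
  perSite <- rowsum(vals, group = runs$sample_id, reorder = FALSE) /
    as.vector(table(factor(runs$sample_id, levels = ids)))
  nRuns <- as.integer(table(factor(runs$sample_id, levels = ids)))
  runMeans <- split(runMean, factor(runs$sample_id, levels = ids))
  repSd <- vapply(runMeans, function(v) if (length(v) >= 2) stats::sd(v) else NA_real_,
                  numeric(1))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  out[cols] <- as.data.frame(perSite[ids, , drop = FALSE])
  out$mean_methylation <- rowMeans(perSite[ids, , drop = FALSE])
  out$n_runs <- nRuns
  out$replicate_sd <- unname(repSd[ids])
  rownames(out) <- NULL
  attr(out, "runMeans") <- runMeans
  out
}

#' Replicate standard-deviation summary
#'
#' Mean replicate SD across samples with at least two runs, overall and
#' restricted to samples whose mean methylation lies below the methylated
#' threshold.
#'
#' @param samples Output of \code{\link{aggregateReplicates}}.
#' @param threshold Methylated threshold M (percent).
#' @return List with \code{mean_sd_all} and \code{mean_sd_below_threshold}
#'   (the latter NA when no qualifying sample falls below M).
#' @export
replicateSdSummary <- function(samples, threshold) {
  ok <- samples$n_runs >= 2
  if (!any(ok))
    gzDataError("no sample has two or more runs; replicate SD undefined")
  below <- ok & samples$mean_methylation < threshold
  list(mean_sd_all = mean(samples$replicate_sd[ok]),
       mean_sd_below_threshold =
         if (any(below)) mean(samples$replicate_sd[below]) else NA_real_)
}

#' Per-CpG distribution summary and correlation matrix
#'
#' Five-number summary plus mean/SD per CpG site, the site-by-site Pearson
#' correlation matrix across samples, and the cohort mean/SD of the sample
#' average methylation. Correlations involving a zero-variance site are
#' reported as NA (undefined), never 0.
#'
#' @param samples Output of \code{\link{aggregateReplicates}}.
#' @return List: \code{per_site} (data.frame), \code{correlation} (matrix
#'   with site labels), \code{cohort_mean}, \code{cohort_sd}, \code{n}.
#' @export
cpgSummary <- function(samples) {
  if (nrow(samples) < 2)
    gzDataError("at least 2 samples are required for distribution summaries")
  cols <- cpgColumns(samples)
  X <- as.matrix(samples[, cols, drop = FALSE])
  fv <- t(apply(X, 2, stats::quantile, probs = c(0, .25, .5, .75, 1)))
  perSite <- data.frame(site = cols, min = fv[, 1], q1 = fv[, 2],
                        median = fv[, 3], q3 = fv[, 4], max = fv[, 5],
                        mean = colMeans(X), sd = apply(X, 2, stats::sd),
                        row.names = NULL, stringsAsFactors = FALSE)
  corr <- suppressWarnings(stats::cor(X))
  constant <- apply(X, 2, function(col) max(col) - min(col) == 0)
  corr[constant, ] <- NA_real_   # undefined, including the diagonal
  corr[, constant] <- NA_real_
  dimnames(corr) <- list(cols, cols)
  list(per_site = perSite, correlation = corr,
       cohort_mean = mean(samples$mean_methylation),
       cohort_sd = stats::sd(samples$mean_methylation),
       n = nrow(samples))
}

#' Squared Mahalanobis distances of CpG profiles
#'
#' Distance of each sample's per-site mean vector from the cohort mean
#' profile, scaled by the inverse of the unbiased (n - 1) sample covariance:
#' d2 = (x - mu)' S^-1 (x - mu). With the unbiased covariance the distances
#' satisfy sum(d2) = (n - 1) * n_sites, used as a self-check.
#'
#' @param samples Output of \code{\link{aggregateReplicates}}.
#' @param pseudoInverse Use the Moore-Penrose pseudo-inverse of S instead of
#'   the inverse (for singular covariance, e.g. collinear sites).
#' @return Numeric vector of squared distances, named by sample_id.
#' @export
mahalanobisDistances <- function(samples, pseudoInverse = FALSE) {
  cols <- cpgColumns(samples)
  X <- as.matrix(samples[, cols, drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  if (!pseudoInverse && n <= p)
    gzDataError("need more samples (%d) than sites (%d) for an invertible covariance; set pseudoInverse = TRUE otherwise", n, p)
  mu <- colMeans(X)
  S <- stats::cov(X)
  d2 <- if (pseudoInverse) {
    C <- sweep(X, 2, mu)
    rowSums((C %*% MASS::ginv(S)) * C)
  } else {
    ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
    if (!ok)
      gzDegeneracyError("sample covariance is singular; rerun with pseudoInverse = TRUE")
    stats::mahalanobis(X, mu, S)
  }
  stats::setNames(as.numeric(d2), samples$sample_id)
}

#' Flag multivariate outliers
#'
#' Compares squared Mahalanobis distances against a chi-squared quantile
#' with df = number of CpG sites. The default action is \code{flag_only}:
#' flagged samples are reported but retained downstream;
#' \code{exclude_and_rerun} (honoured by \code{\link{runGrayZoneAnalysis}})
#' additionally reruns the full analysis without the flagged samples and
#' reports both results side by side.
#'
#' @param distances Squared distances from
#'   \code{\link{mahalanobisDistances}}.
#' @param nSites Number of CpG sites (chi-squared degrees of freedom).
#' @param quantile Cutoff probability in (0, 1); default 0.975.
#' @param action "flag_only" (default) or "exclude_and_rerun".
#' @return List: \code{distances}, \code{cutoff}, \code{flagged} (sample
#'   ids with d2 > cutoff), \code{action}, \code{quantile}.
#' @export
flagOutliers <- function(distances, nSites, quantile = 0.975,
                         action = c("flag_only", "exclude_and_rerun")) {
  action <- match.arg(action)
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      is.na(quantile) || quantile <= 0 || quantile >= 1)
    gzConfigError("outlier quantile must lie strictly between 0 and 1")
  cutoff <- stats::qchisq(quantile, df = nSites)
  list(distances = distances, cutoff = cutoff,
       flagged = names(distances)[distances > cutoff],
       action = action, quantile = quantile)
}

#' Derive the binary methylated threshold (50/50 rule)
#'
#' Finds the integer threshold that most effectively splits the cohort into
#' 50\% methylated and 50\% unmethylated samples: over integer candidates
#' t in 1..99, a sample is methylated iff mean_methylation >= t, and the t
#' minimising |n_methylated - n/2| is returned, ties broken by the smallest
#' such t (conservative: labels more samples methylated).
#'
#' @param samples Output of \code{\link{aggregateReplicates}}.
#' @return Integer threshold M.
#' @export
deriveBinaryThreshold <- function(samples) {
  m <- samples$mean_methylation
  if (length(m) < 2 || length(unique(m)) < 2)
    gzDataError("need at least 2 samples with distinct mean methylation to derive a threshold")
  n <- length(m)
  cand <- 1:99
  imbalance <- vapply(cand, function(t) abs(sum(m >= t) - n / 2), numeric(1))
  as.integer(cand[which.min(imbalance)])
}

#' Detect discordant replicate results
#'
#' A sample is discordant iff its per-run mean-across-sites values do not
#' all fall in the same methylation category under the given classification
#' (binary when \code{g} is NA, three-category otherwise).
#'
#' @param runs Complete runs (after \code{\link{excludeFailedRuns}}).
#' @param M Methylated threshold (integer percent).
#' @param g Gray-zone lower bound, or NA for the binary classification.
#' @return Character vector of discordant sample ids (order of first
#'   appearance).
#' @export
detectDiscordant <- function(runs, M, g = NA) {
  cols <- cpgColumns(runs)
  if (!nrow(runs)) return(character())
  runMean <- rowMeans(as.matrix(runs[, cols, drop = FALSE]))
  cats <- categorize(runMean, M = M, g = g)
  ids <- unique(runs$sample_id)
  disc <- vapply(split(as.character(cats), factor(runs$sample_id, levels = ids)),
                 function(v) length(unique(v)) > 1, logical(1))
  names(disc)[disc]
}
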