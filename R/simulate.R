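## Synthetic-cohort generator: correlated bimodal CpG profiles with
## replicate noise, and category-dependent proportional-hazards survival.

#' Simulation configuration
#'
#' Builds the parameter list driving the synthetic-cohort generator. The
#' defaults emulate a development-style glioblastoma pyrosequencing cohort:
#' a two-component truncated-normal mixture of latent per-sample mean
#' methylation (modes near 3\% and 39\%, giving cohort mean ~21\%, SD ~21\%
#' and ~49\% of samples at or above the 12\% methylated threshold), strongly
#' correlated CpG sites (target pairwise Pearson correlation 0.9), two
#' replicate runs per sample with a measured mean replicate SD near 1.38\%
#' overall and ~0.8\% below the threshold, exponential baseline hazard with
#' ~10.5 months median survival in the gray-zone reference category,
#' category hazard ratios 0.53 (methylated:gray) and 1.8
#' (unmethylated:gray), an age-group hazard ratio of 2.5, and uniform
#' administrative censoring over a 40-month follow-up window (~60\% deaths).
#'
#' @param n_samples Number of tumor samples.
#' @param seed Integer seed; all randomness flows from it.
#' @param site_ids CpG panel (integers).
#' @param n_runs Replicate sequencing runs per sample.
#' @param weight_methylated Mixture weight of the high-methylation mode.
#' @param low_mean,low_sd,high_mean,high_sd Mixture component parameters on
#'   the percent scale (truncated to [0, 100]).
#' @param cpg_correlation Target pairwise inter-site Pearson correlation.
#' @param replicate_sd Target measured mean replicate SD (percent) at the
#'   cohort mean methylation; scales the run-level noise.
#' @param true_M,true_g Ground-truth category boundaries applied to the
#'   latent mean when assigning hazards.
#' @param baseline_median_os Median OS (months) of the gray-zone reference
#'   under the baseline hazard.
#' @param hr_meth_vs_gray,hr_unmeth_vs_gray,hr_age Hazard ratios of the
#'   generating model (age contrast: at/above vs below \code{age_cutoff}).
#' @param age_mean,age_sd,age_min,age_max,age_cutoff Age distribution
#'   (truncated normal, years) and the age-group cutoff.
#' @param prop_male Probability a subject is male.
#' @param followup_months Administrative follow-up window W; censoring
#'   times are drawn uniformly on (0, W). \code{Inf} disables censoring.
#' @param weibull_shape Shape of the baseline Weibull hazard (1 =
#'   exponential).
#' @param fail_rate Probability that a run fails (one CpG site reported
#'   missing), for exercising failed-run exclusion.
#' @return Named list of simulation parameters.
#' @export
simConfig <- function(n_samples = 308, seed = 1, site_ids = 72:83,
                      n_runs = 2,
                      weight_methylated = 0.49,
                      low_mean = 3, low_sd = 2.5,
                      high_mean = 39, high_sd = 16,
                      cpg_correlation = 0.9,
                      replicate_sd = 1.38,
                      true_M = 12, true_g = 5,
                      baseline_median_os = 10.5,
                      hr_meth_vs_gray = 0.53, hr_unmeth_vs_gray = 1.8,
                      hr_age = 2.5,
                      age_mean = 57, age_sd = 12, age_min = 20, age_max = 85,
                      age_cutoff = 65,
                      prop_male = 0.64,
                      followup_months = 40,
                      weibull_shape = 1,
                      fail_rate = 0) {
  cfg <- as.list(environment())
  if (cfg$weight_methylated <= 0 || cfg$weight_methylated >= 1)
    gzConfigError("weight_methylated must lie strictly between 0 and 1")
  if (cfg$low_sd < 0 || cfg$high_sd < 0 || cfg$replicate_sd < 0)
    gzConfigError("standard deviations must be non-negative")
  if (any(c(cfg$hr_meth_vs_gray, cfg$hr_unmeth_vs_gray, cfg$hr_age) <= 0))
    gzConfigError("hazard ratios must be positive")
  if (cfg$followup_months <= 0)
    gzConfigError("followup_months must be positive")
  if (cfg$cpg_correlation <= 0 || cfg$cpg_correlation >= 1)
    gzConfigError("cpg_correlation must lie strictly between 0 and 1")
  cfg
}

#' Validation-style simulation configuration
#'
#' A smaller cohort with the 74-79 CpG panel, a 10\% methylated threshold,
#' a sparse intermediate methylation band, and a short follow-up window
#' giving ~40\% deaths -- the under-powered regime in which the gray-zone
#' search is expected to return none.
#'
#' @param n_samples Cohort size (default 115).
#' @param seed Integer seed.
#' @param followup_months Follow-up window (months); the short default gives
#'   ~40\% deaths.
#' @param ... Further overrides passed to \code{\link{simConfig}}.
#' @return Named list of simulation parameters.
#' @export
validationSimConfig <- function(n_samples = 115, seed = 1,
                                followup_months = 12, ...) {
  simConfig(n_samples = n_samples, seed = seed, site_ids = 74:79,
            weight_methylated = 0.45,
            low_mean = 2, low_sd = 1.5, high_mean = 30, high_sd = 16,
            true_M = 10, true_g = 5,
            followup_months = followup_months, ...)
}

# truncated-normal draws by inverse-CDF (deterministic in the RNG stream)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# untruncated mixture moments (adequate for noise scaling; truncation mild)
mixtureMoments <- function(cfg) {
  w <- c(1 - cfg$weight_methylated, cfg$weight_methylated)
  mu <- c(cfg$low_mean, cfg$high_mean)
  s2 <- c(cfg$low_sd^2, cfg$high_sd^2)
  m1 <- sum(w * mu)
  m2 <- sum(w * (mu^2 + s2))
  list(mean = m1, m2 = m2, var = m2 - m1^2)
}

## internal generators assume the RNG state is already seeded
simLatent <- function(cfg) {
  comp <- stats::rbinom(cfg$n_samples, 1, cfg$weight_methylated)
  m <- numeric(cfg$n_samples)
  hi <- comp == 1
  m[hi] <- rtruncnorm(sum(hi), cfg$high_mean, cfg$high_sd, 0, 100)
  m[!hi] <- rtruncnorm(sum(!hi), cfg$low_mean, cfg$low_sd, 0, 100)
  m
}

simProfilesFromLatent <- function(cfg, m) {
  n <- cfg$n_samples
  p <- length(cfg$site_ids)
  mom <- mixtureMoments(cfg)
  # one shared factor (the latent mean) + site noise proportional to the
  # mean, scaled so that across-sample pairwise site correlation ~ rho:
  # corr = V_m / (V_m + k^2 E[m^2])  =>  k^2 = V_m (1-rho) / (rho E[m^2])
  kk <- sqrt(mom$var * (1 - cfg$cpg_correlation) /
             (cfg$cpg_correlation * mom$m2))
  siteVals <- m + (m * kk) * matrix(stats::rnorm(n * p), n, p)
  # run-level replicate shift; SD grows linearly with methylation so the
  # below-threshold replicate SD sits near 60% of the overall value, and a
  # c4(n_runs) correction makes the *measured* mean SD match the target
  repScale <- if (cfg$n_runs >= 2) cfg$replicate_sd / c4const(cfg$n_runs) else 0
  repSd <- repScale * (0.489 + 0.0246 * m)
  rows <- vector("list", cfg$n_runs)
  clipped <- 0L
  total <- 0L
  ids <- sprintf("S%04d", seq_len(n))
  for (r in seq_len(cfg$n_runs)) {
    shift <- stats::rnorm(n, 0, 1) * repSd
    runVals <- siteVals + shift
    clipped <- clipped + sum(runVals < 0 | runVals > 100)
    total <- total + length(runVals)
    runVals <- pmin(pmax(runVals, 0), 100)
    df <- data.frame(sample_id = ids, run_id = sprintf("R%d", r),
                     stringsAsFactors = FALSE)
    df[paste0("cpg_", cfg$site_ids)] <- as.data.frame(runVals)
    rows[[r]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$sample_id, ids)), , drop = FALSE]
  rownames(out) <- NULL
  if (cfg$fail_rate > 0) {
    fails <- which(stats::runif(nrow(out)) < cfg$fail_rate)
    siteCols <- paste0("cpg_", cfg$site_ids)
    for (i in fails)
      out[i, sample(siteCols, 1)] <- NA_real_
  }
  attr(out, "siteIds") <- as.integer(cfg$site_ids)
  attr(out, "clipFraction") <- clipped / total
  out
}

simSurvivalFromCategories <- function(cfg, categories, ages) {
  n <- length(categories)
  lhr <- ifelse(categories == "methylated", log(cfg$hr_meth_vs_gray),
         ifelse(categories == "unmethylated", log(cfg$hr_unmeth_vs_gray), 0))
  lhr <- lhr + log(cfg$hr_age) * (ages >= cfg$age_cutoff)
  shape <- cfg$weibull_shape
  scale <- cfg$baseline_median_os / log(2)^(1 / shape)
  # inverse of H(t) = (t/scale)^shape * exp(lhr)
  u <- stats::runif(n)
  tt <- scale * (-log(u) / exp(lhr))^(1 / shape)
  cens <- if (is.finite(cfg$followup_months))
    stats::runif(n, 0, cfg$followup_months) else rep(Inf, n)
  event <- tt <= cens
  os <- pmin(tt, cens)
  os <- pmax(os, 1e-3)   # os_months must be strictly positive
  list(os_months = os, event = event)
}

#' Simulate per-CpG methylation profiles
#'
#' Draws a latent mean methylation per sample from the two-component
#' truncated-normal mixture, adds site-level noise proportional to the mean
#' (calibrated analytically so that pairwise inter-site correlation is
#' approximately \code{cpg_correlation}), then emits \code{n_runs}
#' replicate runs per sample with a shared run-level shift whose SD grows
#' with methylation. Values are clipped to [0, 100]; the attribute
#' \code{clipFraction} reports how often.
#'
#' @param config List from \code{\link{simConfig}}.
#' @return Run-level data.frame in the \code{\link{readPyroRuns}} layout;
#'   attributes \code{latentMeans}, \code{clipFraction}, \code{siteIds}.
#' @export
simulateMethylationProfiles <- function(config) {
  withr::with_seed(config$seed, {
    m <- simLatent(config)
    out <- simProfilesFromLatent(config, m)
    attr(out, "latentMeans") <- m
    out
  })
}

#' Simulate survival outcomes for categorised samples
#'
#' Draws survival times from the (default exponential, optionally Weibull)
#' baseline hazard scaled by the category and age-group hazard ratios, with
#' uniform administrative censoring over \code{followup_months}.
#'
#' @param config List from \code{\link{simConfig}}.
#' @param categories Factor/character of true categories (levels
#'   unmethylated/gray/methylated; gray is the reference).
#' @param ages Numeric ages in years.
#' @return data.frame of clinical records (sample ids S0001...).
#' @export
simulateSurvival <- function(config, categories, ages) {
  withr::with_seed(config$seed + 1L, {
    sv <- simSurvivalFromCategories(config, as.character(categories), ages)
    sex <- ifelse(stats::rbinom(length(ages), 1, config$prop_male) == 1,
                  "male", "female")
    data.frame(sample_id = sprintf("S%04d", seq_along(ages)),
               age_years = ages, sex = sex,
               os_months = sv$os_months, event = sv$event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete cohort with ground truth
#'
#' Composes the methylation and survival generators under one RNG stream
#' seeded from \code{config$seed}.
#'
#' @param config List from \code{\link{simConfig}}.
#' @return List: \code{cohort} (a \linkS4class{PyroCohort}) and
#'   \code{truth} (data.frame with each sample's latent mean, true category
#'   under (true_g, true_M), age group), plus \code{clipFraction}.
#' @export
simulateCohort <- function(config) {
  withr::with_seed(config$seed, {
    m <- simLatent(config)
    runs <- simProfilesFromLatent(config, m)
    cats <- categorize(m, M = config$true_M, g = config$true_g)
    ages <- rtruncnorm(config$n_samples, config$age_mean, config$age_sd,
                       config$age_min, config$age_max)
    sv <- simSurvivalFromCategories(config, as.character(cats), ages)
    sex <- ifelse(stats::rbinom(config$n_samples, 1, config$prop_male) == 1,
                  "male", "female")
    ids <- sprintf("S%04d", seq_len(config$n_samples))
    clinical <- data.frame(sample_id = ids, age_years = ages, sex = sex,
                           os_months = sv$os_months, event = sv$event,
                           stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = ids, latent_mean = m,
                        true_category = as.character(cats),
                        age_over_cutoff = ages >= config$age_cutoff,
                        stringsAsFactors = FALSE)
    attr(truth, "config") <- config
    list(cohort = PyroCohort(runs, clinical, config$site_ids),
         truth = truth,
         clipFraction = attr(runs, "clipFraction"))
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the pyro and clinical tables in the exact dialects read by
#' \code{\link{readPyroRuns}} / \code{\link{readClinical}}, plus a
#' ground-truth sidecar TSV.
#'
#' @param sim Output of \code{\link{simulateCohort}}.
#' @param outDir Output directory, created if needed.
#' @return Invisibly, the three paths written.
#' @export
writeSimulatedCohort <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(outDir, "pyro.csv")
  cp <- file.path(outDir, "clinical.csv")
  tp <- file.path(outDir, "truth.tsv")
  writePyroRuns(pyroRuns(sim$cohort), pp)
  writeClinical(clinicalData(sim$cohort), cp)
  utils::write.table(sim$truth, tp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(pp, cp, tp))
}
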