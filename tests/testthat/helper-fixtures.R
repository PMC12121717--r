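# In-code fixtures: tiny delimited tables and random survival datasets.

writeLinesTemp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal complete pyro table on a 3-site panel
toyPyroLines <- function() c(
  "sample_id,run_id,cpg_72,cpg_73,cpg_74",
  "S1,R1,10,12,14",
  "S1,R2,12,14,16",
  "S2,R1,2,3,4",
  "S2,R2,2,3,4")

toyClinicalLines <- function() c(
  "sample_id,age_years,sex,os_months,event",
  "S1,57.5,female,10.5,1",
  "S2,70,male,8,0")

# random small survival dataset with tied event times (for oracle checks)
randSurvData <- function(n, seed, p = 2) {
  withr::with_seed(seed, {
    X <- cbind(a = stats::rnorm(n), b = stats::rbinom(n, 1, 0.5))[, seq_len(p), drop = FALSE]
    tt <- ceiling(stats::rexp(n, 0.15) * 2) / 2   # 0.5-month grid -> ties
    ev <- stats::rbinom(n, 1, 0.7) == 1
    if (!any(ev)) ev[1] <- TRUE
    list(time = tt, event = ev, X = X)
  })
}

# assembled analysis data with category-dependent hazards (skips the
# methylation-profile layer; used by method-level tests)
randAnalysisData <- function(n, seed, g = 5, M = 12,
                             hrMeth = 0.53, hrUnmeth = 1.8, hrAge = 2.5,
                             followup = 40) {
  withr::with_seed(seed, {
    m <- ifelse(stats::rbinom(n, 1, 0.49) == 1,
                pmin(pmax(stats::rnorm(n, 39, 16), 0), 100),
                pmin(pmax(stats::rnorm(n, 3, 2.5), 0), 100))
    age <- pmin(pmax(stats::rnorm(n, 57, 12), 20), 85)
    cat3 <- as.character(categorize(m, M = M, g = g))
    lhr <- ifelse(cat3 == "methylated", log(hrMeth),
           ifelse(cat3 == "unmethylated", log(hrUnmeth), 0)) +
      log(hrAge) * (age >= 65)
    tt <- stats::rexp(n, rate = (log(2) / 10.5) * exp(lhr))
    cens <- stats::runif(n, 0, followup)
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               mean_methylation = m, age_years = age,
               sex = ifelse(stats::rbinom(n, 1, 0.64) == 1, "male", "female"),
               os_months = pmax(pmin(tt, cens), 1e-3),
               event = tt <= cens, stringsAsFactors = FALSE)
  })
}
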