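test_that("categorisation follows the half-open boundary conventions", {
  expect_equal(as.character(categorize(c(4.9, 5.0, 11.999, 12.0), M = 12, g = 5)),
               c("unmethylated", "gray", "gray", "methylated"))
  expect_equal(as.character(categorize(c(11.9, 12), M = 12)),
               c("unmethylated", "methylated"))
  expect_error(categorize(150, M = 12), class = "gzRangeError")
  expect_error(categorize(5, M = 12, g = 12), class = "gzConfigError")
})

test_that("candidate enumeration covers every admissible integer lower bound", {
  c12 <- enumerateCandidates(12)
  expect_equal(c12$g, 1:11)
  expect_equal(unique(c12$M), 12)
  expect_equal(nrow(enumerateCandidates(10)), 9L)
  expect_equal(nrow(enumerateCandidates(1)), 0L)
})

test_that("cohort assembly drops unmatched records with logged counts", {
  samples <- data.frame(sample_id = c("A", "B", "C"), cpg_1 = 1:3,
                        mean_methylation = c(3, 8, 20), n_runs = 2L,
                        replicate_sd = 0)
  clinical <- data.frame(sample_id = c("A", "B", "D"), age_years = c(60, 70, 50),
                         sex = "male", os_months = c(5, 6, 7),
                         event = c(TRUE, FALSE, TRUE))
  expect_message(expect_message(dat <- assembleCohort(samples, clinical),
                                "no clinical record"), "no methylation")
  expect_equal(dat$sample_id, c("A", "B"))
  expect_equal(attr(dat, "droppedSamples"), "C")
  expect_equal(attr(dat, "droppedClinical"), "D")
})

test_that("candidate models use the gray-zone reference and nest the binary model", {
  dat <- randAnalysisData(250, seed = 42)
  binary <- fitBinaryModel(dat, 12)
  cr <- fitCandidateModel(dat, g = 5, M = 12, binaryModel = binary)
  expect_equal(sum(cr@counts), nrow(dat))
  expect_named(cr@counts, c("unmethylated", "gray", "methylated"))
  # nesting: binary loglik cannot exceed the candidate's
  expect_lte(binary@loglikFit, cr@loglik + 1e-8)
  expect_gte(cr@lrtStat, 0)
  # coarsening correctness: forcing the unmethylated coefficient to zero
  # (gray merged into the reference) reproduces the binary model
  cats <- categorize(dat$mean_methylation, M = 12, g = 5)
  Xm <- cbind(age_over_cutoff = as.numeric(dat$age_years >= 65),
              methylated = as.numeric(cats == "methylated"))
  merged <- coxFit(dat$os_months, dat$event, Xm)
  expect_equal(merged@loglikFit, binary@loglikFit, tolerance = 1e-8)
})

test_that("an empty category yields an inestimable, non-qualifying result", {
  dat <- randAnalysisData(80, seed = 2)
  dat$mean_methylation[dat$mean_methylation >= 10 & dat$mean_methylation < 12] <- 14
  dat$mean_methylation[dat$mean_methylation >= 11 & dat$mean_methylation < 12] <- 14
  cr <- fitCandidateModel(dat, g = 11, M = 12)
  expect_false(cr@qualifies)
  expect_match(cr@note, "empty category")
  expect_true(is.na(cr@hrMethVsGray))
  expect_equal(sum(cr@counts), nrow(dat))
})

test_that("strong three-category effects are recovered and qualify", {
  dat <- randAnalysisData(1500, seed = 77)
  cr <- suppressWarnings(fitCandidateModel(dat, g = 5, M = 12))
  expect_true(cr@hrMethVsGray > 0.53 * 0.7 && cr@hrMethVsGray < 0.53 * 1.3)
  expect_true(cr@hrUnmethVsGray > 1.8 * 0.7 && cr@hrUnmethVsGray < 1.8 * 1.3)
  expect_lt(cr@pMethVsGray, 0.05)
  expect_lt(cr@pUnmethVsGray, 0.05)
  # sex adjustment (null sex effect in the generator) leaves the verdict
  crSex <- suppressWarnings(fitCandidateModel(dat, g = 5, M = 12, includeSex = TRUE))
  expect_identical(cr@qualifies, crSex@qualifies)
})

test_that("univariate screen estimates known effects and survives degeneracy", {
  dat <- randAnalysisData(1000, seed = 55)
  sc <- suppressWarnings(univariateScreen(dat, M = 12))
  ageRow <- sc$terms[sc$terms$term == "age_over_cutoff", ]
  expect_true(ageRow$hr > 2.0 && ageRow$hr < 3.1)
  expect_equal(nrow(sc$categories), 11L)
  # constant covariate: inestimable row, screen still completes
  dat$sex <- "male"
  sc2 <- suppressWarnings(univariateScreen(dat, M = 12))
  expect_match(sc2$terms$note[sc2$terms$term == "male_vs_female"], "inestimable")
  expect_false(anyNA(sc2$terms$hr[-1]))
})

test_that("selection applies the three qualification criteria exactly", {
  dat <- randAnalysisData(300, seed = 1001)
  dec <- suppressWarnings(sweepCandidates(dat, 12))
  r <- dec@rationale
  # soundness: re-evaluate the predicates from the candidate slots
  for (cr in dec@candidates) {
    if (is.na(cr@g)) next
    expected <- isTRUE(cr@hrMethVsGray < 1 && cr@pMethVsGray < dec@alpha &&
                       cr@hrUnmethVsGray > 1 && cr@pUnmethVsGray < dec@alpha &&
                       cr@lrtP < dec@alpha)
    expect_identical(cr@qualifies, expected)
  }
  if (!is.null(dec@optimal)) {
    q <- r[r$qualifies, ]
    expect_equal(dec@optimal$g, q$g[which.max(q$lrt_stat)])
  }
  # singleton qualifying candidate is returned regardless of LRT rank
  only <- dec@candidates[!is.na(vapply(dec@candidates, function(x) x@g, integer(1)))]
  fake <- lapply(only, function(cr) {
    cr@qualifies <- FALSE
    cr@pMethVsGray <- 1; cr@pUnmethVsGray <- 1; cr@lrtP <- 1
    cr
  })
  fake[[3]]@qualifies <- TRUE
  fake[[3]]@hrMethVsGray <- 0.5; fake[[3]]@pMethVsGray <- 0.01
  fake[[3]]@hrUnmethVsGray <- 2; fake[[3]]@pUnmethVsGray <- 0.01
  fake[[3]]@lrtP <- 0.01
  fake[[3]]@lrtStat <- 0.001   # worst LRT rank; must still be selected
  dec2 <- selectOptimal(fake, alpha = 0.05)
  expect_equal(dec2@optimal$g, fake[[3]]@g)
  expect_error(selectOptimal(list()), class = "gzConfigError")
})

test_that("partition and nesting invariants hold on random cohorts and specs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(30:60, 1)
    dat <- randAnalysisData(n, seed = 5000 + i)
    M <- sample(8:15, 1)
    g <- sample(seq_len(M - 1), 1)
    cats <- categorize(dat$mean_methylation, M = M, g = g)
    expect_equal(sum(table(cats)), n)
    if (any(table(cats) == 0)) next
    binary <- suppressWarnings(fitBinaryModel(dat, M))
    cr <- suppressWarnings(fitCandidateModel(dat, g, M, binaryModel = binary))
    expect_gte(cr@lrtStat, 0)
    expect_lte(binary@loglikFit, cr@loglik + 1e-8)
  }
})

test_that("the full pipeline is deterministic and recovers a planted gray zone", {
  sim <- simulateCohort(simConfig(n_samples = 250, seed = 31))
  dir <- tempfile(); dir.create(dir)
  pyroPath <- file.path(dir, "pyro.csv")
  clinPath <- file.path(dir, "clinical.csv")
  writePyroRuns(pyroRuns(sim$cohort), pyroPath)
  writeClinical(clinicalData(sim$cohort), clinPath)

  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  cfg <- list(meth_threshold = 12)
  r1 <- suppressWarnings(runGrayZoneAnalysis(pyroPath, clinPath, cfg, out1))
  r2 <- suppressWarnings(runGrayZoneAnalysis(pyroPath, clinPath, cfg, out2))
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
  expect_identical(readLines(file.path(out1, "candidates.tsv")),
                   readLines(file.path(out2, "candidates.tsv")))
  expect_equal(r1$decision$n_candidates, 11L)
  expect_true(file.exists(file.path(out1, "km_curves.tsv")))
})

test_that("exclude_and_rerun reports both analyses side by side", {
  sim <- simulateCohort(simConfig(n_samples = 150, seed = 13))
  dir <- tempfile(); dir.create(dir)
  pyroPath <- file.path(dir, "pyro.csv"); clinPath <- file.path(dir, "clin.csv")
  writePyroRuns(pyroRuns(sim$cohort), pyroPath)
  writeClinical(clinicalData(sim$cohort), clinPath)
  rep <- suppressWarnings(runGrayZoneAnalysis(
    pyroPath, clinPath,
    list(meth_threshold = 12, outlier_action = "exclude_and_rerun",
         outlier_quantile = 0.8)))
  expect_gt(rep$outliers$n_flagged, 0)
  expect_false(is.null(rep$rerun_without_outliers))
  expect_equal(rep$rerun_without_outliers$meth_threshold, 12L)
})
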