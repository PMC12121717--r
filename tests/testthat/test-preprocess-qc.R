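test_that("runs with any failed site are excluded, complete runs kept", {
  lines <- c("sample_id,run_id,cpg_72,cpg_73,cpg_74",
             "S1,R1,10,12,14", "S1,R2,10,,14",
             "S2,R1,2,3,4", "S2,R2,2,3,4",
             "S3,R1,,,")
  runs <- readPyroRuns(writeLinesTemp(lines), 72:74)
  split <- excludeFailedRuns(runs)
  expect_equal(paste(split$kept$sample_id, split$kept$run_id),
               c("S1 R1", "S2 R1", "S2 R2"))
  expect_equal(nrow(split$excluded), 2L)
  expect_equal(nrow(split$kept) + nrow(split$excluded), nrow(runs))
  # a sample whose every run failed contributes nothing downstream
  agg <- aggregateReplicates(split$kept)
  expect_false("S3" %in% agg$sample_id)
})

test_that("replicate aggregation matches closed forms and is order-invariant", {
  lines <- c("sample_id,run_id,cpg_72,cpg_73,cpg_74",
             "S1,R1,10,10,10", "S1,R2,12,12,12")
  runs <- readPyroRuns(writeLinesTemp(lines), 72:74)
  agg <- aggregateReplicates(runs)
  expect_equal(unlist(agg[1, paste0("cpg_", 72:74)], use.names = FALSE),
               rep(11, 3))
  expect_equal(agg$mean_methylation, 11)
  expect_equal(agg$replicate_sd, sqrt(2))

  perm <- runs[c(2, 1), ]
  aggPerm <- aggregateReplicates(perm)
  expect_equal(aggPerm$mean_methylation, agg$mean_methylation)
  expect_equal(aggPerm$replicate_sd, agg$replicate_sd)

  # single-run aggregation is the identity on site values
  single <- runs[1, ]
  aggS <- aggregateReplicates(single)
  expect_identical(unlist(aggS[1, paste0("cpg_", 72:74)], use.names = FALSE),
                   unlist(runs[1, paste0("cpg_", 72:74)], use.names = FALSE))
  expect_true(is.na(aggS$replicate_sd))
})

test_that("replicate SD summary averages qualifying samples, overall and below M", {
  samples <- data.frame(sample_id = c("A", "B", "C"),
                        cpg_72 = c(5, 6, 50), mean_methylation = c(5, 6, 50),
                        n_runs = c(2L, 2L, 1L),
                        replicate_sd = c(sqrt(2), 0, NA))
  s <- replicateSdSummary(samples, threshold = 12)
  expect_equal(s$mean_sd_all, sqrt(2) / 2)
  expect_equal(s$mean_sd_below_threshold, sqrt(2) / 2)

  # brute-force recomputation on a random cohort
  set.seed(3)
  samples2 <- data.frame(sample_id = letters[1:5], cpg_72 = runif(5, 0, 30),
                         n_runs = c(2L, 2L, 2L, 1L, 2L),
                         replicate_sd = c(runif(4, 0, 3), NA))
  samples2$replicate_sd[4] <- NA
  samples2$mean_methylation <- samples2$cpg_72
  s2 <- replicateSdSummary(samples2, threshold = 15)
  ok <- samples2$n_runs >= 2
  expect_equal(s2$mean_sd_all, mean(samples2$replicate_sd[ok]), tolerance = 1e-12)
  below <- ok & samples2$mean_methylation < 15
  expect_equal(s2$mean_sd_below_threshold, mean(samples2$replicate_sd[below]),
               tolerance = 1e-12)

  one <- samples[3, ]
  expect_error(replicateSdSummary(one, 12), class = "gzDataError")
})

test_that("per-CpG summaries and Pearson correlations are correct", {
  X <- matrix(c(1, 4, 2, 8,   3, 9, 5, 17,   7, 7, 7, 7), nrow = 4)
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        cpg_1 = X[, 1], cpg_2 = X[, 2], cpg_3 = X[, 3])
  samples$mean_methylation <- rowMeans(X)
  samples$n_runs <- 2L; samples$replicate_sd <- 0
  qc <- cpgSummary(samples)
  # site 2 = 2 * site 1 + 1 -> r = 1 exactly
  expect_equal(qc$correlation["cpg_1", "cpg_2"], 1)
  # hand-computed Pearson for columns 1 and 2 via the definition
  r12 <- sum((X[, 1] - mean(X[, 1])) * (X[, 2] - mean(X[, 2]))) /
    sqrt(sum((X[, 1] - mean(X[, 1]))^2) * sum((X[, 2] - mean(X[, 2]))^2))
  expect_equal(qc$correlation["cpg_1", "cpg_2"], r12, tolerance = 1e-12)
  # constant site: correlations undefined (NA), not zero
  expect_true(all(is.na(qc$correlation["cpg_3", ])))
  expect_equal(qc$per_site$median[1], stats::median(X[, 1]))
  expect_error(cpgSummary(samples[1, , drop = FALSE]), class = "gzDataError")
})

test_that("Mahalanobis distances match explicit matrix-inverse computation", {
  set.seed(9)
  X <- cbind(rnorm(6, 10, 2), rnorm(6, 20, 5))
  samples <- data.frame(sample_id = paste0("S", 1:6),
                        cpg_1 = X[, 1], cpg_2 = X[, 2])
  d2 <- mahalanobisDistances(samples)
  # hand computation with the explicit 2x2 inverse
  S <- stats::cov(X); mu <- colMeans(X)
  det2 <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det2
  C <- sweep(X, 2, mu)
  expect_equal(unname(d2), rowSums((C %*% Sinv) * C), tolerance = 1e-10)
  # univariate reduction: d2 = (x - mu)^2 / s^2
  one <- samples[, c("sample_id", "cpg_1")]
  expect_error(d1 <- mahalanobisDistances(one), NA)
  expect_equal(unname(d1), (X[, 1] - mean(X[, 1]))^2 / stats::var(X[, 1]),
               tolerance = 1e-10)
})

test_that("Mahalanobis self-checks: zero at the mean, d2 sum, affine invariance", {
  set.seed(21)
  base <- matrix(rnorm(10 * 3), 10, 3)
  # mirror the points and append the centre so one sample sits at the mean
  X <- rbind(base, -base, 0)
  samples <- data.frame(sample_id = paste0("S", 1:21))
  samples[paste0("cpg_", 1:3)] <- as.data.frame(X + 50)
  d2 <- mahalanobisDistances(samples)
  expect_equal(unname(d2[21]), 0, tolerance = 1e-16)
  expect_equal(sum(d2), (nrow(X) - 1) * 3, tolerance = 1e-6)

  A <- matrix(c(2, 0.5, 0, 1, 3, 0.2, 0, 0, 1.5), 3, 3)
  samples2 <- samples
  samples2[paste0("cpg_", 1:3)] <-
    as.data.frame(sweep(as.matrix(samples[paste0("cpg_", 1:3)]) %*% A, 2, c(-5, 2, 1), "+"))
  expect_equal(unname(mahalanobisDistances(samples2)), unname(d2),
               tolerance = 1e-8)
})

test_that("singular covariance errors unless the pseudo-inverse is requested", {
  X <- cbind(1:8, (1:8) * 2)   # perfectly collinear sites
  samples <- data.frame(sample_id = paste0("S", 1:8),
                        cpg_1 = X[, 1], cpg_2 = X[, 2])
  expect_error(mahalanobisDistances(samples), class = "gzDegeneracyError")
  d2 <- mahalanobisDistances(samples, pseudoInverse = TRUE)
  expect_true(all(d2 >= 0))
})

test_that("outlier flagging uses the chi-squared cutoff; flag_only retains samples", {
  set.seed(5)
  X <- matrix(rnorm(40 * 2, 20, 3), 40, 2)
  X[1, ] <- X[1, ] + 30   # displace one sample ~10 SD on both sites
  samples <- data.frame(sample_id = paste0("S", 1:40),
                        cpg_1 = X[, 1], cpg_2 = X[, 2])
  d2 <- mahalanobisDistances(samples)
  rep <- flagOutliers(d2, nSites = 2)
  expect_equal(rep$cutoff, stats::qchisq(0.975, df = 2))
  expect_true("S1" %in% rep$flagged)
  expect_identical(rep$action, "flag_only")
  # all distances under the cutoff -> empty flag set
  rep2 <- flagOutliers(d2[d2 < rep$cutoff], nSites = 2)
  expect_length(rep2$flagged, 0)
  expect_error(flagOutliers(d2, 2, quantile = 1.2), class = "gzConfigError")
})

test_that("50/50 threshold matches exhaustive search with smallest-t tie-break", {
  samples <- data.frame(mean_methylation = c(1, 2, 3, 20, 21, 22))
  expect_equal(deriveBinaryThreshold(samples), 4L)  # every t in 4..20 ties at 0

  # agreement with an inline exhaustive search on random cohorts
  set.seed(17)
  for (i in 1:200) {
    m <- runif(sample(5:60, 1), 0, 100)
    best <- which.min(vapply(1:99, function(t) abs(sum(m >= t) - length(m) / 2),
                             numeric(1)))
    expect_identical(deriveBinaryThreshold(data.frame(mean_methylation = m)),
                     as.integer(best))
  }
  # odd cohort size: minimal imbalance is at least 0.5
  m <- c(1, 6, 40)
  imb <- abs(sum(m >= deriveBinaryThreshold(data.frame(mean_methylation = m))) - 1.5)
  expect_gte(imb, 0.5)
})

test_that("discordance follows category boundaries and partition refinement", {
  mk <- function(m1, m2) {
    data.frame(sample_id = c("S1", "S1"), run_id = c("R1", "R2"),
               cpg_1 = c(m1, m2))
  }
  expect_equal(detectDiscordant(mk(4.8, 5.2), M = 12, g = 5), "S1")
  expect_length(detectDiscordant(mk(6.0, 6.0), M = 12, g = 5), 0)
  # straddling M is discordant under binary AND three-category specs
  expect_equal(detectDiscordant(mk(11.9, 12.1), M = 12), "S1")
  expect_equal(detectDiscordant(mk(11.9, 12.1), M = 12, g = 5), "S1")

  # finer partition discordance is a superset of the binary discordance
  set.seed(31)
  runs <- do.call(rbind, lapply(1:60, function(i) {
    m <- runif(1, 0, 30)
    data.frame(sample_id = sprintf("S%02d", i), run_id = c("R1", "R2"),
               cpg_1 = pmax(m + rnorm(2, 0, 1.5), 0))
  }))
  discBin <- detectDiscordant(runs, M = 12)
  disc3 <- detectDiscordant(runs, M = 12, g = 5)
  expect_true(all(discBin %in% disc3))
  expect_gt(length(disc3), length(discBin))  # boundary-straddlers add cases
})
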