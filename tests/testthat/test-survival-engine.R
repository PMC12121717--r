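test_that("null-model log partial likelihood has its closed form", {
  f0 <- coxFit(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(f0@loglikFit, -log(6), tolerance = 1e-12)
  expect_equal(f0@loglikNull, -log(6), tolerance = 1e-12)
  expect_identical(f0@converged, TRUE)
})

test_that("single-covariate fit matches brute-force partial-likelihood maximisation", {
  # 4 subjects, binary covariate, no ties: explicit partial likelihood
  tt <- c(1, 2, 3, 4)
  ev <- c(TRUE, TRUE, FALSE, TRUE)
  x <- c(1, 0, 1, 0)
  pl <- function(b) {
    risk <- function(i) sum(exp(b * x[tt >= tt[i]]))
    sum(vapply(which(ev), function(i) b * x[i] - log(risk(i)), numeric(1)))
  }
  grid <- seq(-4, 4, by = 1e-4)
  bStar <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit <- coxFit(tt, ev, cbind(x = x))
  expect_equal(unname(coef(fit)), bStar, tolerance = 2e-4)
  expect_equal(logLik(fit), pl(bStar), tolerance = 1e-6)
})

test_that("fits are invariant to time rescaling and Efron equals Breslow without ties", {
  d <- randSurvData(35, seed = 4)
  d$time <- d$time + seq_along(d$time) * 1e-3   # break all ties
  fe <- coxFit(d$time, d$event, d$X, ties = "efron")
  fb <- coxFit(d$time, d$event, d$X, ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-8)
  expect_equal(logLik(fe), logLik(fb), tolerance = 1e-8)

  f7 <- coxFit(d$time * 7, d$event, d$X)
  expect_equal(coef(f7), coef(fe), tolerance = 1e-10)
})

test_that("coefficients, SEs, logliks and score match the survival package with ties", {
  skip_if_not_installed("survival")
  for (s in 1:12) {
    d <- randSurvData(sample(20:40, 1), seed = 100 + s)
    for (ties in c("efron", "breslow")) {
      mine <- coxFit(d$time, d$event, d$X, ties = ties)
      ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X, ties = ties)
      expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(mine@se), unname(sqrt(diag(stats::vcov(ref)))),
                   tolerance = 1e-6)
      expect_equal(mine@loglikFit, ref$loglik[2], tolerance = 1e-6)
      expect_equal(mine@loglikNull, ref$loglik[1], tolerance = 1e-6)
      expect_equal(mine@scoreStat, unname(ref$score), tolerance = 1e-6)
    }
  }
})

test_that("degenerate designs error; monotone likelihood warns, not errors", {
  d <- randSurvData(20, seed = 8)
  expect_error(coxFit(d$time, d$event, cbind(k = rep(1, 20))),
               "k", class = "gzDegeneracyError")
  # perfectly separating covariate: all early deaths in one group
  tt <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(fit <- coxFit(tt, ev, cbind(x = x)), "converge")
  expect_false(fit@converged)
  expect_true(fit@loglikFit >= fit@loglikNull - 1e-8)
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  # 3 subjects: event at 1, censored at 2, event at 3
  km <- kmFit(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km@surv, c(2 / 3, 0))
  expect_equal(km@median, 3)

  # all censored: flat curve, unbounded median
  km0 <- kmFit(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_length(km0@time, 0)
  expect_identical(km0@median, Inf)

  # 10 subjects with ties: frozen product-limit/Greenwood/log(-log) values
  tt <- c(1, 2, 2, 3, 4, 4, 5, 6, 7, 9)
  ev <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  km2 <- kmFit(tt, ev)
  expect_equal(km2@time, c(1, 2, 4, 6))
  expect_equal(km2@surv,
               c(0.9, 0.7, 0.466666666667, 0.311111111111), tolerance = 1e-10)
  expect_equal(km2@greenwoodVar,
               c(0.009, 0.021, 0.0274814814815, 0.0283456790123),
               tolerance = 1e-10)
  expect_equal(km2@lower,
               c(0.4730092713621, 0.3287165932797, 0.1495518180897,
                 0.0552389048792), tolerance = 1e-9)
  expect_equal(km2@upper,
               c(0.985281393367, 0.891949041225, 0.736610236678,
                 0.624540487460), tolerance = 1e-9)
  expect_equal(km2@median, 4)
  expect_equal(km2@medianCI, c(1, Inf))  # upper band never crosses 0.5
})

test_that("KM equals the empirical survival fraction at the last event time", {
  set.seed(12)
  tt <- rexp(40, 0.1)
  ev <- rep(TRUE, 40)   # no censoring after the last event
  km <- kmFit(tt, ev)
  lastEv <- max(tt)
  expect_equal(km@surv[length(km@surv)], mean(tt > lastEv))  # = 0
  mid <- km@time[20]
  expect_equal(km@surv[20], mean(tt > mid))
})

test_that("nested LRT: identity gives 0 with p = 1; subject sets must match", {
  d <- randSurvData(30, seed = 6)
  full <- coxFit(d$time, d$event, d$X)
  red <- coxFit(d$time, d$event, d$X[, 1, drop = FALSE])
  same <- lrtNested(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- lrtNested(full, red)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, stats::pchisq(lrt$statistic, 1, lower.tail = FALSE))

  d2 <- randSurvData(30, seed = 7)
  other <- coxFit(d2$time, d2$event, d2$X[, 1, drop = FALSE])
  expect_error(lrtNested(full, other), class = "gzComparabilityError")
})

test_that("proportional-hazards parameter recovery at moderate scale", {
  # per-seed sampling SD of beta-hat is ~0.058 here (about 1200 events,
  # balanced binary covariate), so 0.2 is a ~3.4-sigma bound per seed
  errs <- vapply(1:5, function(s) {
    withr::with_seed(400 + s, {
      n <- 2000
      x <- stats::rbinom(n, 1, 0.5)
      tt <- stats::rexp(n, 0.07 * exp(log(2) * x))
      cens <- stats::runif(n, 0, 25)
      fit <- coxFit(pmin(tt, cens), tt <= cens, cbind(x = x))
      unname(coef(fit)) - log(2)
    })
  }, numeric(1))
  expect_true(all(abs(errs) < 0.2))
  expect_lt(abs(mean(errs)), 0.08)   # no systematic bias
})
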