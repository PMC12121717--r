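## Self-contained Kaplan-Meier and Cox proportional-hazards estimation.
## The Cox partial likelihood uses the Efron (default) or Breslow tie
## correction and is maximised by Newton-Raphson with step-halving.

## Evaluate log partial likelihood, gradient and observed information at
## beta. X may have zero columns (null model). Handles its own sorting.
coxEval <- function(time, event, X, beta, ties) {
  n <- length(time)
  p <- ncol(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  X <- X[ord, , drop = FALSE]
  eta <- if (p) drop(X %*% beta) else numeric(n)
  # centring guard against exp() overflow; the partial likelihood depends on
  # eta only through risk-set ratios, and the shift cancels in ll (below)
  shift <- if (p) mean(eta) else 0
  w <- exp(eta - shift)

  pp <- if (p) p * (p + 1L) / 2L else 0L
  idx <- if (p) which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE) else NULL
  unpack <- function(v) {
    m <- matrix(0, p, p)
    m[cbind(idx[, 1], idx[, 2])] <- v
    m[cbind(idx[, 2], idx[, 1])] <- v
    m
  }
  wX <- if (p) w * X else NULL
  wXX <- if (p) {
    m <- matrix(0, n, pp)
    for (k in seq_len(pp)) m[, k] <- wX[, idx[k, 1]] * X[, idx[k, 2]]
    m
  } else NULL
  cw0 <- revcumsum(w)
  cw1 <- if (p) revcumsumMat(wX) else NULL
  cw2 <- if (p) revcumsumMat(wXX) else NULL

  evTimes <- unique(time[event])
  firstIdx <- match(evTimes, time)            # risk set = all with time >= t
  deathSets <- split(which(event), match(time[event], evTimes))

  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (k in seq_along(evTimes)) {
    first <- firstIdx[k]
    dset <- deathSets[[k]]
    d <- length(dset)
    S0 <- cw0[first]
    ll <- ll + sum(eta[dset] - shift)
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0)
      if (p) {
        S1 <- cw1[first, ]
        mu <- S1 / S0
        grad <- grad + colSums(X[dset, , drop = FALSE]) - d * mu
        info <- info + d * (unpack(cw2[first, ] / S0) - tcrossprod(mu))
      }
    } else {
      frac <- (seq_len(d) - 1) / d
      s0d <- sum(w[dset])
      A0 <- S0 - frac * s0d
      ll <- ll - sum(log(A0))
      if (p) {
        s1d <- colSums(wX[dset, , drop = FALSE])
        s2d <- colSums(wXX[dset, , drop = FALSE])
        A1 <- matrix(cw1[first, ], d, p, byrow = TRUE) - frac %o% s1d   # d x p
        A2 <- matrix(cw2[first, ], d, pp, byrow = TRUE) - frac %o% s2d  # d x pp
        Mu <- A1 / A0
        grad <- grad + colSums(X[dset, , drop = FALSE]) - colSums(Mu)
        info <- info + unpack(colSums(A2 / A0)) - crossprod(Mu)
      }
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the tie-corrected log partial likelihood by Newton-Raphson with
#' step-halving (at most 10 halvings per step). Convergence is declared when
#' the relative change in log likelihood falls below 1e-9, within at most 50
#' iterations. Standard errors are taken from the inverse observed
#' information at the maximum; hazard-ratio confidence intervals are Wald
#' intervals exp(beta +/- 1.959964 se). The global score test evaluates all
#' coefficients against zero at beta = 0.
#'
#' Monotone (non-converging) likelihoods, e.g. from a perfectly separating
#' category, are reported with \code{converged = FALSE} and a warning rather
#' than an error; the affected hazard ratio carries an effectively infinite
#' confidence bound.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical event indicator (TRUE = death observed).
#' @param covariates Numeric matrix or data.frame, one column per model
#'   term (categorical terms already expanded to indicators); NULL fits the
#'   null model.
#' @param ties Tie correction: "efron" (default) or "breslow".
#' @return A \linkS4class{CoxPHModel}.
#' @export
coxFit <- function(time, event, covariates = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  if (anyNA(time) || anyNA(event))
    gzValidityError("time and event must not contain missing values")
  if (length(time) != length(event))
    gzValidityError("time and event lengths differ")
  if (!any(event)) gzValidityError("at least one event is required")
  X <- if (is.null(covariates)) {
    matrix(0, length(time), 0)
  } else {
    m <- as.matrix(as.data.frame(covariates))
    storage.mode(m) <- "double"
    m
  }
  if (nrow(X) != length(time))
    gzValidityError("covariates must have one row per subject")
  if (anyNA(X))
    gzValidityError("covariates must not contain missing values (drop rows upstream)")
  if (ncol(X)) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    const <- which(apply(X, 2, function(col) max(col) - min(col) == 0))
    if (length(const))
      gzDegeneracyError("covariate column '%s' is constant", colnames(X)[const[1]])
  }
  p <- ncol(X)

  at0 <- coxEval(time, event, X, numeric(p), ties)
  loglikNull <- at0$loglik
  scoreStat <- if (p) {
    tryCatch(drop(crossprod(at0$grad, solve(at0$info, at0$grad))),
             error = function(e) NA_real_)
  } else NA_real_
  scoreP <- if (p) stats::pchisq(scoreStat, df = p, lower.tail = FALSE) else NA_real_

  beta <- numeric(p)
  cur <- at0
  converged <- FALSE
  iter <- 0L
  if (p) {
    maxIter <- 50L
    tol <- 1e-9
    while (iter < maxIter) {
      iter <- iter + 1L
      step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
      if (is.null(step)) break
      newBeta <- beta + step
      newEval <- coxEval(time, event, X, newBeta, ties)
      halvings <- 0L
      while ((!is.finite(newEval$loglik) || newEval$loglik < cur$loglik) &&
             halvings < 10L) {
        halvings <- halvings + 1L
        newBeta <- beta + step / 2^halvings
        newEval <- coxEval(time, event, X, newBeta, ties)
      }
      if (!is.finite(newEval$loglik)) break
      improved <- newEval$loglik >= cur$loglik - 1e-12 * (abs(cur$loglik) + 1)
      done <- abs(newEval$loglik - cur$loglik) < tol * (abs(cur$loglik) + tol)
      if (improved) { beta <- newBeta; cur <- newEval }
      if (done) { converged <- TRUE; break }
      if (!improved) break   # step halving exhausted without improvement
    }
    if (converged && any(abs(beta) > 10)) {
      # the likelihood is monotone in a coefficient (e.g. a perfectly
      # separating category): the Newton iterates plateau at a huge beta
      converged <- FALSE
      warning("Cox partial likelihood appears monotone; a coefficient may be infinite (did not converge)")
    } else if (!converged) {
      warning("Cox model did not converge in ", iter,
              " iterations (possibly monotone likelihood)")
    }
  } else {
    converged <- TRUE
  }

  se <- if (p) {
    covb <- tryCatch(solve(cur$info), error = function(e) NULL)
    if (is.null(covb)) rep(Inf, p) else sqrt(pmax(diag(covb), 0))
  } else numeric(0)
  z <- stats::qnorm(0.975)
  hr <- exp(beta)
  hrCI <- cbind(lower = exp(beta - z * se), upper = exp(beta + z * se))
  waldP <- if (p) 2 * stats::pnorm(-abs(beta / se)) else numeric(0)
  names(beta) <- names(se) <- names(hr) <- names(waldP) <- colnames(X)
  if (p) rownames(hrCI) <- colnames(X)

  new("CoxPHModel",
      coef = beta, se = se, hr = hr, hrCI = hrCI, waldP = waldP,
      loglikNull = loglikNull, loglikFit = cur$loglik,
      scoreStat = scoreStat, scoreP = scoreP,
      n = length(time), nEvents = sum(event),
      converged = converged, iterations = iter, ties = ties)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve with Greenwood variance and
#' 95\% pointwise confidence bands on the log(-log) scale. The median is the
#' smallest event time at which the curve reaches 0.5 or below (Inf if
#' never); its confidence interval is read off where the confidence bands
#' cross 0.5, with -Inf/Inf where a band never crosses.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical event indicator.
#' @param confLevel Confidence level for the bands (default 0.95).
#' @return A \linkS4class{KMFit}.
#' @export
kmFit <- function(time, event, confLevel = 0.95) {
  event <- as.logical(event)
  if (length(time) != length(event) || anyNA(time) || anyNA(event))
    gzValidityError("time and event must be equal-length and complete")
  if (!length(time)) gzValidityError("at least one subject is required")
  evTimes <- sort(unique(time[event]))
  nRisk <- vapply(evTimes, function(t0) sum(time >= t0), numeric(1))
  nEvent <- vapply(evTimes, function(t0) sum(time == t0 & event), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  gwSum <- cumsum(nEvent / (nRisk * (nRisk - nEvent)))  # Inf if S drops to 0
  greenwoodVar <- surv^2 * gwSum
  greenwoodVar[surv == 0] <- 0
  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  # complementary log(-log) bands: S^exp(+/- z * se(log(-log S)))
  ok <- surv > 0 & surv < 1
  lower <- upper <- rep(NA_real_, length(surv))
  seCll <- sqrt(gwSum[ok]) / abs(log(surv[ok]))
  lower[ok] <- surv[ok]^exp(z * seCll)
  upper[ok] <- surv[ok]^exp(-z * seCll)

  med <- if (any(surv <= 0.5)) evTimes[match(TRUE, surv <= 0.5)] else Inf
  bandCross <- function(band) {
    hit <- !is.na(band) & band <= 0.5
    if (any(hit)) evTimes[match(TRUE, hit)] else NA_real_
  }
  lo <- bandCross(lower)
  hi <- bandCross(upper)
  medianCI <- c(if (is.na(lo)) -Inf else lo, if (is.na(hi)) Inf else hi)

  new("KMFit", time = as.numeric(evTimes), nRisk = nRisk, nEvent = nEvent,
      surv = surv, greenwoodVar = greenwoodVar, lower = lower, upper = upper,
      median = med, medianCI = medianCI,
      n = length(time), nEvents = sum(event), confLevel = confLevel)
}

#' Nested likelihood-ratio test between Cox models
#'
#' The statistic is 2 * (loglik(full) - loglik(reduced)), clipped at zero,
#' referred to a chi-squared distribution with df equal to the difference in
#' the number of estimated coefficients. The models must be fitted on the
#' identical subject set (checked via n, events, and the null log
#' likelihood, which depends only on the shared risk sets).
#'
#' @param full,reduced Fitted \linkS4class{CoxPHModel} objects; reduced must
#'   be nested in full.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
lrtNested <- function(full, reduced) {
  if (!is(full, "CoxPHModel") || !is(reduced, "CoxPHModel"))
    gzValidityError("lrtNested expects two CoxPHModel objects")
  if (full@n != reduced@n || full@nEvents != reduced@nEvents ||
      abs(full@loglikNull - reduced@loglikNull) > 1e-8)
    gzComparabilityError("models were not fitted on the identical subject set")
  df <- length(full@coef) - length(reduced@coef)
  if (df < 0)
    gzComparabilityError("reduced model has more coefficients than full model")
  statistic <- max(0, 2 * (full@loglikFit - reduced@loglikFit))
  p <- if (df == 0) 1 else stats::pchisq(statistic, df = df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p = p)
}
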