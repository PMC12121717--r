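## Internal helpers: condition classes, small numeric utilities.

# Condition classes map onto the CLI exit-code contract:
# input/schema problems (exit 2) vs configuration problems (exit 3).
gzError <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "grayzoneError", "error", "condition")))
}

gzSchemaError      <- function(fmt, ...) gzError("gzSchemaError", fmt, ...)
gzRangeError       <- function(fmt, ...) gzError("gzRangeError", fmt, ...)
gzDuplicationError <- function(fmt, ...) gzError("gzDuplicationError", fmt, ...)
gzValidityError    <- function(fmt, ...) gzError("gzValidityError", fmt, ...)
gzConfigError      <- function(fmt, ...) gzError("gzConfigError", fmt, ...)
gzDataError        <- function(fmt, ...) gzError("gzDataError", fmt, ...)
gzIOError          <- function(fmt, ...) gzError("gzIOError", fmt, ...)
gzDegeneracyError  <- function(fmt, ...) gzError("gzDegeneracyError", fmt, ...)
gzComparabilityError <- function(fmt, ...) gzError("gzComparabilityError", fmt, ...)

# reverse cumulative sum (risk-set sums over times sorted ascending)
revcumsum <- function(x) {
  if (!length(x)) return(x)
  rev(cumsum(rev(x)))
}

# column-wise reverse cumulative sums of a matrix
revcumsumMat <- function(m) {
  if (!nrow(m)) return(m)
  apply(m, 2L, revcumsum)
}

trimws2 <- function(x) trimws(x, which = "both")

# unbiasedness constant for the sample SD: E[s] = c4(n) * sigma
c4const <- function(n) {
  if (n < 2) return(NA_real_)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# serialize +/-Inf as the tokens used in the candidate table and report
infToken <- function(x) {
  out <- as.character(x)
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out[is.na(x)] <- "NA"
  out
}

# recursively replace non-finite numerics with tokens so the JSON report
# round-trips without loss
sanitizeForJSON <- function(x) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) {
      if (is.numeric(col) && any(!is.finite(col) & !is.na(col))) infToken(col) else col
    })
    return(x)
  }
  if (is.list(x)) {
    return(lapply(x, sanitizeForJSON))
  }
  if (is.numeric(x) && any(!is.finite(x) & !is.na(x))) return(infToken(x))
  x
}
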