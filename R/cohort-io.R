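## Reading/writing the pyrosequencing run table, the clinical table and the
## candidate results table. Both CSV and TSV dialects are accepted; the
## delimiter is auto-detected from the header line unless overridden.

detectDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) gzSchemaError("file '%s' is empty", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))) "\t" else ","
}

readDelimRaw <- function(path, delim = NULL) {
  if (!file.exists(path)) gzIOError("file '%s' does not exist", path)
  if (is.null(delim)) delim <- detectDelim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          strip.white = TRUE)
  names(df) <- trimws2(names(df))
  df
}

# empty cell or "NA" (case-insensitive) is the only missingness encoding
parseNumericCol <- function(x, col, lo, hi, what) {
  x <- trimws2(x)
  miss <- x == "" | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out))
  if (length(bad))
    gzSchemaError("column '%s': non-numeric value '%s' in data row %d",
                  col, x[bad[1]], bad[1])
  out[miss] <- NA_real_
  oob <- which(!is.na(out) & (out < lo | out > hi))
  if (length(oob))
    gzRangeError("column '%s': %s %g outside [%g, %g] in data row %d",
                 col, what, out[oob[1]], lo, hi, oob[1])
  out
}

#' Read a pyrosequencing run table
#'
#' Parses a delimited table with one row per sequencing run per sample.
#' Required columns: \code{sample_id}, \code{run_id}, and one
#' \code{cpg_<site>} column per panel site, holding percentage methylation
#' on the 0-100 scale. Empty cells or "NA" (case-insensitive) denote a
#' failed measurement at that site. Extra columns are ignored.
#'
#' @param path Path to a CSV or TSV file.
#' @param siteIds Integer vector of CpG site numbers expected in the panel
#'   (e.g. \code{72:83}).
#' @param delim Field delimiter; default NULL auto-detects comma vs tab from
#'   the header line.
#' @return data.frame with columns sample_id, run_id and the \code{cpg_*}
#'   columns in panel order; attribute \code{siteIds} records the panel.
#' @export
readPyroRuns <- function(path, siteIds, delim = NULL) {
  siteIds <- as.integer(siteIds)
  if (!length(siteIds) || anyNA(siteIds))
    gzConfigError("siteIds must be a non-empty integer vector")
  df <- readDelimRaw(path, delim)
  cpgCols <- paste0("cpg_", siteIds)
  need <- c("sample_id", "run_id", cpgCols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    gzSchemaError("pyro table is missing required column(s): %s",
                  paste(miss, collapse = ", "))
  out <- data.frame(sample_id = trimws2(df$sample_id),
                    run_id = trimws2(df$run_id),
                    stringsAsFactors = FALSE)
  for (cc in cpgCols)
    out[[cc]] <- parseNumericCol(df[[cc]], cc, 0, 100, "methylation value")
  dup <- duplicated(out[, c("sample_id", "run_id")])
  if (any(dup))
    gzDuplicationError("duplicate (sample_id, run_id) pair ('%s', '%s') in data row %d",
                       out$sample_id[which(dup)[1]], out$run_id[which(dup)[1]],
                       which(dup)[1])
  attr(out, "siteIds") <- siteIds
  out
}

#' Read a clinical table
#'
#' Required columns: \code{sample_id}, \code{age_years}, \code{sex},
#' \code{os_months}, \code{event}. Sex values are case- and
#' whitespace-normalised; "male"/"m" and "female"/"f" map to their level,
#' everything else to "unknown". The event indicator accepts 0/1,
#' true/false, and dead/alive (case-insensitive).
#'
#' @inheritParams readPyroRuns
#' @return data.frame with columns sample_id, age_years (numeric), sex
#'   (character: male/female/unknown), os_months (numeric, > 0), event
#'   (logical, TRUE = death observed).
#' @export
readClinical <- function(path, delim = NULL) {
  df <- readDelimRaw(path, delim)
  need <- c("sample_id", "age_years", "sex", "os_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gzSchemaError("clinical table is missing required column(s): %s",
                  paste(miss, collapse = ", "))
  sid <- trimws2(df$sample_id)
  dup <- which(duplicated(sid))
  if (length(dup))
    gzDuplicationError("duplicate sample_id '%s' in data row %d", sid[dup[1]], dup[1])
  age <- parseNumericCol(df$age_years, "age_years", 0, Inf, "age")
  os <- parseNumericCol(df$os_months, "os_months", -Inf, Inf, "os_months")
  bad <- which(is.na(os) | os <= 0)
  if (length(bad))
    gzValidityError("os_months must be a positive number (data row %d)", bad[1])
  sexRaw <- tolower(trimws2(df$sex))
  sex <- ifelse(sexRaw %in% c("male", "m"), "male",
         ifelse(sexRaw %in% c("female", "f"), "female", "unknown"))
  evRaw <- tolower(trimws2(df$event))
  event <- rep(NA, length(evRaw))
  event[evRaw %in% c("1", "true", "dead")] <- TRUE
  event[evRaw %in% c("0", "false", "alive")] <- FALSE
  bad <- which(is.na(event))
  if (length(bad))
    gzValidityError("event value '%s' not in {0,1,true,false,dead,alive} (data row %d)",
                    evRaw[bad[1]], bad[1])
  data.frame(sample_id = sid, age_years = age, sex = sex,
             os_months = os, event = event, stringsAsFactors = FALSE)
}

#' Read a full cohort
#'
#' Convenience wrapper producing a \linkS4class{PyroCohort} from the two
#' input tables.
#'
#' @inheritParams readPyroRuns
#' @param pyroPath,clinicalPath Paths to the run and clinical tables.
#' @return A \linkS4class{PyroCohort}.
#' @export
readCohort <- function(pyroPath, clinicalPath, siteIds, delim = NULL) {
  PyroCohort(readPyroRuns(pyroPath, siteIds, delim),
             readClinical(clinicalPath, delim),
             siteIds)
}

#' Write a pyrosequencing run table
#'
#' Inverse of \code{\link{readPyroRuns}}: missing values become empty cells,
#' so a write/read round trip preserves values and missingness.
#'
#' @param runs data.frame as returned by \code{\link{readPyroRuns}}.
#' @param path Output path.
#' @param delim Field delimiter ("," or "\\t"); default chosen from the file
#'   extension (.tsv gets a tab).
#' @export
writePyroRuns <- function(runs, path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  ok <- tryCatch({
    utils::write.table(runs, path, sep = delim, row.names = FALSE,
                       quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gzIOError("cannot write pyro table to '%s'", path)
  invisible(path)
}

#' Write a clinical table
#' @inheritParams writePyroRuns
#' @param clinical data.frame as returned by \code{\link{readClinical}}.
#' @export
writeClinical <- function(clinical, path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- clinical
  out$event <- as.integer(out$event)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, row.names = FALSE,
                       quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gzIOError("cannot write clinical table to '%s'", path)
  invisible(path)
}

#' Write the candidate results table
#'
#' Serialises the per-candidate sweep (one row per gray-zone candidate plus
#' the binary no-gray-zone row) as a tab-separated table. Unbounded median
#' confidence limits are written as the tokens \code{-inf} / \code{inf}.
#'
#' @param results A \linkS4class{GrayZoneDecision} or the data.frame from
#'   \code{\link{candidateTable}}.
#' @param path Output path.
#' @export
writeCandidateTable <- function(results, path) {
  tab <- if (is(results, "GrayZoneDecision")) candidateTable(results) else results
  if (!is.data.frame(tab) || !nrow(tab))
    gzValidityError("candidate results must be non-empty")
  out <- tab
  out[] <- lapply(out, function(col) if (is.numeric(col)) infToken(col) else col)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gzIOError("cannot write candidate table to '%s'", path)
  invisible(path)
}
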