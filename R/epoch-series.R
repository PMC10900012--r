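#' Construct an EpochSeries
#'
#' Builds a validated \linkS4class{EpochSeries} from per-epoch METs values.
#' Valid METs below the 1.0 device floor (seated rest) are clamped to 1.0
#' with a warning, mirroring the device's behaviour.
#'
#' @param subjectId subject identifier (single string).
#' @param mets numeric vector of METs per epoch.
#' @param start start time of the first epoch; \code{POSIXct} or a string
#'   parseable as \code{"YYYY-MM-DD HH:MM:SS"} (UTC).
#' @param epochSeconds epoch length in seconds (default 60).
#' @param valid logical vector marking worn/present epochs (default all
#'   \code{TRUE}; \code{NA} METs are always marked invalid).
#' @return an \linkS4class{EpochSeries}.
#' @examples
#' EpochSeries("s1", c(1.2, 1.4, 1.1), start = "2024-01-01 00:00:00")
#' @export
EpochSeries <- function(subjectId, mets, start = "2024-01-01 00:00:00",
                        epochSeconds = 60, valid = NULL) {
  start <- parseTimestamp(start)
  if (is.na(start)) stop("unparseable start timestamp")
  mets <- as.numeric(mets)
  if (is.null(valid)) valid <- rep(TRUE, length(mets))
  valid <- as.logical(valid) & !is.na(mets)
  low <- valid & mets < 1
  if (any(low)) {
    warning(sum(low), " METs value(s) below the 1.0 device floor clamped")
    mets[low] <- 1
  }
  new("EpochSeries", subjectId = as.character(subjectId), start = start,
      epochSeconds = as.numeric(epochSeconds), mets = mets, valid = valid)
}

parseTimestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' @rdname EpochSeries-class
#' @export
setMethod("subjectId", "EpochSeries", function(x) x@subjectId)

#' @rdname EpochSeries-class
#' @export
setMethod("mets", "EpochSeries", function(x) x@mets)

#' @rdname EpochSeries-class
#' @export
setMethod("validMask", "EpochSeries", function(x) x@valid)

#' @rdname EpochSeries-class
#' @export
setMethod("epochSeconds", "EpochSeries", function(x) x@epochSeconds)

#' @rdname EpochSeries-class
#' @export
setMethod("epochTimes", "EpochSeries", function(x) {
  x@start + (seq_along(x@mets) - 1) * x@epochSeconds
})

# hours since the subject's first midnight (midnight of the start date)
#' @rdname EpochSeries-class
#' @export
setMethod("timeHours", "EpochSeries", function(x) {
  midnight <- trunc(x@start, units = "days")
  offset <- as.numeric(difftime(x@start, midnight, units = "hours"))
  offset + (seq_along(x@mets) - 1) * x@epochSeconds / 3600
})

setMethod("show", "EpochSeries", function(object) {
  n <- length(object@mets)
  cat("EpochSeries for subject", object@subjectId, "\n")
  cat(sprintf("  %d epochs of %gs starting %s UTC (%.2f days)\n", n,
              object@epochSeconds, format(object@start, "%Y-%m-%d %H:%M"),
              n * object@epochSeconds / 86400))
  cat(sprintf("  valid: %.1f%%; METs range [%.2f, %.2f]\n",
              100 * mean(object@valid),
              suppressWarnings(min(object@mets[object@valid])),
              suppressWarnings(max(object@mets[object@valid]))))
})

#' Read epoch-level actigraphy from CSV
#'
#' Reads a long-format CSV with columns \code{subject_id}, \code{timestamp}
#' (ISO-8601, local clock), \code{mets} and optionally \code{valid} (0/1,
#' default 1) into one \linkS4class{EpochSeries} per subject. Gaps that are
#' whole multiples of the epoch length are filled with invalid epochs so
#' spacing stays constant; any other spacing is a format error.
#'
#' @param path CSV file path.
#' @param epochSeconds expected epoch length in seconds (default 60).
#' @return named list of \linkS4class{EpochSeries}, one per subject.
#' @seealso [writeEpochSeries()]
#' @export
readEpochSeries <- function(path, epochSeconds = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "mets")
  if (!all(need %in% names(df)))
    stop("epoch CSV must have columns: ", paste(need, collapse = ", "))
  ts <- suppressWarnings(parseTimestamp(df$timestamp))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("malformed timestamp at row ", bad, ": '", df$timestamp[bad], "'")
  }
  if (is.null(df$valid)) df$valid <- 1L
  out <- lapply(split(seq_len(nrow(df)), df$subject_id), function(idx) {
    idx <- idx[order(ts[idx])]
    t0 <- ts[idx]
    steps <- as.numeric(difftime(t0, t0[1], units = "secs")) / epochSeconds
    if (max(abs(steps - round(steps))) > 1e-6)
      stop("non-constant epoch spacing for subject ", df$subject_id[idx[1]],
           " that cannot be gap-filled at ", epochSeconds, "s")
    steps <- round(steps)
    if (anyDuplicated(steps))
      stop("duplicate timestamps for subject ", df$subject_id[idx[1]])
    n <- max(steps) + 1
    m <- rep(NA_real_, n)
    v <- rep(FALSE, n)
    m[steps + 1] <- df$mets[idx]
    v[steps + 1] <- df$valid[idx] > 0
    EpochSeries(df$subject_id[idx[1]], m, start = t0[1],
                epochSeconds = epochSeconds, valid = v)
  })
  out[order(names(out))]
}

#' Write epoch series to CSV
#'
#' Inverse of [readEpochSeries()]: writes a long-format epoch CSV. Invalid
#' gap epochs with no METs value are omitted (the reader re-inserts them).
#'
#' @param series an \linkS4class{EpochSeries} or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeEpochSeries <- function(series, path) {
  if (is(series, "EpochSeries")) series <- list(series)
  rows <- lapply(series, function(es) {
    keep <- !is.na(mets(es))
    data.frame(
      subject_id = subjectId(es),
      timestamp = format(epochTimes(es)[keep], "%Y-%m-%dT%H:%M:%S"),
      mets = mets(es)[keep],
      valid = as.integer(validMask(es)[keep])
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the subject metadata table
#'
#' One row per subject with covariates: \code{subject_id}, \code{age},
#' \code{sex} (male/female), \code{bmi}, \code{diagnosis}
#' (cerebrovascular/orthopedic), \code{mmse}, \code{motor_fim},
#' \code{hypnotics}, \code{psychotropics}, \code{locomotive_independent}
#' (logicals as 0/1). Inclusion-rule violations (age < 65 or MMSE < 24) are
#' reported as warnings, not rejections.
#'
#' @param path CSV path.
#' @return data.frame of subject covariates.
#' @export
readSubjectTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("subject table must have a subject_id column")
  for (col in c("hypnotics", "psychotropics", "locomotive_independent"))
    if (!is.null(df[[col]])) df[[col]] <- df[[col]] > 0
  if (!is.null(df$age) && any(df$age < 65))
    warning("subjects below the age-65 inclusion rule present")
  if (!is.null(df$mmse) && any(df$mmse < 24))
    warning("subjects below the MMSE >= 24 inclusion rule present")
  df
}

#' @rdname readSubjectTable
#' @param subjects data.frame as returned by [readSubjectTable()].
#' @export
writeSubjectTable <- function(subjects, path) {
  out <- subjects
  for (col in c("hypnotics", "psychotropics", "locomotive_independent"))
    if (!is.null(out[[col]])) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a series into day windows
#'
#' Splits a record into contiguous day windows at a configurable clock
#' boundary (default midnight). Windows covering a full day's worth of
#' epochs are flagged complete; partial first/last days are retained but
#' flagged.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param dayBoundary clock hour at which days begin (default 0 = midnight).
#' @return data.frame with one row per day window: \code{day_index},
#'   \code{start_hour}/\code{end_hour} (hours since first midnight),
#'   \code{n_epochs}, \code{complete}.
#' @export
splitDays <- function(series, dayBoundary = 0) {
  th <- timeHours(series)
  day <- floor((th - dayBoundary) / 24)
  perDay <- round(86400 / epochSeconds(series))
  tab <- table(day)
  idx <- as.integer(names(tab))
  data.frame(
    day_index = idx,
    start_hour = idx * 24 + dayBoundary,
    end_hour = (idx + 1) * 24 + dayBoundary,
    n_epochs = as.integer(tab),
    complete = as.integer(tab) == perDay
  )
}

#' Validate an epoch series
#'
#' Report-only quality checks: device-floor violations, invalid-epoch
#' fraction, and record span. The series passes when the valid fraction
#' meets the configured minimum.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param minValidFraction minimum tolerated fraction of valid epochs
#'   (default 0.8).
#' @return a list of class \code{seriesValidation} with elements
#'   \code{subjectId}, \code{issues} (character), \code{validFraction},
#'   \code{spanDays}, \code{floorViolations} and \code{pass}.
#' @export
validateSeries <- function(series, minValidFraction = 0.8) {
  v <- validMask(series)
  m <- mets(series)
  issues <- character()
  floorViolations <- sum(v & !is.na(m) & m < 1)
  if (floorViolations > 0)
    issues <- c(issues, sprintf("%d epoch(s) below the 1.0 METs floor",
                                floorViolations))
  validFraction <- mean(v)
  if (validFraction < minValidFraction)
    issues <- c(issues, sprintf("valid fraction %.2f below minimum %.2f",
                                validFraction, minValidFraction))
  spanDays <- length(m) * epochSeconds(series) / 86400
  if (spanDays < 1)
    issues <- c(issues, sprintf("record spans only %.2f days", spanDays))
  structure(list(subjectId = subjectId(series), issues = issues,
                 validFraction = validFraction, spanDays = spanDays,
                 floorViolations = floorViolations,
                 pass = validFraction >= minValidFraction),
            class = "seriesValidation")
}

#' @export
print.seriesValidation <- function(x, ...) {
  cat(sprintf("Series validation for %s: %s\n", x$subjectId,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  span %.2f days, %.1f%% valid\n", x$spanDays,
              100 * x$validFraction))
  if (length(x$issues)) cat(paste0("  - ", x$issues, collapse = "\n"), "\n")
  invisible(x)
}

# decimal clock hours -> "HH:MM"
#' Format decimal clock hours as HH:MM
#' @param h numeric vector of decimal hours.
#' @return character vector like \code{"11:48"}.
#' @examples hoursToHHMM(11.8)
#' @export
hoursToHHMM <- function(h) {
  h <- h %% 24
  mins <- round(h * 60)
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}
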