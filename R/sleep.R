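#' Convert METs to activity counts
#'
#' Bridges the device's METs output to the count-based Cole-Kripke rule:
#' \code{counts = max(0, mets - 1) * scale} per epoch. The scale is a
#' calibration parameter because count units are device-specific. Invalid
#' epochs become \code{NA}.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param scale positive counts-per-METs-excess factor (default 15).
#' @return numeric vector of per-epoch counts.
#' @examples
#' es <- EpochSeries("s1", c(1, 1.5, 2))
#' metsToCounts(es, scale = 200)
#' @export
metsToCounts <- function(series, scale = 15) {
  if (scale <= 0) stop("scale must be > 0")
  counts <- pmax(0, mets(series) - 1) * scale
  counts[!validMask(series)] <- NA_real_
  counts
}

# default published 1-min weighted-sum coefficients (lags -4..+2)
ckDefaultWeights <- function() c(106, 54, 58, 76, 230, 74, 67)

#' Cole-Kripke sleep/wake scoring
#'
#' Scores each 1-minute epoch as sleep or wake from activity counts with
#' the weighted moving sum
#' \deqn{D(t) = P \sum_{j=-4}^{+2} w_j \, c(t+j),}
#' sleep iff \eqn{D(t) < } threshold. Missing neighbours (record edges and
#' invalid epochs) contribute 0. The default weights, scale factor
#' \eqn{P = 0.001} and threshold 1 follow the published 1-minute rule.
#'
#' @param series an \linkS4class{EpochSeries} (1-min epochs unless
#'   \code{resample = TRUE}).
#' @param countsScale METs-to-counts calibration, see [metsToCounts()].
#' @param weights 7 coefficients for lags -4..+2.
#' @param scaleFactor multiplier P applied to the weighted sum.
#' @param threshold sleep iff D below this value.
#' @param resample if \code{TRUE}, series with epochs shorter than 60 s are
#'   mean-aggregated to 1-min epochs first; otherwise non-1-min input is a
#'   configuration error.
#' @return a \linkS4class{SleepWakeSeries}.
#' @examples
#' night <- EpochSeries("s1", rep(1.01, 600))
#' table(sleepStates(coleKripke(night)))
#' @export
coleKripke <- function(series, countsScale = 15, weights = ckDefaultWeights(),
                       scaleFactor = 0.001, threshold = 1, resample = FALSE) {
  if (length(weights) != 7) stop("weights must have length 7 (lags -4..+2)")
  if (epochSeconds(series) != 60) {
    if (!resample)
      stop("Cole-Kripke scoring needs 1-min epochs; set resample = TRUE ",
           "to aggregate")
    series <- .resampleTo60s(series)
  }
  counts <- metsToCounts(series, countsScale)
  c0 <- counts
  c0[is.na(c0)] <- 0
  n <- length(c0)
  D <- numeric(n)
  lags <- -4:2
  for (i in seq_along(lags)) {
    j <- lags[i]
    src <- seq_len(n) + j
    ok <- src >= 1 & src <= n
    D[ok] <- D[ok] + weights[i] * c0[src[ok]]
  }
  D <- scaleFactor * D
  states <- factor(ifelse(D < threshold, "sleep", "wake"),
                   levels = c("sleep", "wake", "unknown"))
  states[!validMask(series)] <- "unknown"
  new("SleepWakeSeries", states = states, series = series,
      params = list(countsScale = countsScale, weights = weights,
                    scaleFactor = scaleFactor, threshold = threshold))
}

.resampleTo60s <- function(series) {
  per <- round(60 / epochSeconds(series))
  if (abs(per * epochSeconds(series) - 60) > 1e-9)
    stop("epoch length does not divide 60 s; cannot resample")
  m <- mets(series)
  v <- validMask(series)
  grp <- (seq_along(m) - 1) %/% per
  mm <- as.numeric(tapply(ifelse(v, m, NA), grp, mean, na.rm = TRUE))
  vv <- as.logical(tapply(v, grp, any))
  mm[!vv | is.nan(mm)] <- NA
  EpochSeries(subjectId(series), mm, start = epochTimes(series)[1],
              epochSeconds = 60, valid = vv & !is.na(mm))
}

#' @rdname SleepWakeSeries-class
#' @export
setMethod("sleepStates", "SleepWakeSeries", function(x) x@states)

setMethod("show", "SleepWakeSeries", function(object) {
  tab <- table(object@states)
  cat("SleepWakeSeries for subject", subjectId(object@series), "\n")
  cat(sprintf("  %d epochs: %d sleep / %d wake / %d unknown\n",
              length(object@states), tab["sleep"], tab["wake"],
              tab["unknown"]))
})

#' Detect the main nocturnal sleep bout per night
#'
#' For each night, finds the longest run of sleep epochs, allowing internal
#' wake gaps up to a tolerance (default 10 min), whose onset clock time
#' falls inside the sleep-onset search window (default 18:00 to 12:00 the
#' next day). Bed time is the bout onset clock time and waking time the
#' bout offset clock time. Bouts truncated by the recording boundary are
#' flagged censored and excluded from averaging by [sleepSummary()].
#'
#' @param sw a \linkS4class{SleepWakeSeries}.
#' @param gapToleranceMin wake gaps up to this many minutes stay inside a
#'   bout (default 10).
#' @param onsetWindow numeric length-2 clock interval (hours) in which a
#'   main-sleep onset may fall; crosses midnight by default
#'   (\code{c(18, 12)}).
#' @param boundaryMarginMin bouts starting or ending within this many
#'   minutes of the recording edges are treated as truncated (censored).
#' @param minDurationMin bouts shorter than this are not plausible main
#'   sleep periods and are discarded (default 60).
#' @return data.frame with one row per detected bout: \code{night} (index
#'   of the evening day), \code{onset_hours}/\code{offset_hours} (hours
#'   since first midnight), \code{bed_time}/\code{waking_time} (clock
#'   hours; bed times after midnight are reported on the 24+ scale so
#'   23:30 and 00:30 average sensibly), \code{duration_min},
#'   \code{arousal_min}, \code{censored}.
#' @export
detectMainSleep <- function(sw, gapToleranceMin = 10, onsetWindow = c(18, 12),
                            boundaryMarginMin = 15, minDurationMin = 60) {
  series <- sw@series
  epochMin <- epochSeconds(series) / 60
  th <- timeHours(series)
  isSleep <- sw@states == "sleep"
  r <- rle(as.vector(isSleep))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sleepRuns <- which(r$values)
  if (!length(sleepRuns)) return(.emptyBouts())
  # merge sleep runs separated by wake/unknown gaps <= tolerance
  bouts <- list()
  cur <- c(starts[sleepRuns[1]], ends[sleepRuns[1]])
  for (k in sleepRuns[-1]) {
    gapMin <- (starts[k] - cur[2] - 1) * epochMin
    if (gapMin <= gapToleranceMin) {
      cur[2] <- ends[k]
    } else {
      bouts[[length(bouts) + 1]] <- cur
      cur <- c(starts[k], ends[k])
    }
  }
  bouts[[length(bouts) + 1]] <- cur
  n <- length(isSleep)
  rows <- lapply(bouts, function(b) {
    onset <- th[b[1]]
    offset <- th[b[2]] + epochMin / 60  # end of last sleep epoch
    clock <- onset %% 24
    inWindow <- if (onsetWindow[1] > onsetWindow[2])
      clock >= onsetWindow[1] | clock < onsetWindow[2]
    else clock >= onsetWindow[1] & clock < onsetWindow[2]
    if (!inWindow) return(NULL)
    night <- if (clock >= 12) floor(onset / 24) else floor(onset / 24) - 1
    inside <- seq(b[1], b[2])
    arousal <- sum(sw@states[inside] == "wake") * epochMin
    data.frame(
      night = night, onset_hours = onset, offset_hours = offset,
      bed_time = ifelse(clock < 12, clock + 24, clock),
      waking_time = offset %% 24,
      duration_min = (offset - onset) * 60,
      arousal_min = arousal,
      censored = (b[1] - 1) * epochMin <= boundaryMarginMin ||
        (n - b[2]) * epochMin <= boundaryMarginMin
    )
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(.emptyBouts())
  # a night is boundary-contaminated if any of its bouts is truncated
  nightCensored <- tapply(rows$censored, rows$night, any)
  rows <- rows[rows$duration_min >= minDurationMin, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no sleep bout of at least ", minDurationMin, " min found")
    return(.emptyBouts())
  }
  # keep the longest bout per night
  rows <- rows[order(rows$night, -rows$duration_min), ]
  rows <- rows[!duplicated(rows$night), ]
  rows$censored <- as.vector(nightCensored[as.character(rows$night)])
  rownames(rows) <- NULL
  rows
}

.emptyBouts <- function() {
  data.frame(night = integer(), onset_hours = numeric(),
             offset_hours = numeric(), bed_time = numeric(),
             waking_time = numeric(), duration_min = numeric(),
             arousal_min = numeric(), censored = logical())
}

#' Nightly sleep metrics, averaged across nights
#'
#' Per night, the nightly sleep period is the main bout duration; arousal
#' minutes are wake epochs inside the bout. Total sleep time is the sleep
#' period minus arousal minutes, and sleep efficiency is
#' \eqn{100 (S - \mathrm{arousal}) / S} with \eqn{S} the nightly sleep
#' period (equivalently \eqn{100\,\mathrm{TST}/S}). The four metrics are
#' averaged across uncensored nights.
#'
#' @param bouts data.frame from [detectMainSleep()].
#' @param dropCensored exclude boundary-truncated nights (default
#'   \code{TRUE}).
#' @return one-row data.frame: \code{total_sleep_time_min},
#'   \code{sleep_efficiency_pct}, \code{waking_time_h}, \code{bed_time_h},
#'   \code{n_nights}; per-night detail in attribute \code{"nights"}.
#' @export
sleepSummary <- function(bouts, dropCensored = TRUE) {
  if (dropCensored) bouts <- bouts[!bouts$censored, , drop = FALSE]
  bouts <- bouts[bouts$duration_min > 0, , drop = FALSE]
  if (nrow(bouts) == 0) {
    warning("no scoreable night found")
    out <- data.frame(total_sleep_time_min = NA_real_,
                      sleep_efficiency_pct = NA_real_,
                      waking_time_h = NA_real_, bed_time_h = NA_real_,
                      n_nights = 0L)
    attr(out, "nights") <- bouts
    return(out)
  }
  tst <- bouts$duration_min - bouts$arousal_min
  eff <- 100 * tst / bouts$duration_min
  out <- data.frame(
    total_sleep_time_min = mean(tst),
    sleep_efficiency_pct = mean(eff),
    waking_time_h = mean(bouts$waking_time),
    bed_time_h = mean(bouts$bed_time) %% 24,
    n_nights = nrow(bouts)
  )
  nights <- bouts
  nights$tst_min <- tst
  nights$efficiency_pct <- eff
  attr(out, "nights") <- nights
  out
}
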