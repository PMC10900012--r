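#' Classify METs values into SB / LIPA / MVPA
#'
#' Intensity categories: sedentary behaviour (SB) below 1.6 METs,
#' light-intensity physical activity (LIPA) from 1.6 to below 3.0 METs,
#' moderate-to-vigorous physical activity (MVPA) at 3.0 METs and above.
#' The half-open boundaries keep both printed bin edges (1.5 -> SB,
#' 1.6 -> LIPA, 3.0 -> MVPA) correctly classified while covering
#' continuous METs with no gap.
#'
#' @param mets numeric vector of METs values (>= 1.0; lower values are a
#'   device-floor violation and are clamped upstream).
#' @return factor with levels \code{SB}, \code{LIPA}, \code{MVPA}.
#' @examples
#' classifyMets(c(1.5, 1.6, 2.9, 3.0))
#' @export
classifyMets <- function(mets) {
  if (any(mets < 1, na.rm = TRUE))
    warning("METs below the 1.0 device floor passed to classifyMets")
  cut(mets, breaks = c(-Inf, 1.6, 3.0, Inf), right = FALSE,
      labels = c("SB", "LIPA", "MVPA"))
}

#' Daily activity-intensity totals
#'
#' For each complete day, minutes in each intensity category (epoch count
#' times epoch minutes). SB is counted around the clock, including after
#' lights-off; daytime SB additionally excludes the night window (default
#' 22:00 to 07:00, i.e. daytime 07:00-22:00). Invalid epochs contribute to
#' no category; days whose valid fraction falls below the minimum are
#' dropped from averaging. Results are means across qualifying days.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param days day windows from [splitDays()] (computed if omitted).
#' @param nightWindow clock interval \code{c(start, end)} excluded from
#'   daytime SB; crosses midnight (default \code{c(22, 7)}).
#' @param minValidFraction days below this valid fraction are dropped
#'   (default 0.8).
#' @return one-row data.frame: \code{sb_min_per_day},
#'   \code{daytime_sb_min_per_day}, \code{lipa_min_per_day},
#'   \code{mvpa_min_per_day}, \code{n_days}; per-day detail in attribute
#'   \code{"days"}.
#' @export
summarizeActivity <- function(series, days = splitDays(series),
                              nightWindow = c(22, 7),
                              minValidFraction = 0.8) {
  days <- days[days$complete, , drop = FALSE]
  if (nrow(days) == 0) stop("no complete day in record")
  epochMin <- epochSeconds(series) / 60
  th <- timeHours(series)
  clock <- th %% 24
  ok <- validMask(series) & !is.na(mets(series))
  cls <- classifyMets(mets(series))
  isNight <- if (nightWindow[1] > nightWindow[2])
    clock >= nightWindow[1] | clock < nightWindow[2]
  else clock >= nightWindow[1] & clock < nightWindow[2]
  perDay <- lapply(seq_len(nrow(days)), function(i) {
    inDay <- th >= days$start_hour[i] & th < days$end_hour[i]
    validFrac <- mean(ok[inDay])
    use <- inDay & ok
    data.frame(
      day_index = days$day_index[i],
      valid_fraction = validFrac,
      sb_min = sum(cls[use] == "SB") * epochMin,
      daytime_sb_min = sum(cls[use] == "SB" & !isNight[use]) * epochMin,
      lipa_min = sum(cls[use] == "LIPA") * epochMin,
      mvpa_min = sum(cls[use] == "MVPA") * epochMin
    )
  })
  perDay <- do.call(rbind, perDay)
  keep <- perDay$valid_fraction >= minValidFraction
  if (!any(keep)) stop("no complete day with sufficient valid coverage")
  usedDays <- perDay[keep, , drop = FALSE]
  out <- data.frame(
    sb_min_per_day = mean(usedDays$sb_min),
    daytime_sb_min_per_day = mean(usedDays$daytime_sb_min),
    lipa_min_per_day = mean(usedDays$lipa_min),
    mvpa_min_per_day = mean(usedDays$mvpa_min),
    n_days = nrow(usedDays)
  )
  attr(out, "days") <- perDay
  out
}
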