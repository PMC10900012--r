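#' @import methods
NULL

setOldClass("POSIXct")

#' EpochSeries: a subject's epoch-level METs record
#'
#' Container for one subject's wrist-actigraphy recording at a fixed epoch
#' length (default 60 s). Activity is stored as METs per epoch; 1 MET is the
#' device floor (seated rest), so every valid epoch carries a value >= 1.
#' Time is handled internally as real-valued hours since the subject's first
#' midnight; clock time of day is \code{t mod 24}.
#'
#' @slot subjectId character scalar identifying the subject.
#' @slot start \code{POSIXct} start of the first epoch (UTC).
#' @slot epochSeconds epoch length in seconds.
#' @slot mets numeric vector of METs per epoch (\code{NA} where invalid).
#' @slot valid logical vector; \code{FALSE} marks off-wrist/missing epochs.
#'
#' @examples
#' es <- EpochSeries("s1", rep(1.2, 120), start = "2024-01-01 08:00:00")
#' es
#' head(timeHours(es))
#' @export
setClass("EpochSeries",
  representation(
    subjectId = "character",
    start = "POSIXct",
    epochSeconds = "numeric",
    mets = "numeric",
    valid = "logical"
  )
)

setValidity("EpochSeries", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-NA string")
  if (length(object@epochSeconds) != 1L || object@epochSeconds <= 0)
    msg <- c(msg, "epochSeconds must be a single positive number")
  if (length(object@mets) != length(object@valid))
    msg <- c(msg, "mets and valid must have the same length")
  ok <- object@valid & !is.na(object@mets)
  if (any(object@mets[ok] < 1))
    msg <- c(msg, "valid METs values must be >= 1.0 (device floor)")
  span <- length(object@mets) * object@epochSeconds / 86400
  if (span > 7 + 1e-9)
    msg <- c(msg, "record spans more than 7 days")
  if (length(msg)) msg else TRUE
})

#' HarmonicFit: a fitted multi-component periodic regression
#'
#' Result of fitting \eqn{y(t) = M + \sum_k A_k \cos(\omega_k t - \theta_k)}
#' by closed-form least squares. For the standard rhythm model the
#' components are the 24-h and 12-h cycles.
#'
#' @slot mesor rhythm-adjusted mean M (METs).
#' @slot periods component periods (hours).
#' @slot amplitudes component amplitudes \eqn{A_k \ge 0} (METs).
#' @slot acrophases component acrophases \eqn{\theta_k \in [0, 2\pi)}.
#' @slot rsquared coefficient of determination of the fit.
#' @slot nUsed number of valid epochs entering the fit.
#' @export
setClass("HarmonicFit",
  representation(
    mesor = "numeric",
    periods = "numeric",
    amplitudes = "numeric",
    acrophases = "numeric",
    rsquared = "numeric",
    nUsed = "integer"
  )
)

setValidity("HarmonicFit", function(object) {
  msg <- character()
  k <- length(object@periods)
  if (length(object@amplitudes) != k || length(object@acrophases) != k)
    msg <- c(msg, "periods, amplitudes and acrophases must align")
  if (any(object@periods <= 0)) msg <- c(msg, "periods must be > 0")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@acrophases < 0 | object@acrophases >= 2 * pi))
    msg <- c(msg, "acrophases must lie in [0, 2*pi)")
  if (object@rsquared < -1e-12 || object@rsquared > 1 + 1e-12)
    msg <- c(msg, "rsquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CARParameters: the six circadian activity rhythm descriptors
#'
#' Derived from the fitted composite curve over one clock day: mesor,
#' maximum, minimum, range (maximum - minimum), and the clock times of the
#' daily maximum and minimum.
#'
#' @slot mesor,maximum,minimum,range METs.
#' @slot maxPhase,minPhase clock time in decimal hours, in [0, 24).
#' @slot rsquared copied from the source fit.
#' @export
setClass("CARParameters",
  representation(
    mesor = "numeric",
    maximum = "numeric",
    minimum = "numeric",
    range = "numeric",
    maxPhase = "numeric",
    minPhase = "numeric",
    rsquared = "numeric"
  )
)

setValidity("CARParameters", function(object) {
  msg <- character()
  tol <- 1e-9
  if (object@minimum > object@mesor + tol || object@mesor > object@maximum + tol)
    msg <- c(msg, "must satisfy minimum <= mesor <= maximum")
  if (abs(object@range - (object@maximum - object@minimum)) > tol)
    msg <- c(msg, "range must equal maximum - minimum")
  if (object@maxPhase < 0 || object@maxPhase >= 24 ||
      object@minPhase < 0 || object@minPhase >= 24)
    msg <- c(msg, "phase times must lie in [0, 24)")
  if (object@range > tol && object@maxPhase == object@minPhase)
    msg <- c(msg, "max and min phase must differ when range > 0")
  if (length(msg)) msg else TRUE
})

#' SleepWakeSeries: per-epoch sleep/wake states
#'
#' Epoch-aligned sleep/wake classification produced by the Cole-Kripke
#' weighted-sum rule. Invalid source epochs carry state \code{"unknown"}.
#'
#' @slot states factor with levels \code{sleep}, \code{wake},
#'   \code{unknown}, aligned to the scored \linkS4class{EpochSeries}.
#' @slot series the source \linkS4class{EpochSeries}.
#' @slot params list with the scoring parameters used (weights, scale
#'   factor, threshold, counts scale).
#' @export
setClass("SleepWakeSeries",
  representation(
    states = "factor",
    series = "EpochSeries",
    params = "list"
  )
)

setValidity("SleepWakeSeries", function(object) {
  msg <- character()
  if (!identical(levels(object@states), c("sleep", "wake", "unknown")))
    msg <- c(msg, "states must have levels sleep/wake/unknown")
  if (length(object@states) != length(mets(object@series)))
    msg <- c(msg, "states must align with the source series")
  if (length(msg)) msg else TRUE
})

#' ActigraphyCohort: a set of subjects with recordings and metadata
#'
#' Bundles one \linkS4class{EpochSeries} per subject with a subject
#' metadata table (one row per subject) and, for simulated cohorts, the
#' generator ground truth.
#'
#' @slot series named list of \linkS4class{EpochSeries}.
#' @slot subjects data.frame of subject covariates, one row per subject.
#' @slot groundTruth list of per-subject latent parameters (may be empty
#'   for cohorts read from files).
#' @export
setClass("ActigraphyCohort",
  representation(
    series = "list",
    subjects = "data.frame",
    groundTruth = "list"
  )
)

setValidity("ActigraphyCohort", function(object) {
  msg <- character()
  ids <- vapply(object@series, subjectId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate subject ids in series")
  if (!all(vapply(object@series, is, logical(1), "EpochSeries")))
    msg <- c(msg, "series must be a list of EpochSeries")
  if (nrow(object@subjects) > 0) {
    if (!"subject_id" %in% names(object@subjects))
      msg <- c(msg, "subjects table must have a subject_id column")
    else if (!setequal(object@subjects$subject_id, ids))
      msg <- c(msg, "subjects table and series must cover the same subjects")
  }
  if (length(msg)) msg else TRUE
})
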