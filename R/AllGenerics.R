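#' @rdname EpochSeries-class
#' @param x,object an object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EpochSeries-class
#' @export
setGeneric("mets", function(x) standardGeneric("mets"))

#' @rdname EpochSeries-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochSeconds", function(x) standardGeneric("epochSeconds"))

#' @rdname EpochSeries-class
#' @export
setGeneric("timeHours", function(x) standardGeneric("timeHours"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Evaluate a fitted periodic regression curve
#'
#' Returns \eqn{M + \sum_k A_k \cos(\omega_k t - \theta_k)} for times
#' \code{t} given in hours; vectorized over \code{t}.
#'
#' @param fit a \linkS4class{HarmonicFit}.
#' @param t numeric vector of times in hours (any origin; the basis is
#'   periodic).
#' @return numeric vector of curve values (METs).
#' @examples
#' fit <- new("HarmonicFit", mesor = 1.2, periods = c(24, 12),
#'            amplitudes = c(0.15, 0.05), acrophases = c(pi, 0),
#'            rsquared = 1, nUsed = 0L)
#' evaluateCurve(fit, c(3, 12))
#' @export
setGeneric("evaluateCurve", function(fit, t) standardGeneric("evaluateCurve"))

#' @rdname extractCAR
#' @export
setGeneric("extractCAR", function(fit, ...) standardGeneric("extractCAR"))

#' @rdname SleepWakeSeries-class
#' @export
setGeneric("sleepStates", function(x) standardGeneric("sleepStates"))

#' @rdname ActigraphyCohort-class
#' @export
setGeneric("cohortSeries", function(x) standardGeneric("cohortSeries"))

#' @rdname ActigraphyCohort-class
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @rdname ActigraphyCohort-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
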