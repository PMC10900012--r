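#' Fit a multi-component periodic regression
#'
#' Fits \eqn{y(t) = M + \sum_k [a_k \cos(\omega_k t) + b_k \sin(\omega_k t)]}
#' over the valid epochs by closed-form least squares (no iterative
#' optimiser) and re-expresses each component as amplitude
#' \eqn{A_k = \sqrt{a_k^2 + b_k^2}} and acrophase
#' \eqn{\theta_k = \mathrm{atan2}(b_k, a_k)} normalised to \eqn{[0, 2\pi)}.
#' The default components are the 24-h and 12-h cycles of the composite
#' rhythm model. The fit uses the full multi-day record; the cosine basis
#' is periodic, so multi-day data need no folding. Alternatively the record
#' can first be collapsed to an average clock-day profile.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param periods component periods in hours (default \code{c(24, 12)});
#'   must be distinct and positive.
#' @param averagedDay if \code{TRUE}, fit the mean METs profile by clock
#'   epoch instead of the full record.
#' @return a \linkS4class{HarmonicFit}.
#' @examples
#' t <- seq(0, 24, by = 1/60)[-1441]
#' y <- 1.2 + 0.2 * cos(2 * pi / 24 * t - pi)
#' es <- EpochSeries("s1", y)
#' fitHarmonics(es)
#' @export
fitHarmonics <- function(series, periods = c(24, 12), averagedDay = FALSE) {
  if (any(periods <= 0) || anyDuplicated(periods))
    stop("periods must be distinct and > 0")
  keep <- validMask(series) & !is.na(mets(series))
  t <- timeHours(series)[keep]
  y <- mets(series)[keep]
  if (averagedDay) {
    clockEpoch <- round((t %% 24) * 3600 / epochSeconds(series))
    y <- as.numeric(tapply(y, clockEpoch, mean))
    t <- as.numeric(names(tapply(t %% 24, clockEpoch, min)))
    t <- sort(unique(clockEpoch)) * epochSeconds(series) / 3600
  }
  .fitHarmonicsCore(t, y, periods)
}

.fitHarmonicsCore <- function(t, y, periods) {
  k <- length(periods)
  if (length(y) < 2 * k + 1)
    stop("need at least ", 2 * k + 1, " valid epochs to fit ", k,
         " component(s)")
  omega <- 2 * pi / periods
  X <- matrix(1, length(t), 2 * k + 1)
  for (i in seq_len(k)) {
    X[, 2 * i] <- cos(omega[i] * t)
    X[, 2 * i + 1] <- sin(omega[i] * t)
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    stop("degenerate input: constant series, R-squared undefined")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: too few distinct sampling times for the ",
         "requested periods")
  beta <- qr.coef(qrX, y)
  resid <- y - X %*% beta
  a <- beta[2 * seq_len(k)]
  b <- beta[2 * seq_len(k) + 1]
  amp <- sqrt(a^2 + b^2)
  theta <- atan2(b, a) %% (2 * pi)
  new("HarmonicFit", mesor = unname(beta[1]), periods = as.numeric(periods),
      amplitudes = unname(amp), acrophases = unname(theta),
      rsquared = max(0, min(1, 1 - sum(resid^2) / sst)),
      nUsed = length(y))
}

setMethod("show", "HarmonicFit", function(object) {
  cat("HarmonicFit:", length(object@periods), "component(s),",
      object@nUsed, "epochs\n")
  cat(sprintf("  mesor M = %.4f METs, R^2 = %.3f\n", object@mesor,
              object@rsquared))
  for (i in seq_along(object@periods))
    cat(sprintf("  T = %g h: A = %.4f METs, theta = %.4f rad (peak %s)\n",
                object@periods[i], object@amplitudes[i], object@acrophases[i],
                hoursToHHMM(object@acrophases[i] / (2 * pi / object@periods[i]))))
})

#' @rdname evaluateCurve
#' @export
setMethod("evaluateCurve", "HarmonicFit", function(fit, t) {
  y <- rep(fit@mesor, length(t))
  for (i in seq_along(fit@periods)) {
    omega <- 2 * pi / fit@periods[i]
    y <- y + fit@amplitudes[i] * cos(omega * t - fit@acrophases[i])
  }
  y
})

# derivative of the composite curve, for extremum refinement
.curveDeriv <- function(fit, t) {
  d <- numeric(length(t))
  for (i in seq_along(fit@periods)) {
    omega <- 2 * pi / fit@periods[i]
    d <- d - fit@amplitudes[i] * omega * sin(omega * t - fit@acrophases[i])
  }
  d
}

#' Extract the six CAR parameters from a fitted curve
#'
#' Evaluates the composite regression curve on a clock-day grid (default
#' 60-s resolution) over [0, 24), locates every local extremum, and refines
#' each by root-finding on the analytic derivative, so extrema are exact to
#' numerical precision. Ties are broken by earliest clock time. The six
#' parameters are mesor, maximum, minimum, range = maximum - minimum, and
#' the clock times of the maximum and minimum.
#'
#' @param fit a \linkS4class{HarmonicFit}.
#' @param gridSeconds coarse search resolution in seconds (default 60).
#' @param ... unused.
#' @return a \linkS4class{CARParameters}.
#' @examples
#' fit <- new("HarmonicFit", mesor = 1.2, periods = c(24, 12),
#'            amplitudes = c(0.15, 0.05), acrophases = c(pi, 0),
#'            rsquared = 1, nUsed = 0L)
#' extractCAR(fit)
#' @export
setMethod("extractCAR", "HarmonicFit", function(fit, gridSeconds = 60, ...) {
  step <- gridSeconds / 3600
  grid <- seq(0, 24 - step / 2, by = step)
  y <- evaluateCurve(fit, grid)
  if (max(y) - min(y) < 1e-15) {
    # flat curve: degenerate but legal (all amplitudes 0)
    return(new("CARParameters", mesor = fit@mesor, maximum = fit@mesor,
               minimum = fit@mesor, range = 0, maxPhase = 0, minPhase = 0,
               rsquared = fit@rsquared))
  }
  n <- length(y)
  lag <- c(n, seq_len(n - 1))
  lead <- c(seq(2, n), 1)
  refine <- function(sign) {
    cand <- which(sign * y >= sign * y[lag] & sign * y >= sign * y[lead])
    best <- c(t = Inf, v = -Inf)
    for (i in cand) {
      lo <- grid[i] - step
      hi <- grid[i] + step
      f <- function(t) sign * .curveDeriv(fit, t)
      ti <- grid[i]
      if (f(lo) > 0 && f(hi) < 0) {
        ti <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
      }
      vi <- sign * evaluateCurve(fit, ti)
      ti <- ti %% 24
      if (ti >= 24) ti <- 0  # guard against floating-point wrap
      if (vi > best["v"] + 1e-13 ||
          (abs(vi - best["v"]) <= 1e-13 && ti < best["t"])) {
        best <- c(t = ti, v = vi)
      }
    }
    best
  }
  mx <- refine(1)
  mn <- refine(-1)
  maximum <- mx[["v"]]
  minimum <- -mn[["v"]]
  new("CARParameters", mesor = fit@mesor, maximum = maximum,
      minimum = minimum, range = maximum - minimum,
      maxPhase = mx[["t"]], minPhase = mn[["t"]],
      rsquared = fit@rsquared)
})

setMethod("show", "CARParameters", function(object) {
  cat("CAR parameters:\n")
  cat(sprintf("  mesor   %.4f METs\n", object@mesor))
  cat(sprintf("  maximum %.4f METs at %s (%.3f h)\n", object@maximum,
              hoursToHHMM(object@maxPhase), object@maxPhase))
  cat(sprintf("  minimum %.4f METs at %s (%.3f h)\n", object@minimum,
              hoursToHHMM(object@minPhase), object@minPhase))
  cat(sprintf("  range   %.4f METs; R^2 = %.3f\n", object@range,
              object@rsquared))
})

#' Coerce CARParameters to a one-row data.frame
#' @param car a \linkS4class{CARParameters}.
#' @param fit optionally the source \linkS4class{HarmonicFit}, to append
#'   per-component amplitudes/acrophases.
#' @return one-row data.frame in reporting units (METs, decimal hours plus
#'   HH:MM renderings).
#' @export
carAsRow <- function(car, fit = NULL) {
  row <- data.frame(
    mesor = car@mesor, maximum = car@maximum, minimum = car@minimum,
    range = car@range, max_phase_time = car@maxPhase,
    max_phase_hhmm = hoursToHHMM(car@maxPhase),
    min_phase_time = car@minPhase,
    min_phase_hhmm = hoursToHHMM(car@minPhase),
    r_squared = car@rsquared
  )
  if (!is.null(fit)) {
    for (i in seq_along(fit@periods)) {
      row[[paste0("A", i)]] <- fit@amplitudes[i]
      row[[paste0("theta", i)]] <- fit@acrophases[i]
    }
  }
  row
}

#' Scan candidate periods by R-squared
#'
#' Fits a single-component periodic regression for each candidate period
#' \eqn{T_n = 24/n} hours, \eqn{n = 1 \dots nComponents}, and ranks the
#' candidates by R-squared (descending). Used to confirm that the 24-h and
#' 12-h cycles fit the activity data best. Candidates shorter than two
#' epochs are skipped with a warning; per-candidate fit failures are
#' recorded, not fatal.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param nComponents number of candidate cycles (default 720, i.e. periods
#'   down to 2 minutes for 60-s epochs).
#' @return data.frame of class \code{periodScan} with columns \code{n},
#'   \code{period} (hours), \code{r_squared}, \code{note}; rows sorted by
#'   descending R-squared.
#' @export
scanPeriods <- function(series, nComponents = 720) {
  keep <- validMask(series) & !is.na(mets(series))
  t <- timeHours(series)[keep]
  y <- mets(series)[keep]
  minPeriod <- 2 * epochSeconds(series) / 3600
  n <- seq_len(nComponents)
  periods <- 24 / n
  skip <- periods < minPeriod
  if (any(skip))
    warning(sum(skip), " candidate period(s) shorter than two epochs skipped")
  r2 <- rep(NA_real_, nComponents)
  note <- character(nComponents)
  note[skip] <- "sub-epoch period skipped"
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("degenerate input: constant series, R-squared undefined")
  yc <- y - mean(y)
  for (i in which(!skip)) {
    fitTry <- tryCatch({
      omega <- 2 * pi / periods[i]
      cc <- cos(omega * t); ss <- sin(omega * t)
      X <- cbind(1, cc, ss)
      beta <- qr.coef(qr(X), y)
      if (anyNA(beta)) stop("rank-deficient design")
      resid <- y - X %*% beta
      1 - sum(resid^2) / sst
    }, error = function(e) conditionMessage(e))
    if (is.numeric(fitTry)) r2[i] <- fitTry else note[i] <- fitTry
  }
  out <- data.frame(n = n, period = periods, r_squared = r2, note = note,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r_squared, out$n, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("periodScan", "data.frame")
  out
}

#' Plot a subject's record with the fitted composite curve
#'
#' Raw epoch METs (thinned for legibility) overlaid with the fitted
#' 24-h + 12-h regression curve, in the style used to display individual
#' inpatient rhythms.
#'
#' @param series an \linkS4class{EpochSeries}.
#' @param fit a \linkS4class{HarmonicFit} for the same subject.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{NULL}.
#' @export
plotCARFit <- function(series, fit, ...) {
  keep <- validMask(series)
  t <- timeHours(series)[keep]
  y <- mets(series)[keep]
  graphics::plot(t, y, pch = ".", col = "grey50", xlab = "hours since first midnight",
                 ylab = "METs", main = paste("Subject", subjectId(series)), ...)
  tt <- seq(min(t), max(t), by = 0.05)
  graphics::lines(tt, evaluateCurve(fit, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = fit@mesor, lty = 2, col = "firebrick")
  invisible(NULL)
}
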