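#' Generator configuration for synthetic inpatient cohorts
#'
#' Returns the default configuration of the synthetic-cohort generator,
#' which emulates 5 weekday wrist-actigraphy recordings of elderly
#' rehabilitation inpatients following a fixed ward schedule (lights on
#' 07:00, meals 07:00/12:00/18:00, one morning and two afternoon
#' rehabilitation sessions of 40-60 min, lights out 22:00). Each subject
#' carries a latent two-harmonic (24-h + 12-h) activity rhythm scaled by a
#' subject-level activity factor, scheduled activity bouts, scripted
#' nocturnal sleep with arousals, and positive-skewed multiplicative noise
#' (log-normal on the above-floor METs component, so the 1.0 METs floor is
#' respected without truncation artifacts). Defaults are calibrated so the
#' default cohort reproduces the published inpatient cohort summaries
#' (mesor about 1.23 METs, nightly sleep about 458 min at about 90%
#' efficiency, predominantly sedentary days, and hypnotics users peaking
#' about 2.5 h later).
#'
#' @param seed master seed; per-subject seeds are \code{seed + subject
#'   index}, so cohorts are extensible without perturbing earlier subjects.
#' @param nSubjects,nDays,epochSeconds cohort shape (default 34 subjects,
#'   5 whole days of 60-s epochs starting at a Monday midnight).
#' @param startDate first record day (a Monday; weekends are never
#'   generated).
#' @param ... named overrides for any nested element, e.g.
#'   \code{rhythm = list(c1 = 0.2)}, \code{noise = list(sdLog = 0)}.
#' @return list of class \code{carGeneratorConfig}.
#' @examples
#' cfg <- generatorConfig(seed = 1, nSubjects = 2)
#' cohort <- generateCohort(cfg)
#' cohort
#' @export
generatorConfig <- function(seed = 1234, nSubjects = 34, nDays = 5,
                            epochSeconds = 60, startDate = "2024-01-01",
                            ...) {
  cfg <- list(
    seed = as.integer(seed), nSubjects = nSubjects, nDays = nDays,
    epochSeconds = epochSeconds, startDate = startDate,
    # latent rhythm: excess METs E(t) = c0 + c1 cos(w1(t - p1 - delta))
    #                + c2 cos(w2(t - p2 - delta)); subject scale g
    rhythm = list(c0 = 0.20, c1 = 0.105, c2 = 0.09,
                  p1 = 11.8, p2 = 12.0, phaseMean = 0.3, phaseSd = 1.2,
                  amp2SdLog = 0.12, phase2JitterSd = 0.7),
    activity = list(gMean = 1.07, gSdLog = 0.33, gRange = c(0.5, 1.36)),
    noise = list(sdLog = 0.05),
    sleep = list(script = TRUE, bedMean = 21.84, wakeMean = 6.21,
                 subjectSd = 0.55, nightlySd = 0.25,
                 bedRange = c(20.5, 23.4), wakeRange = c(5.0, 7.8),
                 sleepExcess = 0.085, arousalsPerNight = 6,
                 arousalDurRange = c(1, 4), arousalExcess = c(0.18, 0.28),
                 windDownH = 3.0, windUpH = 1.5, windLevel = 0.13,
                 wakeFloor = 0.12),
    schedule = list(mealTimes = c(7, 12, 18), mealDurMin = 30,
                    mealPeak = 0.12, mealJitter = c(0.7, 1.3),
                    rehabWindows = list(c(9, 12), c(13, 15), c(15, 17)),
                    rehabDurMin = c(40, 60),
                    rehabPassive = 0.12,
                    rehabActiveSlope = 0.22, rehabActiveG0 = 0,
                    rehabActiveMax = 0.8, rehabActiveExcess = c(0.62, 0.72),
                    spikeRatePerDay = 2.0, spikeRateSdLog = 0.3,
                    spikeDurMin = c(1, 3), spikeExcess = c(0.45, 0.7),
                    inRoomSlope = 120, inRoomG0 = 0.3,
                    inRoomBlockMin = c(20, 45),
                    inRoomExcess = c(0.63, 0.73),
                    inRoomWindow = c(7.6, 20.0), inRoomHypShift = 3,
                    dailyJitterH = 0.15,
                    lightsOut = 22, lightsOn = 7),
    effects = list(hypnoticsDelayH = 3.2, hypnoticsMorningDamp = 0.5),
    covariates = list(pMale = 13 / 34, pCerebrovascular = 22 / 34,
                      pHypnotics = 10 / 34, pPsychotropics = 2 / 34,
                      pLocomotiveIndependent = 20 / 34,
                      age = c(77.5, 7.7, 66, 90),
                      bmi = c(22.3, 3.3, 15, 32),
                      mmse = c(28, 1.7, 24, 30),
                      motorFim = c(67.8, 17.4, 13, 91))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  .checkScheduleFeasible(cfg)
  class(cfg) <- "carGeneratorConfig"
  cfg
}

.checkScheduleFeasible <- function(cfg) {
  sch <- cfg$schedule
  widths <- vapply(sch$rehabWindows, diff, 1.0)
  if (any(widths * 60 < max(sch$rehabDurMin)))
    stop("config error: a rehab window is too short for the maximum ",
         "session duration (overlapping bouts would result)")
  ivals <- c(lapply(sch$mealTimes, function(m) c(m, m + sch$mealDurMin / 60)),
             sch$rehabWindows)
  ivals <- ivals[order(vapply(ivals, `[`, 1.0, 1))]
  for (i in seq_len(length(ivals) - 1))
    if (ivals[[i]][2] > ivals[[i + 1]][1] + 1e-9)
      stop("config error: overlapping schedule bouts")
  invisible(TRUE)
}

.truncNorm <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

.latentExcess <- function(t, rhythm, g, delta, c2s, phi2) {
  w1 <- 2 * pi / 24; w2 <- 2 * pi / 12
  g * (rhythm$c0 +
         rhythm$c1 * cos(w1 * (t - rhythm$p1 - delta)) +
         c2s * cos(w2 * (t - rhythm$p2 - delta - phi2)))
}

# half-sine bout profile added onto a window [startH, startH + durH)
.addBout <- function(excess, t, startH, durH, peak) {
  inB <- t >= startH & t < startH + durH
  u <- (t[inB] - startH) / durH
  excess[inB] <- excess[inB] + peak * sin(pi * u)
  excess
}

#' Generate one synthetic subject
#'
#' Draws covariates, the latent rhythm, the day schedule, scripted sleep
#' and noise for a single subject, reproducibly from \code{subjectSeed}.
#' METs are built as
#' \code{max(1, latent_rhythm + schedule_bouts + noise)}, with scripted
#' sleep pulling night epochs to just above the floor. Hypnotics users
#' have their latent rhythm delayed by the configured hours and their
#' morning rehabilitation participation damped, which delays the composite
#' peak while leaving sleep timing untouched.
#'
#' @param config a \code{carGeneratorConfig}.
#' @param subjectSeed integer seed for this subject.
#' @param subjectId id string (default derived from the seed).
#' @return list with \code{record} (covariate row), \code{series}
#'   (\linkS4class{EpochSeries}) and \code{truth} (latent ground truth).
#' @export
generateSubject <- function(config, subjectSeed,
                            subjectId = sprintf("S%04d", subjectSeed)) {
  set.seed(subjectSeed)
  cv <- config$covariates
  record <- data.frame(
    subject_id = subjectId,
    age = round(.truncNorm(1, cv$age[1], cv$age[2], cv$age[3], cv$age[4])),
    sex = ifelse(stats::runif(1) < cv$pMale, "male", "female"),
    bmi = round(.truncNorm(1, cv$bmi[1], cv$bmi[2], cv$bmi[3], cv$bmi[4]), 1),
    diagnosis = ifelse(stats::runif(1) < cv$pCerebrovascular,
                       "cerebrovascular", "orthopedic"),
    mmse = round(.truncNorm(1, cv$mmse[1], cv$mmse[2], cv$mmse[3], cv$mmse[4])),
    motor_fim = round(.truncNorm(1, cv$motorFim[1], cv$motorFim[2],
                                 cv$motorFim[3], cv$motorFim[4])),
    hypnotics = stats::runif(1) < cv$pHypnotics,
    psychotropics = stats::runif(1) < cv$pPsychotropics,
    locomotive_independent = stats::runif(1) < cv$pLocomotiveIndependent,
    stringsAsFactors = FALSE
  )

  rhy <- config$rhythm
  act <- config$activity
  g <- exp(stats::rnorm(1, log(act$gMean) - act$gSdLog^2 / 2, act$gSdLog))
  g <- min(act$gRange[2], max(act$gRange[1], g))
  delta <- stats::rnorm(1, rhy$phaseMean, rhy$phaseSd)
  if (record$hypnotics) delta <- delta + config$effects$hypnoticsDelayH
  c2s <- rhy$c2 * exp(stats::rnorm(1, -rhy$amp2SdLog^2 / 2, rhy$amp2SdLog))
  phi2 <- stats::rnorm(1, 0, rhy$phase2JitterSd)

  n <- round(config$nDays * 86400 / config$epochSeconds)
  t <- (seq_len(n) - 1) * config$epochSeconds / 3600
  excess <- .latentExcess(t, rhy, g, delta, c2s, phi2)

  # ward schedule. Meal times are fixed by the ward; rehabilitation slots
  # and in-room habits are drawn once per subject (inpatients keep stable
  # weekly timetables) and repeat daily with small jitter.
  sch <- config$schedule
  boutLog <- list()
  # subject-level propensity for brief self-care movements
  spikeRate <- sch$spikeRatePerDay * g *
    exp(stats::rnorm(1, -sch$spikeRateSdLog^2 / 2, sch$spikeRateSdLog))
  # habitual rehab slots: start/duration per window, drawn once
  nW <- length(sch$rehabWindows)
  fracs <- rep(min(sch$rehabActiveMax,
                   max(0, sch$rehabActiveSlope * (g - sch$rehabActiveG0))), nW)
  if (record$hypnotics && nW > 1) {
    # drowsy mornings: active exercise shifts from the morning session to
    # the afternoon ones, leaving the daily active total unchanged
    lost <- fracs[1] * (1 - config$effects$hypnoticsMorningDamp)
    fracs[1] <- fracs[1] - lost
    fracs[-1] <- pmin(sch$rehabActiveMax, fracs[-1] + lost / (nW - 1))
  }
  rehabPlan <- lapply(seq_len(nW), function(wi) {
    w <- sch$rehabWindows[[wi]]
    dur <- stats::runif(1, sch$rehabDurMin[1], sch$rehabDurMin[2]) / 60
    list(start = stats::runif(1, w[1], w[2] - dur), dur = dur,
         frac = fracs[wi], activeOffset = stats::runif(1, 0, 1))
  })
  # habitual in-room light-activity blocks (leisure around the bed,
  # washing up, short corridor walks): a daily time budget proportional
  # to the subject's activity level, at light intensity
  irWin <- sch$inRoomWindow
  # drowsy mornings under hypnotics push free-time activity later
  if (record$hypnotics) irWin[1] <- irWin[1] + sch$inRoomHypShift
  irTarget <- sch$inRoomSlope * max(0, g - sch$inRoomG0)
  irPlan <- list()
  spent <- 0
  while (irTarget - spent >= 5) {
    blkDur <- stats::runif(1, sch$inRoomBlockMin[1], sch$inRoomBlockMin[2])
    blkDur <- min(blkDur, irTarget - spent)
    irPlan[[length(irPlan) + 1]] <- list(
      start = irWin[1] + stats::rbeta(1, 2, 2) * (diff(irWin) - blkDur / 60),
      dur = blkDur / 60)
    spent <- spent + blkDur
  }
  jit <- function() stats::runif(1, -sch$dailyJitterH, sch$dailyJitterH)
  for (d in seq_len(config$nDays) - 1) {
    for (m in sch$mealTimes) {
      peak <- g * sch$mealPeak *
        stats::runif(1, sch$mealJitter[1], sch$mealJitter[2])
      excess <- .addBout(excess, t, d * 24 + m, sch$mealDurMin / 60, peak)
      boutLog[[length(boutLog) + 1]] <-
        data.frame(day = d, type = "meal", start_clock = m,
                   dur_min = sch$mealDurMin, peak_excess = peak,
                   active_min = 0, active_excess = NA_real_)
    }
    for (rp in rehabPlan) {
      startC <- rp$start + jit()
      # gentle elevation across the whole session ...
      excess <- .addBout(excess, t, d * 24 + startC, rp$dur,
                         g * sch$rehabPassive)
      # ... plus a contiguous active-exercise block whose share of the
      # session grows with the subject's functional activity level
      activeDur <- rp$frac * rp$dur
      activeExc <- stats::runif(1, sch$rehabActiveExcess[1],
                                sch$rehabActiveExcess[2])
      if (activeDur > 0) {
        activeStart <- startC + rp$activeOffset * (rp$dur - activeDur)
        inA <- t >= d * 24 + activeStart &
          t < d * 24 + activeStart + activeDur
        # exercise sets the absolute activity level (light exercise METs)
        excess[inA] <- pmax(excess[inA], activeExc)
      }
      boutLog[[length(boutLog) + 1]] <-
        data.frame(day = d, type = "rehab", start_clock = startC,
                   dur_min = rp$dur * 60, peak_excess = g * sch$rehabPassive,
                   active_min = activeDur * 60, active_excess = activeExc)
    }
    for (bp in irPlan) {
      blkStart <- bp$start + jit()
      inB <- t >= d * 24 + blkStart & t < d * 24 + blkStart + bp$dur
      excess[inB] <- pmax(excess[inB],
                          stats::runif(1, sch$inRoomExcess[1],
                                       sch$inRoomExcess[2]))
    }
    # brief self-care movements (transfers, toileting) through the day;
    # frequency scales with the subject's activity level, intensity does not
    nSpk <- stats::rpois(1, spikeRate)
    if (nSpk > 0) {
      for (k in seq_len(nSpk)) {
        spkStart <- stats::runif(1, sch$lightsOn, sch$lightsOut - 0.1)
        spkDur <- stats::runif(1, sch$spikeDurMin[1], sch$spikeDurMin[2]) / 60
        spkPeak <- stats::runif(1, sch$spikeExcess[1], sch$spikeExcess[2])
        inS <- t >= d * 24 + spkStart & t < d * 24 + spkStart + spkDur
        excess[inS] <- pmax(excess[inS], spkPeak)
      }
    }
  }

  # scripted sleep: nightly bed/wake around the ward's lights-out/lights-on
  slp <- config$sleep
  truthNights <- NULL
  if (slp$script) {
    # waking wrist activity never sits at the device floor
    excess <- pmax(excess, slp$wakeFloor)
    muBed <- .truncNorm(1, slp$bedMean, slp$subjectSd,
                        slp$bedRange[1], slp$bedRange[2])
    muWake <- .truncNorm(1, slp$wakeMean, slp$subjectSd,
                         slp$wakeRange[1], slp$wakeRange[2])
    asleep <- rep(FALSE, n)
    tEnd <- config$nDays * 24
    nights <- list()
    for (j in seq(-1, config$nDays - 1)) {
      bed <- if (j < 0) -Inf else
        j * 24 + .truncNorm(1, muBed, slp$nightlySd,
                            slp$bedRange[1], slp$bedRange[2])
      wake <- if (j == config$nDays - 1) Inf else
        (j + 1) * 24 + .truncNorm(1, muWake, slp$nightlySd,
                                  slp$wakeRange[1], slp$wakeRange[2])
      lo <- max(bed, 0); hi <- min(wake, tEnd)
      if (lo >= hi) next
      # smooth wind-down before bed and wind-up after waking, so the
      # day/night transition is gradual rather than a square step
      w0 <- slp$windLevel
      dn <- t >= bed - slp$windDownH & t < bed
      excess[dn] <- w0 + (excess[dn] - w0) * (bed - t[dn]) / slp$windDownH
      up <- t >= wake & t < wake + slp$windUpH
      excess[up] <- w0 + (excess[up] - w0) * (t[up] - wake) / slp$windUpH
      asleep <- asleep | (t >= lo & t < hi)
      # arousals inside the in-record portion of the night
      # arousal load scales with how much of the night is in-record
      nAr <- stats::rpois(1, slp$arousalsPerNight * min(1, (hi - lo) / 8))
      arMin <- 0
      if (nAr > 0 && hi - lo > 1) {
        # arousal times are drawn irregularly with a guaranteed minimum
        # separation, so scored wake runs stay within the bout-gap
        # tolerance (hard-core construction: sorted uniforms plus fixed
        # spacing offsets)
        gapH <- 25 / 60
        span <- hi - lo - 0.7
        nAr <- min(nAr, max(1, floor(span / gapH) - 1))
        free <- span - (nAr - 1) * gapH
        starts <- lo + 0.3 + sort(stats::runif(nAr, 0, free)) +
          (seq_len(nAr) - 1) * gapH
        for (k in seq_along(starts)) {
          durA <- round(stats::runif(1, slp$arousalDurRange[1],
                                     slp$arousalDurRange[2]))
          startA <- starts[k]
          inA <- t >= startA & t < min(startA + durA / 60, hi)
          excA <- stats::runif(1, slp$arousalExcess[1], slp$arousalExcess[2])
          excess[inA] <- excA
          asleep[inA] <- FALSE
          arMin <- arMin + sum(inA) * config$epochSeconds / 60
        }
      }
      nights[[length(nights) + 1]] <-
        data.frame(night = j, bed_clock = if (is.finite(bed)) bed %% 24 else NA,
                   wake_clock = if (is.finite(wake)) wake %% 24 else NA,
                   arousal_min = arMin)
    }
    truthNights <- do.call(rbind, nights)
    excess[asleep] <- slp$sleepExcess
  }

  # population value of the rhythm estimand: the 24-h + 12-h Fourier
  # projection of the noise-free signal, and its composite peak time
  w1 <- 2 * pi / 24; w2 <- 2 * pi / 12
  prj <- function(f) c(2 * mean(excess * cos(f * t)),
                       2 * mean(excess * sin(f * t)))
  ab1 <- prj(w1); ab2 <- prj(w2)
  projFit <- new("HarmonicFit", mesor = 1 + mean(excess),
                 periods = c(24, 12),
                 amplitudes = c(sqrt(sum(ab1^2)), sqrt(sum(ab2^2))),
                 acrophases = c(atan2(ab1[2], ab1[1]) %% (2 * pi),
                                atan2(ab2[2], ab2[1]) %% (2 * pi)),
                 rsquared = 1, nUsed = length(t))
  projCar <- extractCAR(projFit)

  eta <- exp(stats::rnorm(n, -config$noise$sdLog^2 / 2, config$noise$sdLog))
  metsVals <- pmax(1, 1 + excess * eta)
  series <- EpochSeries(subjectId, metsVals,
                        start = paste(config$startDate, "00:00:00"),
                        epochSeconds = config$epochSeconds)
  w1 <- 2 * pi / 24; w2 <- 2 * pi / 12
  truth <- list(
    subject_id = subjectId, seed = subjectSeed, g = g,
    mesor = 1 + g * rhy$c0, A1 = g * rhy$c1,
    theta1 = (w1 * (rhy$p1 + delta)) %% (2 * pi),
    A2 = g * c2s,
    theta2 = (w2 * (rhy$p2 + delta + phi2)) %% (2 * pi),
    peak_delay = delta,
    # estimand values: Fourier (24 h + 12 h) projection of the noise-free
    # signal and its composite extrema
    proj_mesor = projFit@mesor, proj_A1 = projFit@amplitudes[1],
    proj_peak_time = projCar@maxPhase, proj_maximum = projCar@maximum,
    nights = truthNights,
    bouts = do.call(rbind, boutLog)
  )
  list(record = record, series = series, truth = truth)
}

#' Generate a synthetic inpatient cohort
#'
#' Generates \code{nSubjects} independent subjects from per-subject seeds
#' \code{seed + i}. Identical (config, seed) yield byte-identical cohorts.
#'
#' @param config a \code{carGeneratorConfig} from [generatorConfig()].
#' @return an \linkS4class{ActigraphyCohort}.
#' @export
generateCohort <- function(config = generatorConfig()) {
  out <- lapply(seq_len(config$nSubjects), function(i) {
    generateSubject(config, config$seed + i, sprintf("S%02d", i))
  })
  new("ActigraphyCohort",
      series = stats::setNames(lapply(out, `[[`, "series"),
                               vapply(out, function(x) x$record$subject_id, "")),
      subjects = do.call(rbind, lapply(out, `[[`, "record")),
      groundTruth = stats::setNames(lapply(out, `[[`, "truth"),
                                    vapply(out, function(x) x$record$subject_id, "")))
}

#' @rdname ActigraphyCohort-class
#' @export
setMethod("cohortSeries", "ActigraphyCohort", function(x) x@series)

#' @rdname ActigraphyCohort-class
#' @export
setMethod("subjectTable", "ActigraphyCohort", function(x) x@subjects)

#' @rdname ActigraphyCohort-class
#' @export
setMethod("groundTruth", "ActigraphyCohort", function(x) x@groundTruth)

setMethod("show", "ActigraphyCohort", function(object) {
  cat("ActigraphyCohort:", length(object@series), "subject(s)\n")
  if (length(object@series)) {
    spans <- vapply(object@series, function(s)
      length(mets(s)) * epochSeconds(s) / 86400, 1.0)
    cat(sprintf("  record span %.1f-%.1f days; ground truth %s\n",
                min(spans), max(spans),
                if (length(object@groundTruth)) "available" else "absent"))
  }
})

#' Tabulate generator ground truth
#'
#' Per-subject latent rhythm parameters and scripted sleep, for
#' truth-versus-fitted recovery analyses.
#'
#' @param cohort an \linkS4class{ActigraphyCohort} produced by
#'   [generateCohort()].
#' @return data.frame with one row per subject.
#' @export
describeGroundTruth <- function(cohort) {
  gt <- groundTruth(cohort)
  if (!length(gt)) stop("cohort carries no ground truth")
  do.call(rbind, lapply(gt, function(x) {
    data.frame(
      subject_id = x$subject_id, g = x$g, mesor = x$mesor,
      A1 = x$A1, theta1 = x$theta1, A2 = x$A2, theta2 = x$theta2,
      peak_delay_h = x$peak_delay,
      proj_mesor = x$proj_mesor, proj_A1 = x$proj_A1,
      proj_peak_time = x$proj_peak_time, proj_maximum = x$proj_maximum,
      bed_clock_mean = mean(x$nights$bed_clock, na.rm = TRUE),
      wake_clock_mean = mean(x$nights$wake_clock, na.rm = TRUE),
      arousal_min_mean = mean(x$nights$arousal_min),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write a cohort to disk in the standard exchange formats
#'
#' Emits \code{epochs.csv} (long epoch CSV), \code{subjects.csv}
#' (metadata) and, when present, \code{ground_truth.json}.
#'
#' @param cohort an \linkS4class{ActigraphyCohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEpochSeries(cohortSeries(cohort), file.path(dir, "epochs.csv"))
  writeSubjectTable(subjectTable(cohort), file.path(dir, "subjects.csv"))
  gt <- groundTruth(cohort)
  if (length(gt))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a cohort from the standard exchange formats
#' @param dir directory holding \code{epochs.csv} and \code{subjects.csv}.
#' @param epochSeconds epoch length for [readEpochSeries()].
#' @return an \linkS4class{ActigraphyCohort} (without ground truth).
#' @export
readCohort <- function(dir, epochSeconds = 60) {
  new("ActigraphyCohort",
      series = readEpochSeries(file.path(dir, "epochs.csv"), epochSeconds),
      subjects = readSubjectTable(file.path(dir, "subjects.csv")),
      groundTruth = list())
}
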