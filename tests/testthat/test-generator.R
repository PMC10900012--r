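test_that("identical config and seed give identical subjects", {
  cfg <- generatorConfig(seed = 5, nSubjects = 2)
  a <- generateSubject(cfg, 7)
  b <- generateSubject(cfg, 7)
  expect_identical(mets(a$series), mets(b$series))
  expect_identical(a$record, b$record)
  expect_identical(a$truth$g, b$truth$g)
  # different subject seed gives a different draw
  expect_false(identical(mets(a$series),
                         mets(generateSubject(cfg, 8)$series)))
})

test_that("per-subject seeds make cohorts extensible without perturbation", {
  small <- generateCohort(generatorConfig(seed = 40, nSubjects = 3))
  large <- generateCohort(generatorConfig(seed = 40, nSubjects = 5))
  for (id in names(cohortSeries(small)))
    expect_identical(mets(cohortSeries(small)[[id]]),
                     mets(cohortSeries(large)[[id]]))
})

test_that("the default cohort has the study shape", {
  cohort <- defaultRun()$cohort
  expect_length(cohortSeries(cohort), 34)
  for (es in cohortSeries(cohort)[c(1, 17, 34)]) {
    d <- splitDays(es)
    expect_equal(sum(d$complete), 5)
    expect_true(all(mets(es) >= 1))
  }
})

test_that("covariate prevalences sit inside binomial 95% bands", {
  subjects <- subjectTable(defaultRun()$cohort)
  n <- nrow(subjects)
  inBand <- function(k, p) {
    expect_gte(k, qbinom(0.025, n, p))
    expect_lte(k, qbinom(0.975, n, p))
  }
  inBand(sum(subjects$sex == "male"), 13 / 34)
  inBand(sum(subjects$hypnotics), 10 / 34)
  inBand(sum(subjects$diagnosis == "cerebrovascular"), 22 / 34)
  inBand(sum(subjects$locomotive_independent), 20 / 34)
  expect_true(all(subjects$age >= 65 & subjects$age <= 90))
  expect_true(all(subjects$mmse >= 24 & subjects$mmse <= 30))
  expect_true(all(subjects$motor_fim >= 13 & subjects$motor_fim <= 91))
})

test_that("without noise, bouts or sleep the fit recovers the latent rhythm", {
  cfg <- generatorConfig(seed = 3,
    rhythm = list(c0 = 0.30, c1 = 0.20, c2 = 0.05),  # stays above the floor
    noise = list(sdLog = 0),
    sleep = list(script = FALSE),
    schedule = list(mealPeak = 0, rehabPassive = 0, rehabActiveSlope = 0,
                    spikeRatePerDay = 0, inRoomSlope = 0))
  sub <- generateSubject(cfg, 12)
  fit <- fitHarmonics(sub$series)
  expect_equal(fit@mesor, sub$truth$mesor, tolerance = 1e-6)
  expect_equal(fit@amplitudes[1], sub$truth$A1, tolerance = 1e-6)
  expect_equal(fit@acrophases[1], sub$truth$theta1, tolerance = 1e-6)
  expect_equal(fit@amplitudes[2], sub$truth$A2, tolerance = 1e-6)
  expect_equal(fit@rsquared, 1, tolerance = 1e-9)
})

test_that("ground truth joins to fitted output and supports recovery checks", {
  run <- defaultRun()
  gt <- describeGroundTruth(run$cohort)
  ct <- run$cohortTable
  joined <- merge(gt, ct, by = "subject_id")
  expect_equal(nrow(joined), 34)
  expect_gt(cor(joined$mesor.y, joined$mesor.x), 0.95)
  phaseErr <- (joined$max_phase_time - joined$proj_peak_time + 12) %% 24 - 12
  expect_lt(mean(abs(phaseErr)), 0.5)
  # scripted bed/wake land near the ward's lights-out/lights-on
  expect_true(all(abs(gt$bed_clock_mean - 22) < 1.6))
  expect_true(all(abs(gt$wake_clock_mean - 7) < 2.2))
})

test_that("detected bed and wake times track the script on >= 90% of nights", {
  run <- defaultRun()
  hits <- 0; tot <- 0
  for (id in names(cohortSeries(run$cohort))) {
    b <- attr(run$results[[id]]$sleep, "nights")
    tn <- groundTruth(run$cohort)[[id]]$nights
    for (k in seq_len(nrow(b))) {
      tr <- tn[tn$night == b$night[k], ]
      if (nrow(tr) == 1 && is.finite(tr$bed_clock) && is.finite(tr$wake_clock)) {
        tot <- tot + 1
        hits <- hits + (abs(b$bed_time[k] %% 24 - tr$bed_clock) <= 0.25 &&
                          abs(b$waking_time[k] - tr$wake_clock) <= 0.25)
      }
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("nights spent asleep keep counts below the wake-inducing level", {
  sub <- generateSubject(generatorConfig(seed = 60), 61)
  counts <- metsToCounts(sub$series, scale = 15)
  th <- timeHours(sub$series)
  night <- th %% 24 >= 23 | th %% 24 < 5
  # weighted-sum wake needs window counts near 1.5; sleeping epochs sit low
  expect_gt(mean(counts[night] < 1.5, na.rm = TRUE), 0.9)
})

test_that("an infeasible schedule is a config error", {
  expect_error(generatorConfig(schedule = list(rehabWindows =
    list(c(9, 9.5), c(13, 15), c(15, 17)))), "config error")
  expect_error(generatorConfig(schedule = list(mealTimes = c(7, 9.2, 18))),
               "overlapping")
})

test_that("cohort files round-trip through the exchange formats", {
  dir <- withr::local_tempdir()
  cohort <- generateCohort(generatorConfig(seed = 77, nSubjects = 2, nDays = 1))
  writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- readCohort(dir)
  expect_identical(names(cohortSeries(back)), names(cohortSeries(cohort)))
  for (id in names(cohortSeries(back)))
    expect_equal(mets(cohortSeries(back)[[id]]),
                 mets(cohortSeries(cohort)[[id]]), tolerance = 1e-9)
  st <- subjectTable(back)
  expect_equal(st$age, subjectTable(cohort)$age)
  expect_equal(st$hypnotics, subjectTable(cohort)$hypnotics)
})
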