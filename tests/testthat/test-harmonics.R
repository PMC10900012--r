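test_that("a noise-free single-component signal is recovered exactly", {
  es <- makeCosSeries(M = 1.2, A1 = 0.2, th1 = pi, A2 = 0, days = 1)
  fit <- fitHarmonics(es, periods = 24)
  expect_equal(fit@mesor, 1.2, tolerance = 1e-9)
  expect_equal(fit@amplitudes, 0.2, tolerance = 1e-9)
  expect_equal(fit@acrophases, pi, tolerance = 1e-9)
  expect_equal(fit@rsquared, 1, tolerance = 1e-9)
})

test_that("degenerate and rank-deficient inputs are rejected", {
  const <- EpochSeries("s1", rep(1.3, 1440))
  expect_error(fitHarmonics(const), "R-squared undefined")
  short <- EpochSeries("s1", c(1.2, 1.3, 1.4))
  expect_error(fitHarmonics(short), "at least")
})

test_that("noisy two-component coefficients match a normal-equations oracle", {
  es <- makeCosSeries(M = 1.25, A1 = 0.18, th1 = 2.9, A2 = 0.06, th2 = 1.1,
                      days = 5, noiseSd = 0.1, seed = 99)
  fit <- fitHarmonics(es)
  # independent oracle: solve X'X beta = X'y directly
  t <- timeHours(es); y <- mets(es)
  X <- cbind(1, cos(2 * pi / 24 * t), sin(2 * pi / 24 * t),
             cos(2 * pi / 12 * t), sin(2 * pi / 12 * t))
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit@mesor, beta[1], tolerance = 1e-8)
  expect_equal(fit@amplitudes[1], sqrt(beta[2]^2 + beta[3]^2),
               tolerance = 1e-8)
  expect_equal(fit@acrophases[1], atan2(beta[3], beta[2]) %% (2 * pi),
               tolerance = 1e-8)
  expect_equal(fit@amplitudes[2], sqrt(beta[4]^2 + beta[5]^2),
               tolerance = 1e-8)
})

test_that("mesor equals the sample mean for whole-day uniform sampling", {
  for (seed in 1:5) {
    es <- makeCosSeries(M = 1.3, A1 = 0.15, th1 = seed, A2 = 0.05,
                        th2 = 2 * seed, days = 3, noiseSd = 0.05, seed = seed)
    fit <- fitHarmonics(es)
    expect_equal(fit@mesor, mean(mets(es)), tolerance = 1e-9)
  }
})

test_that("R-squared is invariant to level shifts and whole-period origin shifts", {
  es <- makeCosSeries(M = 1.25, A1 = 0.2, th1 = 1.5, A2 = 0.05, th2 = 0.7,
                      days = 2, noiseSd = 0.08, seed = 5)
  r2 <- fitHarmonics(es)@rsquared
  shifted <- EpochSeries("s1", mets(es) + 0.7, start = "2024-01-01 00:00:00")
  expect_equal(fitHarmonics(shifted)@rsquared, r2, tolerance = 1e-9)
  # same data relabelled one whole day later
  lagged <- EpochSeries("s1", mets(es), start = "2024-01-02 00:00:00")
  expect_equal(fitHarmonics(lagged)@rsquared, r2, tolerance = 1e-9)
})

test_that("evaluateCurve reproduces closed-form values", {
  fit <- makeFit(1.2, c(24, 12), c(0.15, 0.05), c(pi, 0))
  expect_equal(evaluateCurve(fit, 12), 1.4, tolerance = 1e-12)
  expect_equal(evaluateCurve(fit, 3), 1.2 - 0.15 * sqrt(2) / 2,
               tolerance = 1e-9)  # approx 1.094
  flat <- makeFit(1.3, c(24, 12), c(0, 0), c(0, 0))
  expect_equal(evaluateCurve(flat, c(0, 5.5, 23)), rep(1.3, 3))
})

test_that("extractCAR matches closed forms for a single component", {
  car <- extractCAR(makeFit(1.2, 24, 0.2, pi))
  expect_equal(car@maximum, 1.4, tolerance = 1e-9)
  expect_equal(car@minimum, 1.0, tolerance = 1e-9)
  expect_equal(car@range, 0.4, tolerance = 1e-12)
  expect_equal(car@maxPhase, 12, tolerance = 1e-9)
  expect_equal(car@minPhase, 0, tolerance = 1e-9)
})

test_that("extractCAR finds the interior minimum of a composite curve", {
  car <- extractCAR(makeFit(1.2, c(24, 12), c(0.15, 0.05), c(pi, 0)))
  expect_equal(car@maximum, 1.4, tolerance = 1e-9)
  expect_equal(car@maxPhase, 12, tolerance = 1e-6)
  # interior minimum near 2.7 h (mirrored near 21.3 h; earliest reported)
  expect_lt(abs(car@minPhase - 2.7), 0.1)
  expect_lt(abs(car@minimum - 1.094), 0.002)
})

test_that("CAR invariants hold for random fits", {
  set.seed(31)
  for (i in 1:25) {
    fit <- makeFit(runif(1, 1, 2), c(24, 12), runif(2, 0, 0.4),
                   runif(2, 0, 2 * pi))
    car <- extractCAR(fit)
    expect_equal(car@range, car@maximum - car@minimum, tolerance = 1e-12)
    expect_lte(car@maximum, fit@mesor + sum(fit@amplitudes) + 1e-9)
    expect_gte(car@minimum, fit@mesor - sum(fit@amplitudes) - 1e-9)
    expect_gte(car@mesor, car@minimum - 1e-9)
    expect_lte(car@mesor, car@maximum + 1e-9)
    if (car@range > 0) expect_true(car@maxPhase != car@minPhase)
  }
})

test_that("period scan ranks the true period first for pure signals", {
  es24 <- makeCosSeries(M = 1.3, A1 = 0.2, th1 = 1, days = 2,
                        noiseSd = 0.02, seed = 3)
  scan24 <- scanPeriods(es24, 48)
  expect_equal(scan24$period[1], 24)
  # pure 8-h cycle: y = M + A cos(2*pi/8 * t)
  t <- (0:(2 * 1440 - 1)) / 60
  es8 <- EpochSeries("s8", 1.3 + 0.2 * cos(2 * pi / 8 * t) +
                       rnorm(length(t), 0, 0.02))
  scan8 <- scanPeriods(es8, 48)
  expect_equal(scan8$period[1], 8)
})

test_that("period scan skips sub-epoch candidates with a warning", {
  es <- makeCosSeries(days = 1, epochSeconds = 300)  # 5-min epochs
  expect_warning(scan <- scanPeriods(es, 200), "skipped")
  expect_true(all(is.na(scan$r_squared[scan$note != ""])))
  expect_true(all(scan$period[!is.na(scan$r_squared)] >= 2 * 300 / 3600))
})
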