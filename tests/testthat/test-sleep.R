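test_that("metsToCounts applies the floor and scale", {
  es <- EpochSeries("s1", c(1.0, 1.5, 2.0), valid = c(TRUE, TRUE, FALSE))
  expect_equal(metsToCounts(es, scale = 200), c(0, 100, NA))
  expect_equal(metsToCounts(es, scale = 15)[1:2], c(0, 7.5))
  expect_error(metsToCounts(es, scale = 0), "> 0")
})

test_that("all-quiet input scores as sleep, a large spike as wake", {
  night <- EpochSeries("s1", rep(1.01, 120))
  expect_true(all(sleepStates(coleKripke(night)) == "sleep"))
  spiky <- rep(1.01, 120)
  spiky[60] <- 3.5   # isolated large movement
  st <- sleepStates(coleKripke(EpochSeries("s1", spiky)))
  expect_equal(as.character(st[60]), "wake")
  # weighted neighbours are dragged to wake; remote epochs stay asleep
  expect_equal(as.character(st[61]), "wake")
  expect_true(all(st[1:54] == "sleep"))
  expect_true(all(st[66:120] == "sleep"))
})

test_that("states match a hand-computed weighted sum, epoch by epoch", {
  counts <- c(0, 4, 0, 0, 12, 2, 0, 0, 6, 0)
  es <- EpochSeries("s1", 1 + counts / 15)  # countsScale 15 recovers counts
  st <- sleepStates(coleKripke(es, countsScale = 15))
  w <- c(106, 54, 58, 76, 230, 74, 67)
  expected <- sapply(1:10, function(i) {
    D <- 0
    for (j in -4:2) {
      k <- i + j
      if (k >= 1 && k <= 10) D <- D + w[j + 5] * counts[k]
    }
    if (0.001 * D < 1) "sleep" else "wake"
  })
  expect_equal(as.character(st), expected)
})

test_that("scoring is monotone: raising a count never turns wake into sleep", {
  set.seed(21)
  base <- abs(rnorm(60, 0.5, 0.6))
  es <- EpochSeries("s1", 1 + base / 15)
  st0 <- sleepStates(coleKripke(es, countsScale = 15))
  for (i in c(5, 20, 41)) {
    bumped <- base
    bumped[i] <- bumped[i] + 5
    st1 <- sleepStates(coleKripke(EpochSeries("s1", 1 + bumped / 15),
                                  countsScale = 15))
    expect_true(all(!(st0 == "wake" & st1 == "sleep")))
  }
})

test_that("non-1-min epochs need resampling", {
  es30 <- EpochSeries("s1", rep(1.01, 240), epochSeconds = 30)
  expect_error(coleKripke(es30), "resample")
  sw <- coleKripke(es30, resample = TRUE)
  expect_length(sleepStates(sw), 120)
})

# build a day-night-day series: wake until bedH, sleep to wakeH next day
nightSeries <- function(bedH = 22, wakeH = 30, days = 2, wakeMets = 1.3,
                        sleepMets = 1.02, gaps = NULL) {
  n <- days * 1440
  t <- (0:(n - 1)) / 60
  m <- rep(wakeMets, n)
  m[t >= bedH & t < wakeH] <- sleepMets
  if (!is.null(gaps)) for (g in gaps) m[t >= g[1] & t < g[1] + g[2] / 60] <- 1.6
  EpochSeries("s1", m)
}

test_that("a clean 22:00-06:00 night is detected with exact edges", {
  sw <- coleKripke(nightSeries())
  b <- detectMainSleep(sw)
  b <- b[!b$censored, ]
  expect_equal(nrow(b), 1)
  expect_equal(b$bed_time, 22, tolerance = 0.05)
  expect_equal(b$waking_time, 6, tolerance = 0.05)
  expect_equal(b$duration_min, 480, tolerance = 3)
})

test_that("wake gaps within tolerance stay inside the bout", {
  sw <- coleKripke(nightSeries(gaps = list(c(26, 5))))  # 5-min gap at 02:00
  b <- detectMainSleep(sw)
  b <- b[!b$censored, ]
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 480, tolerance = 3)
  expect_gte(b$arousal_min, 5)
  # a 30-min scripted arousal splits the night into two bouts; the longest
  # (the post-arousal segment) is kept for that night
  sw2 <- coleKripke(nightSeries(gaps = list(c(25, 30))))
  b2 <- detectMainSleep(sw2)
  b2 <- b2[!b2$censored, ]
  expect_equal(nrow(b2), 1)
  expect_lt(b2$duration_min, 330)
})

test_that("bouts truncated by the record boundary are censored", {
  # asleep at record start, and again at record end
  m <- c(rep(1.02, 6 * 60), rep(1.3, 15.5 * 60), rep(1.02, 2.5 * 60))
  sw <- coleKripke(EpochSeries("s1", m))
  b <- detectMainSleep(sw)
  expect_true(all(b$censored))
})

test_that("sleep summary implements the efficiency formula exactly", {
  bouts <- data.frame(night = 0, onset_hours = 22, offset_hours = 30,
                      bed_time = 22, waking_time = 6, duration_min = 480,
                      arousal_min = 30, censored = FALSE)
  s <- sleepSummary(bouts)
  expect_equal(s$total_sleep_time_min, 450)
  expect_equal(s$sleep_efficiency_pct, 93.75)
  expect_equal(s$n_nights, 1)
  # efficiency == 100 * TST / bout duration, asserted the other way round
  nights <- attr(s, "nights")
  expect_equal(nights$efficiency_pct,
               100 * nights$tst_min / nights$duration_min)
  # zero-arousal night
  bouts$arousal_min <- 0
  expect_equal(sleepSummary(bouts)$sleep_efficiency_pct, 100)
})

test_that("summary averages across nights and drops censored ones", {
  bouts <- data.frame(night = 0:2, onset_hours = c(22, 46, 70),
                      offset_hours = c(30, 54, 78),
                      bed_time = c(22, 21.5, 22.5),
                      waking_time = c(6, 6.5, 6),
                      duration_min = c(480, 500, 460),
                      arousal_min = c(30, 20, 40),
                      censored = c(FALSE, FALSE, TRUE))
  s <- sleepSummary(bouts)
  expect_equal(s$n_nights, 2)
  expect_equal(s$total_sleep_time_min, mean(c(450, 480)))
  expect_equal(s$bed_time_h, 21.75)
  expect_warning(sleepSummary(bouts[bouts$censored, ]), "no scoreable night")
})
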