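test_that("identical groups give p = 1; separated groups give the exact minimal p", {
  same <- compareGroups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                        "mann_whitney")
  expect_equal(same$p_value, 1)
  sep <- compareGroups(c(0, 0, 0, 10, 10, 10), rep(c("a", "b"), each = 3),
                       "mann_whitney")
  expect_equal(sep$statistic, 0)
  # exact two-sided p = 2 / choose(6, 3): all 20 rank assignments enumerated
  expect_equal(sep$p_value, 2 / choose(6, 3))
})

test_that("Welch's test matches unequal-variance expectations", {
  set.seed(4)
  x <- rnorm(12, 0, 1); y <- rnorm(8, 2, 3)
  got <- compareGroups(c(x, y), rep(c("a", "b"), c(12, 8)), "welch")
  ref <- t.test(x, y)
  expect_equal(got$p_value, ref$p.value)
  expect_error(compareGroups(c(1, 2), c("a", "a"), "welch"), "two levels")
  expect_error(compareGroups(c(1, 2, 3), c("a", "a", "b"), "welch"),
               "2 observations")
})

test_that("correlations are symmetric, sign-equivariant, and exact on lines", {
  x <- c(2, 4, 1, 7, 5, 3)
  expect_equal(correlateVars(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlateVars(x, exp(x), "spearman")$r, 1)  # monotone map
  set.seed(2)
  a <- rnorm(20); b <- a + rnorm(20)
  expect_equal(correlateVars(a, b, "pearson")$r,
               correlateVars(b, a, "pearson")$r)
  expect_equal(correlateVars(-a, b, "pearson")$r,
               -correlateVars(a, b, "pearson")$r)
  expect_error(correlateVars(rep(1, 5), 1:5), "constant")
})

test_that("auto mode picks Pearson for normal data, Spearman otherwise", {
  set.seed(12)
  expect_equal(correlateVars(rnorm(50), rnorm(50), "auto")$method, "pearson")
  skewed <- rexp(50)^3
  expect_equal(correlateVars(skewed, rnorm(50), "auto")$method, "spearman")
})

test_that("Durbin-Watson reproduces the toy cases and the i.i.d. null", {
  expect_equal(durbinWatson(rep(1, 5)), 0)
  expect_equal(durbinWatson(c(1, -1, 1, -1)), 3)
  set.seed(77)
  d <- durbinWatson(rnorm(1000))
  expect_gt(d, 1.8); expect_lt(d, 2.2)
})

test_that("simple regression recovers exact lines and slope = r when standardized", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  y <- 0.5 * x - 2
  r <- suppressWarnings(simpleRegression(y, x))  # exact fit: summary warns
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(r$coefficients["x", 1]), 0.5, tolerance = 1e-12)
  set.seed(15)
  a <- rnorm(40); b <- 0.6 * a + rnorm(40)
  rs <- simpleRegression(scale(b)[, 1], scale(a)[, 1])
  expect_equal(unname(rs$coefficients["x", 1]), cor(a, b), tolerance = 1e-9)
  expect_error(simpleRegression(b, rep(2, 40)), "constant predictor")
})

test_that("regression diagnostics agree with independent oracles", {
  skip_if_not_installed("lmtest")
  skip_if_not_installed("car")
  set.seed(23)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  X <- cbind(X, x3 = 0.7 * X[, "x1"] + rnorm(n, 0, 0.5))
  y <- 1 + X %*% c(0.5, -0.3, 0.2) + rnorm(n, 0, 0.4)
  got <- multipleRegression(y[, 1], X)
  ref <- lm(y ~ X)
  expect_equal(got$r_squared, summary(ref)$r.squared, tolerance = 1e-12)
  expect_equal(got$durbin_watson,
               unname(lmtest::dwtest(ref)$statistic), tolerance = 1e-9)
  refv <- lm(y ~ x1 + x2 + x3, data = data.frame(y = y[, 1], X))
  expect_equal(unname(got$vif), unname(car::vif(refv)), tolerance = 1e-9)
})

test_that("orthogonal predictors have VIF 1; duplicates are a rank error", {
  n <- 32
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  set.seed(6)
  y <- x1 + x2 + rnorm(n)
  got <- multipleRegression(y, cbind(x1, x2))
  expect_equal(unname(got$vif), c(1, 1), tolerance = 1e-9)
  expect_error(multipleRegression(y, cbind(x1, x1)), "rank error")
})

test_that("the cohort report covers the full comparison and correlation grids", {
  run <- defaultRun()
  rep_ <- run$report
  # 5 grouping factors x 10 outcomes; 11 continuous factors, sleep metrics
  # skip their own column
  expect_equal(nrow(rep_$comparisons), 5 * 10)
  expect_equal(nrow(rep_$correlations), 11 * 10 - 4)
  expect_match(rep_$header, "no multiple-testing correction")
  expect_true(all(is.na(rep_$comparisons$welch_p) |
                    (rep_$comparisons$welch_p >= 0 &
                       rep_$comparisons$welch_p <= 1)))
  # degenerate cohort: identical subjects flag every cell, never crash
  ct <- run$cohortTable
  flat <- ct[rep(1, 8), ]
  flat$subject_id <- paste0("d", 1:8)
  flat$sex <- rep(c("male", "female"), 4)
  degen <- cohortReport(flat)
  expect_true(all(degen$correlations$note != ""))
})

test_that("SB and LIPA correlate with opposite signs against the rhythm height", {
  ct <- defaultRun()$cohortTable
  for (o in c("mesor", "maximum", "range")) {
    expect_lt(cor(ct$sb_min_per_day, ct[[o]], method = "spearman"), -0.5)
    expect_gt(cor(ct$lipa_min_per_day, ct[[o]], method = "spearman"), 0.5)
  }
})

test_that("the hypnotics phase delay is detected in most simulated cohorts", {
  # effect sized to the observed ~2-2.5 h delay in peak activity time
  hits <- vapply(1:25, function(s) {
    cfg <- generatorConfig(seed = 30000 + s * 101)
    cohort <- generateCohort(cfg)
    ph <- vapply(cohortSeries(cohort), function(es)
      extractCAR(fitHarmonics(es))@maxPhase, 1.0)
    hyp <- subjectTable(cohort)$hypnotics
    if (sum(hyp) < 2 || sum(!hyp) < 2) return(NA)
    compareGroups(ph, hyp, "welch")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})
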