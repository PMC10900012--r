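# Shared fixtures, built in code.

# noiseless (or noisy) two-component cosine series on 1-min epochs
makeCosSeries <- function(M = 1.2, A1 = 0.2, th1 = pi, A2 = 0, th2 = 0,
                          days = 1, epochSeconds = 60, noiseSd = 0,
                          seed = NULL, subjectId = "sim") {
  if (!is.null(seed)) set.seed(seed)
  n <- round(days * 86400 / epochSeconds)
  t <- (seq_len(n) - 1) * epochSeconds / 3600
  y <- M + A1 * cos(2 * pi / 24 * t - th1) + A2 * cos(2 * pi / 12 * t - th2)
  if (noiseSd > 0) y <- y + rnorm(n, 0, noiseSd)
  EpochSeries(subjectId, pmax(1, y), start = "2024-01-01 00:00:00",
              epochSeconds = epochSeconds)
}

makeFit <- function(M, periods, A, th, r2 = 1, n = 0L) {
  new("HarmonicFit", mesor = M, periods = periods, amplitudes = A,
      acrophases = th, rsquared = r2, nUsed = as.integer(n))
}

# the default synthetic cohort and its pipeline run, computed once per
# test session (several acceptance checks share it)
.fixtures <- new.env(parent = emptyenv())

defaultRun <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- suppressMessages(
      runPipeline(runConfig(generator = generatorConfig())))
  }
  .fixtures$run
}
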