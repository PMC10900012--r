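#' Two-group comparison (Welch's t or Mann-Whitney U)
#'
#' Two-sided comparison of a numeric outcome between two groups, by
#' Welch's unequal-variance t-test or the Mann-Whitney (Wilcoxon rank-sum)
#' test. The Mann-Whitney p-value is exact for combined n <= 20 without
#' ties, and uses the normal approximation with tie/continuity correction
#' otherwise.
#'
#' @param values numeric vector.
#' @param groups factor/vector with exactly two levels, aligned with
#'   \code{values}.
#' @param method \code{"welch"} or \code{"mann_whitney"}.
#' @return list with \code{statistic}, \code{p_value}, \code{method},
#'   \code{n} (per-group sizes) and per-group means.
#' @examples
#' compareGroups(c(0, 0, 0, 10, 10, 10), rep(c("a", "b"), each = 3),
#'               method = "mann_whitney")
#' @export
compareGroups <- function(values, groups, method = c("welch", "mann_whitney")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  split_ <- split(values, groups)
  if (any(vapply(split_, length, 1L) < 2))
    stop("need at least 2 observations per group")
  if (method == "welch") {
    ht <- stats::t.test(split_[[1]], split_[[2]], var.equal = FALSE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else if (length(values) <= 20) {
    # exact permutation distribution of the rank sum; handles ties by
    # enumerating all group assignments with midranks
    ex <- .mwExact(split_[[1]], split_[[2]])
    stat <- ex$U
    p <- ex$p
  } else {
    ht <- suppressWarnings(stats::wilcox.test(
      split_[[1]], split_[[2]], exact = FALSE, correct = TRUE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(statistic = stat, p_value = p, method = method,
       n = vapply(split_, length, 1L),
       means = vapply(split_, mean, 1.0))
}

.mwExact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  w <- colSums(matrix(r[sets], nrow = n1))
  pLo <- mean(w <= wObs + 1e-9)
  pHi <- mean(w >= wObs - 1e-9)
  list(U = wObs - n1 * (n1 + 1) / 2, p = min(1, 2 * min(pLo, pHi)))
}

#' Correlation with significance test
#'
#' Pearson's or Spearman's rank correlation with a two-sided p-value. In
#' \code{"auto"} mode Pearson is used when both variables pass a
#' Shapiro-Wilk normality check at alpha = 0.05, Spearman otherwise.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @param method \code{"pearson"}, \code{"spearman"} or \code{"auto"}.
#' @return list with \code{r}, \code{p_value}, \code{method}, \code{n}.
#' @export
correlateVars <- function(x, y, method = c("pearson", "spearman", "auto")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  if (method == "auto") {
    normal <- stats::shapiro.test(x)$p.value > 0.05 &&
      stats::shapiro.test(y)$p.value > 0.05
    method <- if (normal) "pearson" else "spearman"
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ht$estimate), p_value = ht$p.value, method = method,
       n = length(x))
}

#' Durbin-Watson statistic
#'
#' \eqn{d = \sum_{t \ge 2} (e_t - e_{t-1})^2 / \sum_t e_t^2} on residuals
#' in the order given. Values near 2 indicate no first-order
#' autocorrelation; the statistic lies in [0, 4].
#'
#' @param residuals numeric residual vector, in subject/observation order.
#' @return the statistic (numeric scalar).
#' @examples
#' durbinWatson(c(1, -1, 1, -1))
#' @export
durbinWatson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Single (simple) linear regression with diagnostics
#'
#' Ordinary least squares of \code{y} on one predictor, reporting the
#' coefficient table, overall F and p, R-squared, and the Durbin-Watson
#' statistic on residuals in observation order.
#'
#' @param y response vector.
#' @param x single predictor vector.
#' @param names optional c(response, predictor) labels for the report.
#' @return list of class \code{regressionResult}.
#' @export
simpleRegression <- function(y, x, names = c("y", "x")) {
  if (length(y) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("rank error: constant predictor")
  df <- stats::setNames(data.frame(y, x), c(names[1], names[2]))
  fit <- stats::lm(stats::reformulate(names[2], names[1]), data = df)
  .regressionResult(fit, response = names[1], predictors = names[2],
                    vif = stats::setNames(NA_real_, names[2]))
}

#' Multiple linear regression with VIF and Durbin-Watson
#'
#' OLS with per-coefficient p-values, overall F/p/R-squared, variance
#' inflation factors computed from the definition (each predictor regressed
#' on the others, \eqn{VIF_j = 1/(1 - R^2_j)}), and the Durbin-Watson
#' statistic. Exactly collinear predictors are a rank error; a high
#' condition number triggers a warning.
#'
#' @param y response vector.
#' @param X numeric matrix or data.frame of predictors (full column rank,
#'   \code{n > ncol(X) + 1}).
#' @return list of class \code{regressionResult}.
#' @export
multipleRegression <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) <= ncol(X) + 1) stop("need n > predictors + 1")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1)
    stop("rank error: collinear predictor columns")
  if (kappa(cbind(1, scale(X)), exact = FALSE) > 1e8)
    warning("predictors are nearly collinear (high condition number)")
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1) return(1)
    r2j <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2j)
  }, 1.0)
  .regressionResult(fit, response = "y", predictors = colnames(X),
                    vif = stats::setNames(vif, colnames(X)))
}

.regressionResult <- function(fit, response, predictors, vif) {
  sm <- summary(fit)
  fstat <- sm$fstatistic
  out <- list(
    response = response,
    coefficients = stats::coef(sm),
    f_statistic = unname(fstat[1]),
    p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
    r_squared = sm$r.squared,
    durbin_watson = durbinWatson(stats::residuals(fit)),
    vif = vif,
    n = length(stats::residuals(fit))
  )
  class(out) <- "regressionResult"
  out
}

#' @export
print.regressionResult <- function(x, ...) {
  cat(sprintf("Regression on %s (n = %d): R^2 = %.3f, F = %.3f, p = %.4g\n",
              x$response, x$n, x$r_squared, x$f_statistic, x$p_value))
  print(round(x$coefficients, 4))
  cat(sprintf("Durbin-Watson d = %.3f", x$durbin_watson))
  if (!all(is.na(x$vif)))
    cat("; VIF:", paste(sprintf("%s = %.3f", names(x$vif), x$vif),
                        collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Assemble the per-subject cohort table
#'
#' Merges subject covariates with the derived CAR parameters, sleep
#' summary and activity summary into one row per subject; the input to the
#' cohort statistics layer.
#'
#' @param subjects covariate data.frame (one row per subject).
#' @param carRows data.frame of per-subject CAR rows (with
#'   \code{subject_id}).
#' @param sleepRows,activityRows per-subject sleep and activity summaries
#'   (with \code{subject_id}).
#' @return merged data.frame keyed by \code{subject_id}.
#' @export
buildCohortTable <- function(subjects, carRows, sleepRows, activityRows) {
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject_id")
  out <- merge(subjects, carRows, by = "subject_id")
  out <- merge(out, sleepRows, by = "subject_id")
  out <- merge(out, activityRows, by = "subject_id")
  out[order(out$subject_id), ]
}

.carOutcomes <- c("mesor", "maximum", "minimum", "range",
                  "max_phase_time", "min_phase_time",
                  "total_sleep_time_min", "sleep_efficiency_pct",
                  "waking_time_h", "bed_time_h")

.comparisonFactors <- c("sex", "diagnosis", "locomotive_independent",
                        "hypnotics", "psychotropics")

.correlationFactors <- c("age", "bmi", "mmse", "motor_fim",
                         "total_sleep_time_min", "sleep_efficiency_pct",
                         "waking_time_h", "bed_time_h",
                         "sb_min_per_day", "lipa_min_per_day",
                         "mvpa_min_per_day")

#' Cohort comparison and correlation grids
#'
#' Runs the full statistics grids on the merged cohort table: every
#' grouping factor (sex, diagnosis, locomotive independence, hypnotics,
#' psychotropics) against every CAR/sleep outcome with both Welch's t and
#' Mann-Whitney tests; and every continuous factor (age, BMI, MMSE, motor
#' FIM, sleep metrics, SB/LIPA/MVPA) against every outcome with both
#' Pearson and Spearman coefficients. Alpha is 0.05 two-sided and no
#' multiple-testing adjustment is applied (stated in the report header).
#' Degenerate cells (constant vectors, empty groups) are flagged, not
#' fatal.
#'
#' @param cohort data.frame from [buildCohortTable()].
#' @param outcomes outcome columns (defaults to the CAR and sleep set).
#' @return list of class \code{cohortReport} with data.frames
#'   \code{comparisons} and \code{correlations} plus a \code{header} note.
#' @export
cohortReport <- function(cohort, outcomes = .carOutcomes) {
  outcomes <- intersect(outcomes, names(cohort))
  factors <- intersect(.comparisonFactors, names(cohort))
  missing <- setdiff(.carOutcomes, names(cohort))
  if (length(missing))
    stop("schema error: cohort table lacks columns: ",
         paste(missing, collapse = ", "))
  comp <- list()
  for (f in factors) for (o in outcomes) {
    g <- factor(cohort[[f]])
    v <- cohort[[o]]
    row <- data.frame(factor = f, outcome = o, welch_p = NA_real_,
                      mann_whitney_p = NA_real_,
                      mean_group1 = NA_real_, mean_group2 = NA_real_,
                      note = "")
    res <- tryCatch({
      w <- compareGroups(v, g, "welch")
      m <- compareGroups(v, g, "mann_whitney")
      row$welch_p <- w$p_value
      row$mann_whitney_p <- m$p_value
      row$mean_group1 <- w$means[1]
      row$mean_group2 <- w$means[2]
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
    comp[[length(comp) + 1]] <- res
  }
  corr <- list()
  cfac <- intersect(.correlationFactors, names(cohort))
  for (f in cfac) for (o in setdiff(outcomes, f)) {
    row <- data.frame(factor = f, outcome = o, pearson_r = NA_real_,
                      pearson_p = NA_real_, spearman_r = NA_real_,
                      spearman_p = NA_real_, note = "")
    res <- tryCatch({
      p <- correlateVars(cohort[[f]], cohort[[o]], "pearson")
      s <- correlateVars(cohort[[f]], cohort[[o]], "spearman")
      row$pearson_r <- p$r; row$pearson_p <- p$p_value
      row$spearman_r <- s$r; row$spearman_p <- s$p_value
      row
    }, error = function(e) { row$note <- conditionMessage(e); row })
    corr[[length(corr) + 1]] <- res
  }
  out <- list(
    header = paste("Two-sided alpha = 0.05;",
                   "no multiple-testing correction applied."),
    comparisons = do.call(rbind, comp),
    correlations = do.call(rbind, corr)
  )
  class(out) <- "cohortReport"
  out
}

#' @export
print.cohortReport <- function(x, ...) {
  cat("Cohort report.", x$header, "\n")
  cat(sprintf("  %d comparison cells, %d correlation cells\n",
              nrow(x$comparisons), nrow(x$correlations)))
  invisible(x)
}

#' Write a cohort report bundle to disk
#'
#' Tables as TSV plus a machine-readable JSON with every statistic.
#'
#' @param report a \code{cohortReport}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$comparisons, file.path(dir, "comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$correlations, file.path(dir, "correlations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
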