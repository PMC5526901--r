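## Evaluation statistics: inter-laboratory coefficient of variation, the
## asymptotic CV-equality test, paired t and Pearson comparisons, and
## limit-of-detection reporting over spike-in dilution series.

#' Coefficient of variation, in percent
#'
#' `CV = SD / mean * 100` with the sample standard deviation
#' (n - 1 denominator).
#'
#' @param values numeric vector of length >= 2 with non-zero mean.
#' @return CV in percent.
#' @examples
#' cv(c(2, 4))  # 47.14
#' @export
cv <- function(values) {
  if (length(values) < 2)
    stop("CV requires at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV is undefined for zero mean", call. = FALSE)
  sd(values) / m * 100
}

#' Asymptotic test for equality of coefficients of variation
#'
#' The Feltz-Miller asymptotic chi-square test for equal CVs across k
#' groups: with `m_i = n_i - 1` and group CVs `c_i` (as fractions), the
#' pooled CV is `c = sum(m_i c_i) / sum(m_i)` and the statistic
#' `D = sum(m_i (c_i - c)^2) / (c^2 (0.5 + c^2))` is asymptotically
#' chi-square with `k - 1` degrees of freedom under the null.
#'
#' @param groups list of at least two numeric vectors, each of length two
#'   or more and with non-zero mean.
#' @return `list(statistic, df, p.value)`.
#' @references Feltz CJ, Miller GE (1996). An asymptotic test for the
#'   equality of coefficients of variation from k populations.
#'   *Statistics in Medicine* 15(6):647-658.
#' @export
cvEqualityTest <- function(groups) {
  if (length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2))
    stop("every group needs at least two values", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  if (any(means == 0))
    stop("CV is undefined for a group with zero mean", call. = FALSE)
  m <- n - 1
  ci <- vapply(groups, function(g) sd(g) / mean(g), numeric(1))
  cpool <- sum(m * ci) / sum(m)
  D <- sum(m * (ci - cpool)^2) / (cpool^2 * (0.5 + cpool^2))
  df <- length(groups) - 1
  list(statistic = D, df = df,
       p.value = pchisq(D, df, lower.tail = FALSE))
}

#' Paired t-test between two analysis methods
#'
#' Two-sided paired t-test on the per-sample differences, optionally after
#' a log10 transform of both vectors (the sensitivity analysis used when
#' frequency data are right-skewed).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param log10 transform both sides by `log10` first (requires positive
#'   values).
#' @return `list(statistic, df, p.value)`.
#' @export
pairedTTest <- function(x, y, log10 = FALSE) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (log10) {
    if (any(x <= 0) || any(y <= 0))
      stop("log10 transform requires positive values", call. = FALSE)
    x <- log10(x); y <- log10(y)
  }
  if (all(x == y))  # identical methods: no evidence of a difference
    return(list(statistic = 0, df = length(x) - 1, p.value = 1))
  ht <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @param log10 transform both sides by `log10` first (requires positive
#'   values).
#' @return `list(r, r.squared, p.value)` with the two-sided p-value.
#' @export
pearsonR2 <- function(x, y, log10 = FALSE) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3)
    stop("need at least three pairs", call. = FALSE)
  if (log10) {
    if (any(x <= 0) || any(y <= 0))
      stop("log10 transform requires positive values", call. = FALSE)
    x <- log10(x); y <- log10(y)
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop("Pearson correlation is undefined for zero variance",
         call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  list(r = r, r.squared = r^2, p.value = ht$p.value)
}

#' Limit-of-detection report over a dilution series
#'
#' Tabulates theoretical versus estimated multimer+ frequencies and
#' detection flags per dilution step (rows ordered by decreasing
#' theoretical frequency, duplicates kept as separate columns of the same
#' row group), and summarizes the lowest reliably detected frequency: the
#' smallest theoretical percentage at which every duplicate was detected.
#' The conventional 10-event detection threshold corresponds to 0.001% at
#' one million lymphocytes, and that reference line value is recorded in
#' the report.
#'
#' @param series `data.frame` with columns `theoretical` (percent),
#'   `estimated` (percent), `detected` (logical) and optionally
#'   `duplicate`.
#' @return A `LoDReport`: `list(table, lowestDetected,
#'   thresholdPercent = 0.001)`; `lowestDetected` is `NA` when no step is
#'   detected in all duplicates.
#' @export
lodReport <- function(series) {
  stopifnot(nrow(series) >= 1,
            all(c("theoretical", "estimated", "detected") %in%
                  names(series)))
  if (is.null(series$duplicate)) series$duplicate <- 1L
  tab <- series[order(-series$theoretical, series$duplicate), ,
                drop = FALSE]
  rownames(tab) <- NULL
  byStep <- split(tab$detected, tab$theoretical)
  fullDet <- vapply(byStep, all, logical(1))
  thr <- as.numeric(names(byStep))
  ok <- fullDet & thr > 0
  lowest <- if (any(ok)) min(thr[ok]) else NA_real_
  structure(list(table = tab, lowestDetected = lowest,
                 thresholdPercent = 0.001),
            class = "LoDReport")
}

#' @export
print.LoDReport <- function(x, ...) {
  cat("Limit-of-detection report\n")
  print(x$table, digits = 4)
  cat(sprintf("lowest reliably detected frequency: %s%%\n",
              format(x$lowestDetected)))
  cat(sprintf("conventional detection threshold: %g%%\n",
              x$thresholdPercent))
  invisible(x)
}
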