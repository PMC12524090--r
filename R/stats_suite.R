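# Statistical comparison suite for paired classifier evaluations:
# paired t-test, binomial proportion confidence interval, Cohen's d,
# McNemar's test with continuity correction, Cohen's kappa, and the
# percentile bootstrap of an accuracy.

#' Paired one-tailed t-test on accuracy columns
#'
#' Tests whether the second condition (e.g. semi-supervised) outperforms
#' the first (e.g. supervised) across paired evaluation splits:
#' `t = dbar / (s_d / sqrt(n))` with `dbar = mean(b - a)`, `s_d` the sample
#' standard deviation (n - 1) of the differences, df = n - 1 and a
#' one-tailed p-value. With zero variance and a nonzero mean difference the
#' p-value is reported as the boundary value (0 or 1) with a warning.
#'
#' @param a,b aligned numeric accuracy vectors (percent scale), length >= 2.
#' @return list of class `pairedTTest`: `meanDiff`, `sdDiff`, `t`, `df`,
#'   `pValue`, `n`.
#' @export
#' @examples
#' pairedTTest(c(1, 2, 3), c(2, 2, 5))
pairedTTest <- function(a, b) {
  stopIfNot(length(a) == length(b), "paired vectors must align")
  n <- length(a)
  stopIfNot(n >= 2, "need at least 2 pairs")
  d <- b - a
  dbar <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    warning("zero variance of the paired differences; p at boundary",
            call. = FALSE)
    t <- if (dbar == 0) 0 else sign(dbar) * Inf
    p <- if (dbar > 0) 0 else if (dbar < 0) 1 else 0.5
  } else {
    t <- dbar / (sd_d / sqrt(n))
    p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  }
  structure(list(meanDiff = dbar, sdDiff = sd_d, t = t, df = n - 1,
                 pValue = p, n = n),
            class = "pairedTTest")
}

#' @export
print.pairedTTest <- function(x, ...) {
  cat(sprintf("Paired t-test (one-tailed): dbar = %.4f, s_d = %.4f, t(%d) = %.3f, p = %.4g\n",
              x$meanDiff, x$sdDiff, x$df, x$t, x$pValue))
  invisible(x)
}

#' Mean and standard deviation of an accuracy column
#'
#' Descriptive Mean ± SD summary; `population = TRUE` (the default) uses
#' the population convention (divide by n), which is the convention that
#' reproduces the printed summaries of typical accuracy tables, while
#' `population = FALSE` gives the sample SD (n - 1).
#'
#' @param x numeric vector.
#' @param population divide by n (TRUE) or n - 1 (FALSE)?
#' @return named vector `c(mean, sd)`.
#' @export
accuracySummary <- function(x, population = TRUE) {
  m <- mean(x)
  s <- if (population) sqrt(mean((x - m)^2)) else stats::sd(x)
  c(mean = m, sd = s)
}

#' Binomial proportion confidence interval for an accuracy
#'
#' Normal-approximation interval `p ± z * sqrt(p (1 - p) / n)`. The
#' standard error is reported on the proportion scale, the bounds on the
#' percent scale and deliberately *not* clipped to `[0, 100]`, preserving
#' the plain arithmetic of the formula.
#'
#' @param p accuracy proportion in `[0, 1]`.
#' @param n test sample size.
#' @param z critical value (default 1.96 for a 95% interval).
#' @return list of class `proportionCI`: `p`, `n`, `z`, `se`, `lower`,
#'   `upper` (bounds in percent).
#' @export
#' @examples
#' binomialCI(0.9839, 1311)
binomialCI <- function(p, n, z = 1.96) {
  stopIfNot(p >= 0 && p <= 1, "p must lie in [0, 1]")
  stopIfNot(n >= 1, "n must be >= 1")
  se <- sqrt(p * (1 - p) / n)
  structure(list(p = p, n = as.integer(n), z = z, se = se,
                 lower = (p - z * se) * 100, upper = (p + z * se) * 100),
            class = "proportionCI")
}

#' @export
print.proportionCI <- function(x, ...) {
  cat(sprintf("%.2f%% [%.2f, %.2f]  (SE %.5f, n = %d, z = %.2f)\n",
              x$p * 100, x$lower, x$upper, x$se, x$n, x$z))
  invisible(x)
}

#' Cohen's d effect size from group summaries
#'
#' `d = (mean2 - mean1) / S_pooled` with the pooled standard deviation
#' `S_pooled = sqrt(((n2 - 1) s2^2 + (n1 - 1) s1^2) / (n1 + n2 - 2))`,
#' which reduces to `sqrt((s1^2 + s2^2) / 2)` at equal group sizes. Group 2
#' is the condition of interest (e.g. semi-supervised), group 1 the
#' baseline.
#'
#' @param mean2,sd2,n2 summary of the condition of interest.
#' @param mean1,sd1,n1 summary of the baseline.
#' @return list of class `effectSize`: means, SDs, `pooledSD`, `d`.
#' @export
#' @examples
#' cohensD(86.04, 1.58, 5, 84.74, 1.42, 5)  # d ~ 0.87
cohensD <- function(mean2, sd2, n2, mean1, sd1, n1) {
  stopIfNot(sd1 >= 0 && sd2 >= 0, "SDs must be non-negative")
  stopIfNot(n1 >= 2 && n2 >= 2, "group sizes must be >= 2")
  pooled <- sqrt(((n2 - 1) * sd2^2 + (n1 - 1) * sd1^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled SD is zero; d undefined", call. = FALSE)
  structure(list(mean2 = mean2, sd2 = sd2, n2 = n2,
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 pooledSD = pooled, d = (mean2 - mean1) / pooled),
            class = "effectSize")
}

#' @export
print.effectSize <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f  (pooled SD %.3f)\n", x$d, x$pooledSD))
  invisible(x)
}

#' Paired 2x2 contingency table of two classifiers
#'
#' Counts over the same test set: `a` both correct, `b` baseline wrong /
#' model correct, `c` baseline correct / model wrong, `d` both wrong.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return list of class `contingency2x2` with the counts and `n`.
#' @export
contingencyTable2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopIfNot(all(counts >= 0) && all(counts == floor(counts)),
            "counts must be non-negative integers")
  structure(as.list(counts), n = sum(counts), class = "contingency2x2")
}

#' McNemar's test with continuity correction
#'
#' `chi2 = (max(|b - c| - 1, 0))^2 / (b + c)` (Yates continuity
#' correction; the clamp at 0 avoids a positive statistic when `b = c`),
#' with a two-sided p-value from the chi-squared distribution with 1 df.
#' Only the discordant counts enter the statistic.
#'
#' @param table a [contingencyTable2x2()], or `NULL` when giving `b`/`c`
#'   directly.
#' @param b,c discordant counts (overridden by `table` if supplied).
#' @return list of class `mcnemarResult`: `chi2`, `pValue`, `b`, `c`.
#' @export
#' @examples
#' mcnemarTest(b = 30, c = 15)  # chi2 ~ 4.36
mcnemarTest <- function(table = NULL, b = NULL, c = NULL) {
  if (!is.null(table)) {
    stopIfNot(inherits(table, "contingency2x2"), "need a contingency2x2")
    b <- table$b; c <- table$c
  }
  stopIfNot(!is.null(b) && !is.null(c), "need discordant counts b and c")
  if (b + c == 0) stop("no discordant pairs (b + c = 0)", call. = FALSE)
  chi2 <- max(abs(b - c) - 1, 0)^2 / (b + c)
  structure(list(chi2 = chi2,
                 pValue = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 b = b, c = c),
            class = "mcnemarResult")
}

#' @export
print.mcnemarResult <- function(x, ...) {
  cat(sprintf("McNemar chi2 = %.3f (b = %d, c = %d), p = %.4g\n",
              x$chi2, x$b, x$c, x$pValue))
  invisible(x)
}

#' Cohen's kappa from a paired 2x2 table
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with the
#' observed agreement `p_o = (a + d) / n` and the expected agreement `p_e`
#' from the row/column marginals. When `p_e = 1` kappa is undefined and
#' reported as `NA`.
#'
#' @param table a [contingencyTable2x2()].
#' @return list of class `kappaResult`: `kappa`, `observedAgreement`,
#'   `expectedAgreement`, `n`.
#' @export
cohensKappa <- function(table) {
  stopIfNot(inherits(table, "contingency2x2"), "need a contingency2x2")
  n <- attr(table, "n")
  stopIfNot(n > 0, "empty table")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, observedAgreement = po,
                 expectedAgreement = pe, n = n),
            class = "kappaResult")
}

#' Percentile bootstrap of a classification accuracy
#'
#' Resamples the per-sample correctness flags with replacement (to the
#' original size) `nResamples` times, computing the accuracy of each
#' resample. Reports the median, the 2.5/97.5 percentile interval and the
#' bootstrap standard error with the `1/(B - 1)` variance convention; all
#' on the percent scale. Deterministic per seed.
#'
#' @param correctFlags logical/0-1 vector: was each test sample classified
#'   correctly?
#' @param nResamples number of bootstrap resamples B (default 1000).
#' @param seed integer seed.
#' @param probs percentile bounds (default `c(0.025, 0.975)`).
#' @return list of class `bootstrapResult`: `median`, `lower`, `upper`,
#'   `se`, `mean`, `nResamples`, `n`.
#' @export
bootstrapAccuracy <- function(correctFlags, nResamples = 1000L, seed = 1L,
                              probs = c(0.025, 0.975)) {
  flags <- as.numeric(correctFlags)
  n <- length(flags)
  stopIfNot(n >= 1, "need a non-empty vector")
  acc <- withSeed(seed, {
    vapply(seq_len(nResamples),
           function(i) mean(flags[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  }) * 100
  q <- stats::quantile(acc, probs = probs, names = FALSE, type = 7)
  structure(list(median = stats::median(acc), lower = q[1], upper = q[2],
                 se = sqrt(sum((acc - mean(acc))^2) / (nResamples - 1)),
                 mean = mean(acc), nResamples = as.integer(nResamples),
                 n = n),
            class = "bootstrapResult")
}

#' @export
print.bootstrapResult <- function(x, ...) {
  cat(sprintf("Bootstrap accuracy: median %.2f%% [%.2f, %.2f], SE %.3f (B = %d)\n",
              x$median, x$lower, x$upper, x$se, x$nResamples))
  invisible(x)
}
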