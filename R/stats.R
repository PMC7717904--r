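# Cohort-level statistics: mean +/- s.e.m., the two-tailed Student t-test
# and percent-of-control expression ratios.

#' Summarize a vector of densities as n, mean and s.e.m.
#'
#' Uses the unbiased sample standard deviation (n - 1 denominator);
#' \code{sem = sd / sqrt(n)}.
#'
#' @param values numeric vector, length >= 2.
#' @return list with \code{n}, \code{mean}, \code{sem}.
#' @export
summarizeDensities <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to form a s.e.m.")
  list(n = length(values), mean = mean(values),
       sem = stats::sd(values) / sqrt(length(values)))
}

#' Two-sample two-tailed Student t-test
#'
#' Pooled-variance Student test with \code{df = n_a + n_b - 2} (the
#' classical test; Welch's unequal-variance form available via
#' \code{welch = TRUE}). Degenerate zero-variance inputs are handled
#' explicitly: equal constant groups give \code{t = 0, p = 1}; unequal
#' constant groups give \code{p = 0} flagged degenerate.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   Student form.
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
groupTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Percent-of-control expression ratio
#'
#' \code{100 * mean(test) / mean(control)}, computed from group means (not
#' the mean of per-pair ratios).
#'
#' @param test densities of the test genotype.
#' @param control densities of the littermate controls.
#' @return percentage (numeric scalar).
#' @export
expressionRatio <- function(test, control) {
  mc <- mean(control)
  if (mc == 0) stop("control mean is zero")
  if (mc < 0) stop("control mean must be positive")
  100 * mean(test) / mc
}

#' Compare two genotype groups of densities
#'
#' Bundles \code{\link{summarizeDensities}}, \code{\link{groupTTest}} and
#' \code{\link{expressionRatio}} into one cohort comparison.
#'
#' @param test,control density vectors.
#' @param welch use Welch's test.
#' @return list with \code{test}, \code{control} summaries, \code{t_test}
#'   and \code{percent_of_control}.
#' @export
compareGroups <- function(test, control, welch = FALSE) {
  list(test = summarizeDensities(test),
       control = summarizeDensities(control),
       t_test = groupTTest(test, control, welch = welch),
       percent_of_control = expressionRatio(test, control))
}
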