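# Probe-wise equal-variance tests and FDR adjustment: the comparison
# baselines and the probe-wise DV detector.

new_test_result <- function(statistic, p_value, direction) {
  structure(
    list(statistic = statistic, p_value = p_value, p_adjusted = NA_real_,
         direction = direction),
    class = "TestResult"
  )
}

#' Two-sided F test for equal variances
#'
#' Tests whether the ratio of sample variances \eqn{s_c^2 / s_n^2} differs
#' from one; the two-sided p value is twice the smaller tail of the
#' \eqn{F_{m_c - 1, m_n - 1}} distribution, capped at 1.
#'
#' @param case_values,control_values Numeric vectors, each with at least 2
#'   values.
#'
#' @return A `TestResult` list: `statistic` (\eqn{s_c^2/s_n^2}), `p_value`,
#'   `p_adjusted` (NA until [bh_adjust()]), `direction`
#'   (sign of \eqn{s_c^2 - s_n^2}).
#' @export
f_test <- function(case_values, control_values) {
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("each group needs at least 2 values")
  s2c <- stats::var(case_values)
  s2n <- stats::var(control_values)
  if (s2c == 0 || s2n == 0) {
    warning("zero variance in a group; F test undefined")
    return(new_test_result(NaN, NaN, sign(s2c - s2n)))
  }
  ft <- stats::var.test(case_values, control_values)
  new_test_result(unname(ft$statistic), ft$p.value, sign(s2c - s2n))
}

trimmed_mean <- function(x) mean(x, trim = 0.1)

#' Levene-family tests for equal variances
#'
#' Classic one-way ANOVA F statistic on the absolute deviations
#' \eqn{|x - \mathrm{center}(\mathrm{group})|}: Levene's test centers at the
#' group mean, Brown-Forsythe at the group median, and the trimmed variant
#' at the 10\% symmetrically trimmed group mean. The p value comes from
#' \eqn{F_{1, m - 2}}.
#'
#' @param case_values,control_values Numeric vectors, each with at least 3
#'   values.
#' @param center `"mean"`, `"median"`, or `"trimmed_mean"`.
#'
#' @return A `TestResult` list (see [f_test()]).
#' @export
levene_family_test <- function(case_values, control_values,
                               center = c("mean", "median", "trimmed_mean")) {
  center <- match.arg(center)
  if (length(case_values) < 3L || length(control_values) < 3L)
    stop("each group needs at least 3 values")
  cf <- switch(center, mean = mean, median = stats::median,
               trimmed_mean = trimmed_mean)
  zc <- abs(case_values - cf(case_values))
  zn <- abs(control_values - cf(control_values))
  dir <- sign(stats::var(case_values) - stats::var(control_values))
  m <- length(zc) + length(zn)
  zb <- c(mean(zc), mean(zn))
  zbar <- (length(zc) * zb[1] + length(zn) * zb[2]) / m
  ssb <- length(zc) * (zb[1] - zbar)^2 + length(zn) * (zb[2] - zbar)^2
  ssw <- sum((zc - zb[1])^2) + sum((zn - zb[2])^2)
  if (ssw == 0) {
    if (ssb == 0) {
      # identical deviation patterns: no evidence against equal spread
      return(new_test_result(0, 1, dir))
    }
    warning("constant absolute deviations within groups; test undefined")
    return(new_test_result(NaN, NaN, dir))
  }
  stat <- ssb / (ssw / (m - 2))
  new_test_result(stat, stats::pf(stat, 1, m - 2, lower.tail = FALSE), dir)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement; NaN/NA entries
#' are excluded from the adjustment and restored in place.
#'
#' @param p_values Numeric vector of p values in `[0, 1]` (NA/NaN allowed).
#'
#' @return Adjusted p values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p values must lie in [0, 1]")
  out <- rep(NaN, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

PROBEWISE_TESTS <- c("F", "levene", "bf", "ltrim")

run_probewise_test <- function(test, xc, xn) {
  switch(test,
         F = f_test(xc, xn),
         levene = levene_family_test(xc, xn, "mean"),
         bf = levene_family_test(xc, xn, "median"),
         ltrim = levene_family_test(xc, xn, "trimmed_mean"))
}

#' Probe-wise differential-variability detection
#'
#' Runs the chosen equal-variance test for every probe, adjusts p values by
#' Benjamini-Hochberg, and flags probes with adjusted p below `alpha` as DV.
#' Flagged probes are labeled OV when \eqn{s_c^2 > s_n^2} and UV when
#' \eqn{s_c^2 < s_n^2}; everything else is EV.
#'
#' @param data An [expression_dataset()].
#' @param test `"F"`, `"levene"` (mean center), `"bf"` (median center,
#'   Brown-Forsythe), or `"ltrim"` (10\% trimmed mean center).
#' @param alpha FDR threshold (default 0.05).
#'
#' @return A `dv_calls` data frame with columns `probe_id`, `label`, `dv`,
#'   `direction`, `statistic`, `p_value`, `p_adjusted`; probes whose test is
#'   undefined get NaN p values and are never flagged.
#' @export
probewise_detect <- function(data, test = PROBEWISE_TESTS, alpha = 0.05) {
  test <- match.arg(test)
  idx <- group_index(data)
  res <- apply(data$values, 1, function(row) {
    r <- suppressWarnings(run_probewise_test(test, row[idx$case],
                                             row[idx$control]))
    c(r$statistic, r$p_value, r$direction)
  })
  stat <- res[1, ]; p <- res[2, ]; dir <- res[3, ]
  padj <- bh_adjust(p)
  dv <- !is.na(padj) & padj < alpha
  label <- ifelse(dv & dir > 0, "OV", ifelse(dv & dir < 0, "UV", "EV"))
  out <- data.frame(
    probe_id = data$probe_ids,
    label = factor(label, levels = CLUSTER_KINDS),
    dv = dv & dir != 0,
    direction = dir,
    statistic = stat, p_value = p, p_adjusted = padj,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$dv <- out$label != "EV"
  class(out) <- c("dv_calls", "data.frame")
  attr(out, "method") <- test
  attr(out, "alpha") <- alpha
  out
}
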