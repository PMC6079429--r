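# Agreement and error metrics between true and detected cluster
# memberships, plus paired method comparison.

#' Pair-counting Jaccard index between two partitions
#'
#' Over all probe pairs, counts pairs co-clustered in both partitions
#' (n11), co-clustered only in the first (n10), and only in the second
#' (n01), and returns `n11 / (n11 + n10 + n01)`. Identical partitions give
#' 1; partitions sharing no co-clustered pair give 0. The index is
#' invariant to relabeling cluster names within either partition. Computed
#' from the contingency table, so it scales to many probes.
#'
#' @param true_labels,pred_labels Vectors of equal length (>= 2) of cluster
#'   labels.
#'
#' @return The Jaccard index in `[0, 1]`.
#' @examples
#' jaccard_index(c("A", "A", "B", "B"), c("A", "A", "A", "B"))  # 1/4
#' @export
jaccard_index <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  if (length(true_labels) < 2L)
    stop("need at least 2 probes")
  tab <- table(as.character(true_labels), as.character(pred_labels))
  choose2 <- function(n) n * (n - 1) / 2
  n11 <- sum(choose2(tab))
  n10 <- sum(choose2(rowSums(tab))) - n11
  n01 <- sum(choose2(colSums(tab))) - n11
  denom <- n11 + n10 + n01
  if (denom == 0) return(0)
  n11 / denom
}

as_dv_logical <- function(labels) {
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), CLUSTER_KINDS)
  if (length(bad))
    stop("labels must be OV/EV/UV; got ", paste(bad, collapse = ", "))
  lab != "EV"
}

#' False positive rate of DV detection
#'
#' The proportion of detected DV probes (OV or UV) among the true non-DV
#' (EV) probes.
#'
#' @param true_labels,pred_labels OV/EV/UV label vectors of equal length.
#'
#' @return FPR in `[0, 1]`, or NaN (with a warning) when there are no true
#'   EV probes.
#' @export
fpr <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  td <- as_dv_logical(true_labels)
  pd <- as_dv_logical(pred_labels)
  if (!any(!td)) {
    warning("no true non-DV probes; FPR undefined")
    return(NaN)
  }
  sum(pd & !td) / sum(!td)
}

#' False negative rate of DV detection
#'
#' The proportion of detected non-DV (EV) probes among the true DV (OV or
#' UV) probes.
#'
#' @inheritParams fpr
#'
#' @return FNR in `[0, 1]`, or NaN (with a warning) when there are no true
#'   DV probes.
#' @export
fnr <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  td <- as_dv_logical(true_labels)
  pd <- as_dv_logical(pred_labels)
  if (!any(td)) {
    warning("no true DV probes; FNR undefined")
    return(NaN)
  }
  sum(!pd & td) / sum(td)
}

#' Two-sided Wilcoxon signed rank test for paired measures
#'
#' Compares paired per-replicate measures (e.g., bootstrap validation rates
#' of two methods). Zero differences are dropped; the null distribution is
#' exact for 25 or fewer non-zero untied differences and a normal
#' approximation with continuity correction otherwise.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#'
#' @return The two-sided p value.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero")
    return(1)
  }
  ties <- anyDuplicated(abs(nz)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    nz, alternative = "two.sided",
    exact = length(nz) <= 25L && !ties, correct = TRUE
  ))
  wt$p.value
}

#' Evaluate detected memberships against simulation truth
#'
#' Convenience wrapper computing the pair-counting Jaccard index, FPR, and
#' FNR for one detection result.
#'
#' @param truth A `SimulationTruth` (from [simulate_dataset()]) or an
#'   OV/EV/UV label vector.
#' @param calls A `dv_calls` data frame or an OV/EV/UV label vector.
#'
#' @return A list with `jaccard`, `fpr`, `fnr`.
#' @export
evaluate_calls <- function(truth, calls) {
  tl <- if (inherits(truth, "SimulationTruth")) truth$labels else truth
  pl <- if (inherits(calls, "dv_calls")) calls$label else calls
  list(jaccard = jaccard_index(tl, pl), fpr = fpr(tl, pl), fnr = fnr(tl, pl))
}
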