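# Significance tests used to compare models and segmentation sources.

#' Two-sided paired t-test on per-subject scores
#'
#' Standard paired t statistic on the differences with n - 1 degrees of
#' freedom (delegated to \code{stats::t.test}). Degenerate cases follow a
#' fixed convention: all differences exactly zero gives t = 0, p = 1; a
#' nonzero constant difference (zero s.d.) gives an infinite t and
#' p = \code{.Machine$double.xmin} rather than an exact zero.
#'
#' @param a,b Equal-length (>= 2) numeric vectors paired by subject.
#' @return List with \code{t}, \code{p}, \code{df} and \code{meanDiff}.
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      message("pairedTTest: all differences zero; p = 1 by convention")
      return(list(t = 0, p = 1, df = length(d) - 1L, meanDiff = 0))
    }
    message("pairedTTest: constant nonzero differences; p set to machine minimum")
    return(list(t = sign(d[1L]) * Inf, p = .Machine$double.xmin,
                df = length(d) - 1L, meanDiff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), meanDiff = mean(d))
}

#' Paired Wilcoxon signed-rank comparison of two p-value profiles
#'
#' Compares region-wise p-values obtained from two segmentation sources
#' (e.g. reference vs model labels). Zero differences are dropped (the
#' classic signed-rank policy); the exact distribution is used for up to
#' 25 remaining pairs and the normal approximation with continuity
#' correction above that. All pairs tied gives p = 1 by convention.
#'
#' @param pA,pB Equal-length numeric vectors paired by region.
#' @return List with \code{p} (two-sided), \code{statistic} (V), and
#'   \code{nUsed} (pairs after dropping ties).
#' @export
compareSources <- function(pA, pB) {
  stopifnot(length(pA) == length(pB))
  keep <- (pA - pB) != 0
  n <- sum(keep)
  if (n == 0L) {
    message("compareSources: all pairs tied; p = 1 by convention")
    return(list(p = 1, statistic = NA_real_, nUsed = 0L))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(pA[keep], pB[keep], paired = TRUE,
                       exact = n <= 25L, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic), nUsed = n)
}
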