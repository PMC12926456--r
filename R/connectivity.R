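# Synthetic conductance connectivity: region-block structure on the
# fsaverage3 (642-vertex) column grid.

# Symmetric nonnegative K x K region template with within-region strength
# strictly above all between-region strengths.
.connTemplate <- function(K, params, seed) {
  set.seed(seed)
  tpl <- matrix(stats::runif(K * K, 0, params$connBetween), K, K)
  tpl <- (tpl + t(tpl)) / 2
  diag(tpl) <- params$connWithin +
    stats::runif(K, 0, 0.25 * params$connWithin)
  tpl
}

#' Generate a synthetic conductance connectivity map
#'
#' Emulates the output of a conductance-based structural-connectivity
#' model: each vertex carries a length-642 vector of nonnegative
#' conductances to the fsaverage3 grid. Entry (v, j) is the region-template
#' value for the pair (label(v), label(j)) plus Gaussian noise, clipped at
#' zero; within-region conductance exceeds between-region conductance,
#' giving rows the block structure that makes connectivity informative for
#' parcellation.
#'
#' @param labels Integer parcel labels (1..K) for the subject's mesh rows.
#' @param params A \code{\link{cohortParams}} list.
#' @param seed Subject-level RNG seed.
#' @param template Optional precomputed K x K region template (drawn once
#'   per cohort by the generator); derived from \code{params$seed} when
#'   absent.
#' @param lowresLabels Labels of the 642 fsaverage3 column vertices
#'   (defaults to \code{labels} when the mesh itself is the s = 3
#'   icosphere).
#' @return Numeric matrix, \code{length(labels)} x \code{length(lowresLabels)},
#'   all entries >= 0.
#' @export
synthConnectivity <- function(labels, params, seed, template = NULL,
                              lowresLabels = labels) {
  K <- max(labels, max(lowresLabels))
  if (is.null(template))
    template <- .connTemplate(K, params, deriveSeed(params$seed, 0L, 98L))
  M <- template[labels, lowresLabels, drop = FALSE]
  if (params$connNoiseSd > 0) {
    set.seed(seed)
    M <- M + stats::rnorm(length(M), 0, params$connNoiseSd)
  }
  M[M < 0] <- 0
  unname(M)
}
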