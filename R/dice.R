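# Multi-class (macro) Dice evaluation.

#' Multi-class Dice score of a predicted parcellation
#'
#' Per region r, \code{Dice_r = 2 |P_r n T_r| / (|P_r| + |T_r|)}. Regions
#' absent from both the prediction and the truth are skipped; regions
#' present in exactly one get 0. The macro score is the unweighted mean
#' over the scored regions. A designated "unknown" label (e.g. the medial
#' wall) can be excluded from the macro average.
#'
#' @param pred,truth Equal-length integer label vectors.
#' @param K Optional number of classes; when supplied, labels outside
#'   1..K raise an error.
#' @param unknown Optional label value excluded from scoring.
#' @return List with \code{perRegion} (named numeric, one entry per scored
#'   region) and \code{macro}.
#' @examples
#' diceScore(c(0, 1, 1, 1), c(0, 0, 1, 1))$macro  # 11/15
#' @export
diceScore <- function(pred, truth, K = NULL, unknown = NULL) {
  if (length(pred) != length(truth))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(pred), length(truth)), call. = FALSE)
  regions <- sort(unique(c(pred, truth)))
  if (!is.null(K) && any(regions < 1L | regions > K))
    stop(sprintf("labels outside 1..%d found", K), call. = FALSE)
  if (!is.null(unknown)) regions <- setdiff(regions, unknown)
  per <- vapply(regions, function(r) {
    p <- pred == r; t <- truth == r
    2 * sum(p & t) / (sum(p) + sum(t))
  }, numeric(1L))
  names(per) <- as.character(regions)
  list(perRegion = per, macro = mean(per))
}

#' Per-subject macro Dice over a set of subjects
#'
#' @param predList,truthList Parallel lists of label vectors.
#' @param unknown Optional label excluded from scoring.
#' @return Numeric vector of per-subject macro Dice scores.
#' @export
macroDice <- function(predList, truthList, unknown = NULL) {
  mapply(function(p, t) diceScore(p, t, unknown = unknown)$macro,
         predList, truthList)
}
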