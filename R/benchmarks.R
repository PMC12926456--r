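# Reference benchmark values from the published multimodal GNN cortical
# segmentation study on the HCP young-adult "100 Unrelated Subjects"
# cohort. These printed results are inputs to context/arithmetic checks
# (cross-hemisphere summaries, parameter-count effects, RMSE margins);
# they are not reproduced by the synthetic pipeline, whose absolute scores
# depend on the synthetic cohort.

#' Published benchmark results for multimodal GNN cortical segmentation
#'
#' Returns the reference result tables of the published HCP benchmark:
#' \code{dice} -- average holdout Dice (mean, s.d.) per hemisphere,
#' feature set and architecture; \code{parameterStudy} -- GCN Dice as a
#' function of the trainable-parameter count for the fully structural
#' feature set (with the multimodal reference row); \code{agePrediction}
#' -- the age standard deviation and the best reported age-prediction
#' RMSE. Feature-set labels match \code{\link{featureSetLabel}}.
#'
#' @return A list with elements \code{dice}, \code{parameterStudy} and
#'   \code{agePrediction}.
#' @examples
#' b <- publishedBenchmarks()
#' subset(b$dice, featureSet == "coords+thickness+curvature+conductance")
#' @export
publishedBenchmarks <- function() {
  dice <- rbind(
    data.frame(hemisphere = "left", featureSet = c(
      "coords", "coords+thickness", "coords+curvature",
      "coords+thickness+curvature",
      "coords+thickness+curvature+conductance", "coords+conductance"),
      gcn = c(0.712, 0.743, 0.742, 0.761, 0.9104, 0.8930),
      gcnSd = c(0.009, 0.003, 0.003, 0.008, 0.0008, 0.0006),
      gat = c(0.707, 0.744, 0.745, 0.768, 0.927, 0.914),
      gatSd = c(0.017, 0.005, 0.007, 0.005, 0.003, 0.003),
      gunet = c(NA, NA, NA, 0.744, 0.882, NA),
      gunetSd = c(NA, NA, NA, 0.003, 0.003, NA)),
    data.frame(hemisphere = "right", featureSet = c(
      "coords", "coords+thickness", "coords+curvature",
      "coords+thickness+curvature",
      "coords+thickness+curvature+conductance", "coords+conductance"),
      gcn = c(0.708, 0.735, 0.725, 0.753, 0.900, 0.886),
      gcnSd = c(0.005, 0.004, 0.006, 0.007, 0.001, 0.002),
      gat = c(0.711, 0.728, 0.722, 0.760, 0.918, 0.904),
      gatSd = c(0.004, 0.008, 0.009, 0.003, 0.002, 0.002),
      gunet = c(NA, NA, NA, 0.734, 0.876, NA),
      gunetSd = c(NA, NA, NA, 0.004, 0.009, NA)))
  parameterStudy <- data.frame(
    featureSet = c(rep("coords+thickness+curvature", 3L),
                   "coords+thickness+curvature+conductance"),
    parameters = c(145001L, 285801L, 499201L, 473705L),
    dice = c(0.7410, 0.7633, 0.7630, 0.9104),
    sd = c(0.0013, 0.0031, 0.0017, 0.0008))
  agePrediction <- list(sdAge = 3.70, bestRmse = 3.44,
                        bestRegressor = "tree",
                        bestAttribute = "conductance")
  list(dice = dice, parameterStudy = parameterStudy,
       agePrediction = agePrediction)
}

#' Cross-hemisphere mean Dice of a benchmark cell
#'
#' Averages the left- and right-hemisphere mean Dice of one (feature set,
#' architecture) cell of \code{\link{publishedBenchmarks}}; e.g. the
#' multimodal GAT cell averages to 0.923 (3 d.p.).
#'
#' @param featureSet Feature-set label.
#' @param architecture "gcn", "gat" or "gunet".
#' @return The cross-hemisphere mean Dice.
#' @export
crossHemisphereMean <- function(featureSet, architecture = "gat") {
  d <- publishedBenchmarks()$dice
  vals <- d[d$featureSet == featureSet, architecture]
  if (!length(vals) || all(is.na(vals)))
    stop(sprintf("no benchmark cell for (%s, %s)", featureSet,
                 architecture), call. = FALSE)
  mean(vals)
}

#' Dice change when widening a model at fixed features
#'
#' From the parameter study of \code{\link{publishedBenchmarks}}: the
#' holdout Dice difference between the doubled-width and original GCN on
#' the fully structural feature set (0.7633 - 0.7410 = 0.0223).
#'
#' @return Named list with the two Dice values and \code{delta}.
#' @export
widthDoublingDelta <- function() {
  ps <- publishedBenchmarks()$parameterStudy
  structural <- ps[ps$featureSet == "coords+thickness+curvature", ]
  structural <- structural[order(structural$parameters), ]
  list(original = structural$dice[1L], doubled = structural$dice[2L],
       delta = structural$dice[2L] - structural$dice[1L])
}
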