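# Per-vertex feature assembly, cohort-level min-max normalization, and
# Gaussian noise augmentation.

#' Assemble the per-vertex feature matrix of a subject
#'
#' Columns are ordered coordinates (x, y, z), thickness, curvature, then
#' the 642 conductance columns; flags not set in the spec are omitted.
#'
#' @param subject A \linkS4class{CorticalSubject}.
#' @param spec A \linkS4class{FeatureSpec}.
#' @return Numeric V x d matrix with named columns.
#' @examples
#' # d = 3 for coordinates only; 647 with all flags on an fsaverage3 mesh
#' @export
assembleFeatures <- function(subject, spec) {
  stopifnot(is(subject, "CorticalSubject"), is(spec, "FeatureSpec"))
  cols <- list()
  if (spec@coords) cols$coords <- meshVertices(subjectMesh(subject))
  if (spec@thickness) cols$thickness <- matrix(subjectThickness(subject),
                                               dimnames = list(NULL, "thickness"))
  if (spec@curvature) cols$curvature <- matrix(subjectCurvature(subject),
                                               dimnames = list(NULL, "curvature"))
  if (spec@conductance) {
    conn <- subjectConnectivity(subject)
    if (ncol(conn) == 0L)
      stop(sprintf("subject %s has no connectivity map but the feature spec requests conductance",
                   subjectId(subject)), call. = FALSE)
    colnames(conn) <- sprintf("cond_%03d", seq_len(ncol(conn)))
    cols$conductance <- conn
  }
  do.call(cbind, unname(cols))
}

#' Fit cohort-wide min-max normalization
#'
#' Per-column minima and maxima are computed over all vertices of all
#' subjects in the fitted set, and every matrix is mapped by
#' \code{(x - min) / (max - min)} into [0, 1]. Constant columns map to 0.
#' The returned scaler can be re-applied to unseen subjects (values outside
#' the fitted range are clipped to [0, 1]) and serialized to JSON.
#'
#' @param featureList List of V x d feature matrices (one per subject).
#' @return List with \code{scaled} (the normalized matrices) and
#'   \code{scaler} (a "minMaxScaler" object).
#' @export
cohortMinMax <- function(featureList) {
  if (!is.list(featureList) || length(featureList) == 0L)
    stop("'featureList' must be a nonempty list of feature matrices",
         call. = FALSE)
  d <- ncol(featureList[[1L]])
  mins <- rep(Inf, d); maxs <- rep(-Inf, d)
  for (X in featureList) {
    stopifnot(ncol(X) == d)
    mins <- pmin(mins, apply(X, 2L, min))
    maxs <- pmax(maxs, apply(X, 2L, max))
  }
  scaler <- structure(
    list(min = mins, max = maxs, featureNames = colnames(featureList[[1L]])),
    class = "minMaxScaler")
  list(scaled = lapply(featureList, applyScaler, scaler = scaler,
                       clip = FALSE),
       scaler = scaler)
}

#' Apply / invert a fitted min-max scaler
#'
#' @param scaler A "minMaxScaler" from \code{\link{cohortMinMax}}.
#' @param X Feature matrix with the fitted number of columns.
#' @param clip Clip the result to [0, 1] (used for unseen subjects whose
#'   values may fall outside the fitted range).
#' @return The transformed matrix.
#' @export
applyScaler <- function(scaler, X, clip = TRUE) {
  stopifnot(inherits(scaler, "minMaxScaler"), ncol(X) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1                    # constant columns -> all zeros
  out <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, rng, "/")
  if (clip) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' @rdname applyScaler
#' @export
invertScaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "minMaxScaler"), ncol(X) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 0                    # constant columns restore the min
  sweep(sweep(X, 2L, rng, "*"), 2L, scaler$min, "+")
}

#' Serialize / restore a min-max scaler as JSON
#'
#' @param scaler A "minMaxScaler".
#' @param path JSON file path.
#' @return \code{writeScaler}: the path, invisibly; \code{readScaler}: the
#'   scaler.
#' @export
writeScaler <- function(scaler, path) {
  jsonlite::write_json(
    list(min = scaler$min, max = scaler$max,
         featureNames = scaler$featureNames),
    path, digits = NA, auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' @rdname writeScaler
#' @export
readScaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = as.numeric(obj$min), max = as.numeric(obj$max),
                 featureNames = obj$featureNames),
            class = "minMaxScaler")
}

#' Gaussian noise augmentation of a feature matrix
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation \code{sigma}
#' to a (normalized) feature matrix; applied fresh at every epoch during
#' training. Deterministic when a seed is supplied.
#'
#' @param X Feature matrix.
#' @param sigma Noise s.d. (on the normalized [0, 1] scale); 0 returns X
#'   unchanged.
#' @param seed Optional RNG seed.
#' @return The perturbed matrix.
#' @export
augmentNoise <- function(X, sigma, seed = NULL) {
  if (length(sigma) != 1L || !is.numeric(sigma) || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single nonnegative number", call. = FALSE)
  if (sigma == 0) return(X)
  if (!is.null(seed)) set.seed(seed)
  X + matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X))
}
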