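# Feature-set x architecture ablation harness.

#' Run a feature-set / architecture ablation experiment
#'
#' For every combination of feature spec and model configuration: assemble
#' and cohort-normalize the features, train one model per cross-validation
#' fold (the fold is the epoch-validation set, the remaining folds train),
#' apply each fold's final model to the held-out subjects, and report the
#' mean and s.d. of the holdout macro Dice across folds (and across
#' subjects). This mirrors the usual ablation table layout: one row per
#' (feature set, architecture) cell.
#'
#' By default the min-max scaler is fitted on the entire cohort,
#' replicating the dataset-wide normalization of the reference protocol
#' (which leaks test statistics); set \code{fitOnTrain = TRUE} for
#' leakage-free normalization fitted on the non-holdout subjects only.
#'
#' @param cohort A \linkS4class{CorticalCohort}.
#' @param specs List of \linkS4class{FeatureSpec} objects.
#' @param configs Named list of \linkS4class{ModelConfig} objects.
#' @param hyper A \code{\link{hyperParams}} list.
#' @param hemisphere Which hemisphere to run ("left" or "right").
#' @param nHoldout Held-out final-validation subjects (default 8).
#' @param k Cross-validation folds (default 5).
#' @param fitOnTrain Fit the scaler on non-holdout subjects only.
#' @return List with \code{table} (data frame: featureSet, architecture,
#'   meanDice, sdDice, sdSubjects, folds) and \code{scores} (per cell, the
#'   holdout-subject x fold macro-Dice matrix), classed "ablationResult".
#' @export
runAblation <- function(cohort, specs, configs, hyper = hyperParams(),
                        hemisphere = "left", nHoldout = 8L, k = 5L,
                        fitOnTrain = FALSE) {
  stopifnot(length(specs) >= 1L, length(configs) >= 1L)
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, function(c) c@architecture, "")
  subjects <- cohortSubjects(cohortHemisphere(cohort, hemisphere))
  if (!length(subjects))
    stop(sprintf("cohort has no '%s' hemisphere subjects", hemisphere),
         call. = FALSE)
  ids <- vapply(subjects, subjectId, "")
  graph <- meshToGraph(subjectMesh(subjects[[1L]]))
  labelsList <- lapply(subjects, subjectLabels)
  split <- makeSplits(ids, nHoldout = nHoldout, k = k, seed = hyper$seed)
  holdIdx <- match(split$holdout, ids)

  rows <- list(); scores <- list()
  for (spec in specs) {
    specLab <- featureSetLabel(spec)
    raw <- lapply(subjects, assembleFeatures, spec = spec)
    if (fitOnTrain) {
      fitIdx <- which(!ids %in% split$holdout)
      scaler <- cohortMinMax(raw[fitIdx])$scaler
      feats <- lapply(raw, applyScaler, scaler = scaler, clip = TRUE)
    } else {
      feats <- cohortMinMax(raw)$scaled
    }
    for (cfgName in names(configs)) {
      config <- configs[[cfgName]]
      foldScores <- matrix(NA_real_, length(holdIdx), k,
                           dimnames = list(split$holdout, NULL))
      for (f in seq_len(k)) {
        valIdx <- match(split$folds[[f]], ids)
        trainIdx <- match(unlist(split$folds[-f]), ids)
        fit <- trainModel(feats, labelsList, graph, config,
                          hyper = hyper, trainIdx = trainIdx,
                          valIdx = valIdx)
        gc2 <- .graphCache(graph, config@architecture)
        for (jj in seq_along(holdIdx)) {
          j <- holdIdx[jj]
          pred <- predictParcellation(fit$model, feats[[j]], gc2)
          foldScores[jj, f] <- diceScore(pred, labelsList[[j]])$macro
        }
      }
      perFold <- colMeans(foldScores)
      perSubject <- rowMeans(foldScores)
      rows[[length(rows) + 1L]] <- data.frame(
        featureSet = specLab, architecture = cfgName,
        meanDice = mean(perFold), sdDice = stats::sd(perFold),
        sdSubjects = stats::sd(perSubject), folds = k,
        stringsAsFactors = FALSE)
      scores[[specLab]][[cfgName]] <- foldScores
    }
  }
  structure(list(table = do.call(rbind, rows), scores = scores,
                 split = split),
            class = c("ablationResult", "list"))
}

#' Per-subject holdout scores of one ablation cell
#'
#' Convenience accessor returning each holdout subject's macro Dice
#' averaged over the fold models, the pairing unit for
#' \code{\link{pairedTTest}} comparisons between cells.
#'
#' @param result An "ablationResult" from \code{\link{runAblation}}.
#' @param featureSet Feature-set label (as in the result table).
#' @param architecture Architecture name (as in the result table).
#' @return Named numeric vector, one score per holdout subject.
#' @export
ablationSubjectScores <- function(result, featureSet, architecture) {
  m <- result$scores[[featureSet]][[architecture]]
  if (is.null(m))
    stop(sprintf("no cell (%s, %s) in this ablation", featureSet,
                 architecture), call. = FALSE)
  rowMeans(m)
}
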