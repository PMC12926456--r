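# Training loop (Adam + plateau scheduler), split plans, and history.

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: Adam with starting learning
#' rate 0.01, 100 epochs, batch size 1 (subjects iterated singly), fresh
#' Gaussian feature noise each epoch, and a reduce-on-plateau scheduler
#' monitoring the validation loss (factor 0.5, patience 5).
#'
#' @param lr Starting learning rate (> 0).
#' @param epochs Number of epochs (>= 1).
#' @param batchSize Subjects per gradient step (the reference protocol
#'   uses 1; larger values average gradients over consecutive subjects).
#' @param plateauFactor Multiplicative learning-rate decay on plateau.
#' @param plateauPatience Epochs without validation-loss improvement
#'   before decaying.
#' @param minLr Learning-rate floor.
#' @param augmentSigma S.d. of the Gaussian feature-noise augmentation
#'   (applied to normalized features; 0 disables).
#' @param seed RNG seed controlling initialization, epoch shuffling and
#'   augmentation noise.
#' @return A classed list.
#' @export
hyperParams <- function(lr = 0.01, epochs = 100L, batchSize = 1L,
                        plateauFactor = 0.5, plateauPatience = 5L,
                        minLr = 1e-5, augmentSigma = 0.01, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1)
  p <- list(lr = lr, epochs = .checkCount(epochs, "epochs", 1L),
            batchSize = .checkCount(batchSize, "batchSize", 1L),
            plateauFactor = .checkScalar(plateauFactor, "plateauFactor",
                                         0, 1),
            plateauPatience = .checkCount(plateauPatience,
                                          "plateauPatience", 0L),
            minLr = minLr, augmentSigma = augmentSigma,
            seed = .checkCount(seed, "seed", 0L))
  class(p) <- c("HyperParams", "list")
  p
}

#' Holdout + k-fold split plan over subject ids
#'
#' Uniformly samples \code{nHoldout} ids as the final validation set, then
#' shuffles the remaining ids and partitions them into \code{k} near-equal
#' folds; the whole plan is deterministic under the seed. With 97 ids and
#' the defaults this yields 8 holdout subjects and folds of sizes
#' 18/18/18/18/17 over the remaining 89.
#'
#' @param ids Character or integer vector of subject ids.
#' @param nHoldout Held-out final-validation count (default 8).
#' @param k Number of cross-validation folds (default 5, >= 2).
#' @param seed RNG seed.
#' @return List with \code{holdout} and \code{folds} (a list of k id
#'   vectors), classed "SplitPlan".
#' @export
makeSplits <- function(ids, nHoldout = 8L, k = 5L, seed = 1L) {
  nHoldout <- .checkCount(nHoldout, "nHoldout", 0L)
  k <- .checkCount(k, "k", 2L)
  if (length(ids) <= nHoldout)
    stop("need more ids than holdout subjects", call. = FALSE)
  set.seed(seed)
  holdout <- if (nHoldout > 0L) sample(ids, nHoldout) else ids[0L]
  rest <- sample(setdiff(ids, holdout))
  if (k > length(rest))
    stop(sprintf("k = %d exceeds the %d remaining subjects", k,
                 length(rest)), call. = FALSE)
  sizes <- rep(length(rest) %/% k, k)
  extra <- length(rest) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(rest, rep(seq_len(k), times = sizes))
  names(folds) <- NULL
  structure(list(holdout = holdout, folds = folds, seed = seed),
            class = c("SplitPlan", "list"))
}

# -- Adam ----------------------------------------------------------------

.zerosLike <- function(x) {
  if (is.list(x)) lapply(x, .zerosLike)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else numeric(length(x))
}

.adamInit <- function(params) {
  list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)
}

# One Adam update; params/grads/state$m/state$v share the same nesting.
.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

.sumGrads <- function(a, b) {
  if (is.list(a)) Map(.sumGrads, a, b) else a + b
}

# -- training loop --------------------------------------------------------

#' Train a GNN parcellation model
#'
#' Per epoch, training subjects are visited singly in a shuffled order
#' (batch size 1 by default); each visit adds fresh Gaussian noise to the
#' (normalized) features, runs the forward pass, computes the mean
#' per-vertex cross-entropy, backpropagates analytically, and takes an
#' Adam step. The plateau scheduler halves the learning rate after
#' \code{plateauPatience} epochs without validation-loss improvement.
#' Training and validation macro-Dice are recorded every epoch. The
#' final-epoch model is returned (no early stopping).
#'
#' @param features List of V x d normalized feature matrices.
#' @param labels List of integer label vectors (1..K), parallel to
#'   \code{features}.
#' @param graph The shared \linkS4class{VertexGraph}.
#' @param config A \linkS4class{ModelConfig}.
#' @param hyper A \code{\link{hyperParams}} list.
#' @param trainIdx,valIdx Integer indices into \code{features} for the
#'   training and epoch-validation subjects (validation may be empty, in
#'   which case the scheduler monitors the training loss).
#' @return List with \code{model} (a \linkS4class{GNNModel}) and
#'   \code{history} (a per-epoch data frame).
#' @export
trainModel <- function(features, labels, graph, config, hyper = hyperParams(),
                       trainIdx = seq_along(features), valIdx = integer()) {
  stopifnot(length(features) == length(labels), length(trainIdx) >= 1L)
  d <- ncol(features[[1L]])
  set.seed(hyper$seed)
  model <- buildModel(config, d)
  gcache <- .graphCache(graph, config@architecture)
  state <- .adamInit(model@params)
  lr <- hyper$lr
  best <- Inf
  stall <- 0L
  hist <- vector("list", hyper$epochs)

  evalSet <- function(idx) {
    if (!length(idx)) return(c(NA_real_, NA_real_))
    losses <- numeric(length(idx)); dices <- numeric(length(idx))
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      fw <- .forwardModel(model, features[[i]], gcache)
      losses[ii] <- softmaxCrossEntropy(fw$logits, labels[[i]])$loss
      pred <- max.col(fw$logits, ties.method = "first")
      dices[ii] <- diceScore(pred, labels[[i]])$macro
    }
    c(mean(losses), mean(dices))
  }

  for (epoch in seq_len(hyper$epochs)) {
    order <- sample(trainIdx)
    epochLoss <- 0
    pending <- NULL
    nPending <- 0L
    for (i in order) {
      X <- augmentNoise(features[[i]], hyper$augmentSigma)
      fw <- .forwardModel(model, X, gcache, training = TRUE)
      ce <- softmaxCrossEntropy(fw$logits, labels[[i]])
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d (subject index %d); aborting training",
                     epoch, i), call. = FALSE)
      epochLoss <- epochLoss + ce$loss
      grads <- .backwardModel(model, fw, ce$grad, X, gcache)
      pending <- if (is.null(pending)) grads else .sumGrads(pending, grads)
      nPending <- nPending + 1L
      if (nPending >= hyper$batchSize) {
        upd <- .adamStep(model@params, pending, state, lr)
        model@params <- upd$params
        state <- upd$state
        pending <- NULL; nPending <- 0L
      }
    }
    if (nPending > 0L) {
      upd <- .adamStep(model@params, pending, state, lr)
      model@params <- upd$params
      state <- upd$state
    }
    tr <- evalSet(trainIdx)
    va <- evalSet(valIdx)
    monitored <- if (length(valIdx)) va[1L] else epochLoss / length(order)
    if (monitored < best - 1e-8) {
      best <- monitored
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > hyper$plateauPatience) {
        lr <- max(lr * hyper$plateauFactor, hyper$minLr)
        stall <- 0L
      }
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, trainLoss = tr[1L], trainDice = tr[2L],
      valLoss = va[1L], valDice = va[2L])
  }
  list(model = model, history = do.call(rbind, hist))
}
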