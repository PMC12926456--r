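# Model assembly: parameter initialization, full forward/backward passes
# per architecture, parameter counting, and checkpoint I/O.

.glorot <- function(fanIn, fanOut, n = fanIn * fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  stats::runif(n, -lim, lim)
}

.initGcnLayer <- function(dIn, dOut) {
  list(W = matrix(.glorot(dIn, dOut), dIn, dOut), b = numeric(dOut))
}

.initGatLayer <- function(dIn, dOut, heads, average) {
  list(W = lapply(seq_len(heads), function(h)
         matrix(.glorot(dIn, dOut), dIn, dOut)),
       aSrc = lapply(seq_len(heads), function(h)
         .glorot(dOut, 1L, n = dOut)),
       aDst = lapply(seq_len(heads), function(h)
         .glorot(dOut, 1L, n = dOut)),
       b = numeric(if (average) dOut else heads * dOut))
}

#' Build a GNN node classifier
#'
#' Stacks layers according to the configuration: GCN and GAT use the
#' configured hidden widths followed by a linear output layer emitting raw
#' logits for the K classes (GAT concatenates heads in hidden layers and
#' averages them at the output). The Graph U-Net uses an input embedding
#' GCN, \code{depth} top-k pooling + GCN encoder levels, mirrored
#' unpooling + skip-connection + GCN decoder levels, and a GCN output
#' head. Weights are Glorot-uniform; biases zero.
#'
#' @param config A \linkS4class{ModelConfig}.
#' @param inDim Input feature dimension (>= 1).
#' @param seed Optional RNG seed for initialization.
#' @return A \linkS4class{GNNModel}.
#' @examples
#' m <- buildModel(modelConfig("gcn", nClasses = 5, hidden = 8), inDim = 4)
#' countParameters(m)  # 4*8 + 8 + 8*5 + 5
#' @export
buildModel <- function(config, inDim, seed = NULL) {
  stopifnot(is(config, "ModelConfig"))
  inDim <- .checkCount(inDim, "inDim", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  K <- config@nClasses
  params <- switch(config@architecture,
    gcn = {
      dims <- c(inDim, config@hidden, K)
      list(layers = lapply(seq_len(length(dims) - 1L), function(l)
        .initGcnLayer(dims[l], dims[l + 1L])))
    },
    gat = {
      nh <- config@heads
      dims <- c(inDim, config@hidden)
      hiddenLayers <- lapply(seq_len(length(dims) - 1L), function(l)
        .initGatLayer(if (l == 1L) inDim else dims[l] * nh, dims[l + 1L],
                      nh, average = FALSE))
      outIn <- if (length(config@hidden)) utils::tail(config@hidden, 1L) * nh
               else inDim
      list(layers = c(hiddenLayers,
                      list(.initGatLayer(outIn, K, nh, average = TRUE))))
    },
    gunet = {
      w <- config@hidden[1L]
      list(inLayer = .initGcnLayer(inDim, w),
           enc = lapply(seq_len(config@depth), function(l)
             list(p = .glorot(w, 1L, n = w), gcn = .initGcnLayer(w, w))),
           dec = lapply(seq_len(config@depth), function(l)
             .initGcnLayer(w, w)),
           outLayer = .initGcnLayer(w, K))
    },
    stop(sprintf("unknown architecture '%s'", config@architecture),
         call. = FALSE))
  new("GNNModel", config = config, inDim = inDim, params = params)
}

#' Count the trainable parameters of a model
#'
#' Sums the sizes of every weight matrix, bias, attention vector and
#' pooling projection; equals the closed-form sum of the layer shapes.
#'
#' @param model A \linkS4class{GNNModel}.
#' @return Integer parameter count.
#' @export
countParameters <- function(model) {
  length(unlist(model@params, use.names = FALSE))
}

# -- full forward / backward ---------------------------------------------

.forwardModel <- function(model, H, gcache, training = FALSE) {
  cfg <- model@config
  act <- .activation(cfg@activation)
  idAct <- .activation("identity")
  p <- model@params
  switch(cfg@architecture,
    gcn = {
      nl <- length(p$layers)
      caches <- vector("list", nl)
      for (l in seq_len(nl)) {
        a <- if (l == nl) idAct else act
        caches[[l]] <- .gcnForward(H, gcache$S, p$layers[[l]]$W,
                                   p$layers[[l]]$b, a)
        caches[[l]]$input <- H
        H <- caches[[l]]$out
      }
      list(logits = H, caches = caches)
    },
    gat = {
      nl <- length(p$layers)
      caches <- vector("list", nl)
      for (l in seq_len(nl)) {
        avg <- l == nl
        a <- if (l == nl) idAct else act
        caches[[l]] <- .gatForward(H, gcache$ed, p$layers[[l]], a,
                                   average = avg)
        caches[[l]]$input <- H
        H <- caches[[l]]$out
      }
      list(logits = H, caches = caches)
    },
    gunet = {
      depth <- cfg@depth
      Slist <- vector("list", depth + 1L)
      edgeList <- vector("list", depth + 1L)
      Vlist <- integer(depth + 1L)
      Slist[[1L]] <- gcache$S; edgeList[[1L]] <- gcache$edges
      Vlist[1L] <- gcache$V
      cIn <- .gcnForward(H, Slist[[1L]], p$inLayer$W, p$inLayer$b, act)
      cIn$input <- H
      h <- cIn$out
      skips <- vector("list", depth)
      pools <- vector("list", depth)
      encs <- vector("list", depth)
      for (l in seq_len(depth)) {
        skips[[l]] <- h
        pools[[l]] <- topkPool(h, edgeList[[l]], p$enc[[l]]$p, cfg@poolRatio)
        Vlist[l + 1L] <- length(pools[[l]]$idx)
        edgeList[[l + 1L]] <- pools[[l]]$edges
        Slist[[l + 1L]] <- .normAdjFromEdges(pools[[l]]$edges, Vlist[l + 1L])
        encs[[l]] <- .gcnForward(pools[[l]]$H, Slist[[l + 1L]],
                                 p$enc[[l]]$gcn$W, p$enc[[l]]$gcn$b, act)
        h <- encs[[l]]$out
      }
      decs <- vector("list", depth)
      for (l in rev(seq_len(depth))) {
        hUp <- topkUnpool(h, pools[[l]]$idx, Vlist[l]) + skips[[l]]
        decs[[l]] <- .gcnForward(hUp, Slist[[l]], p$dec[[l]]$W,
                                 p$dec[[l]]$b, act)
        decs[[l]]$inputSum <- hUp
        h <- decs[[l]]$out
      }
      cOut <- .gcnForward(h, Slist[[1L]], p$outLayer$W, p$outLayer$b, idAct)
      list(logits = cOut$out,
           caches = list(cIn = cIn, pools = pools, encs = encs, decs = decs,
                         cOut = cOut, Slist = Slist, Vlist = Vlist))
    })
}

.backwardModel <- function(model, fw, dLogits, H0, gcache) {
  cfg <- model@config
  act <- .activation(cfg@activation)
  idAct <- .activation("identity")
  p <- model@params
  switch(cfg@architecture,
    gcn = {
      nl <- length(p$layers)
      grads <- vector("list", nl)
      d <- dLogits
      for (l in rev(seq_len(nl))) {
        a <- if (l == nl) idAct else act
        bk <- .gcnBackward(d, fw$caches[[l]], gcache$S, p$layers[[l]]$W, a)
        grads[[l]] <- list(W = bk$dW, b = bk$db)
        d <- bk$dH
      }
      list(layers = grads)
    },
    gat = {
      nl <- length(p$layers)
      grads <- vector("list", nl)
      d <- dLogits
      for (l in rev(seq_len(nl))) {
        avg <- l == nl
        a <- if (l == nl) idAct else act
        bk <- .gatBackward(d, fw$caches[[l]], fw$caches[[l]]$input,
                           gcache$ed, p$layers[[l]], a, average = avg)
        grads[[l]] <- list(W = bk$dW, aSrc = bk$daSrc, aDst = bk$daDst,
                           b = bk$db)
        d <- bk$dH
      }
      list(layers = grads)
    },
    gunet = {
      depth <- cfg@depth
      ca <- fw$caches
      bkOut <- .gcnBackward(dLogits, ca$cOut, ca$Slist[[1L]],
                            p$outLayer$W, idAct)
      d <- bkOut$dH
      decGrads <- vector("list", depth)
      encGrads <- vector("list", depth)
      skipGrads <- vector("list", depth)
      # decoder side: decs[[1]] was the last layer applied, so the
      # gradient walks l = 1..depth, splitting at each level into the
      # skip-connection branch (stored) and the unpooling gather
      for (l in seq_len(depth)) {
        bkDec <- .gcnBackward(d, ca$decs[[l]], ca$Slist[[l]], p$dec[[l]]$W,
                              act)
        decGrads[[l]] <- list(W = bkDec$dW, b = bkDec$db)
        skipGrads[[l]] <- bkDec$dH
        d <- bkDec$dH[ca$pools[[l]]$idx, , drop = FALSE]   # unpool gather
      }
      # encoder side: d now sits at the deepest level; the pool input at
      # level l is the same tensor as the skip, so the stored skip
      # gradient joins there
      for (l in rev(seq_len(depth))) {
        bkEnc <- .gcnBackward(d, ca$encs[[l]], ca$Slist[[l + 1L]],
                              p$enc[[l]]$gcn$W, act)
        bkPool <- .topkPoolBackward(bkEnc$dH, ca$pools[[l]])
        encGrads[[l]] <- list(p = bkPool$dp,
                              gcn = list(W = bkEnc$dW, b = bkEnc$db))
        d <- bkPool$dH + skipGrads[[l]]
      }
      bkIn <- .gcnBackward(d, ca$cIn, ca$Slist[[1L]], p$inLayer$W, act)
      list(inLayer = list(W = bkIn$dW, b = bkIn$db),
           enc = encGrads, dec = decGrads,
           outLayer = list(W = bkOut$dW, b = bkOut$db))
    })
}

# -- loss -----------------------------------------------------------------

#' Softmax cross-entropy over vertices
#'
#' Mean per-vertex cross-entropy of the logits against integer labels
#' (1..K), with the analytic logit gradient.
#'
#' @param logits V x K matrix of raw scores.
#' @param labels Integer vector of true classes in 1..K.
#' @return List with \code{loss}, \code{grad} (V x K), and \code{prob}.
#' @export
softmaxCrossEntropy <- function(logits, labels) {
  V <- nrow(logits)
  stopifnot(length(labels) == V)
  m <- apply(logits, 1L, max)
  P <- exp(logits - m)
  P <- P / rowSums(P)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(V), labels)] + eps))
  G <- P
  G[cbind(seq_len(V), labels)] <- G[cbind(seq_len(V), labels)] - 1
  list(loss = loss, grad = G / V, prob = P)
}

#' Predict a parcellation with a trained model
#'
#' Runs the forward pass and takes the per-vertex argmax of the logits
#' (ties broken toward the lower class index).
#'
#' @param model A \linkS4class{GNNModel}.
#' @param H V x d (normalized) feature matrix.
#' @param graph A \linkS4class{VertexGraph} (or a prebuilt graph cache).
#' @return Integer vector of predicted labels in 1..K.
#' @export
predictParcellation <- function(model, H, graph) {
  gcache <- if (is(graph, "VertexGraph"))
    .graphCache(graph, model@config@architecture) else graph
  logits <- .forwardModel(model, H, gcache)$logits
  max.col(logits, ties.method = "first")
}

#' Model logits
#'
#' @inheritParams predictParcellation
#' @return V x K logit matrix.
#' @export
modelLogits <- function(model, H, graph) {
  gcache <- if (is(graph, "VertexGraph"))
    .graphCache(graph, model@config@architecture) else graph
  .forwardModel(model, H, gcache)$logits
}

# -- checkpoint I/O -------------------------------------------------------

# Parameters are stored as flat arrays with a shape manifest, in the
# deterministic traversal order of the nested parameter list; the
# architecture config rebuilds the structure on load.

.paramShapes <- function(params) {
  leaves <- list()
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else leaves[[length(leaves) + 1L]] <<- if (is.matrix(x)) dim(x)
                                           else length(x)
    invisible(NULL)
  }
  walk(params)
  leaves
}

.fillParams <- function(params, values) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    v <- values[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  out <- fill(params)
  stopifnot(pos == length(values))
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a JSON document: the architecture configuration, the
#' input dimension, a manifest of parameter shapes, and one flat numeric
#' array holding all parameters in deterministic traversal order.
#'
#' @param model A \linkS4class{GNNModel}.
#' @param path JSON file path.
#' @return \code{saveModel}: the path, invisibly; \code{loadModel}: the
#'   restored \linkS4class{GNNModel}.
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  jsonlite::write_json(list(
    config = list(architecture = cfg@architecture, hidden = cfg@hidden,
                  heads = cfg@heads, poolRatio = cfg@poolRatio,
                  depth = cfg@depth, activation = cfg@activation,
                  nClasses = cfg@nClasses, dropout = cfg@dropout),
    inDim = model@inDim,
    shapes = .paramShapes(model@params),
    values = as.numeric(unlist(model@params, use.names = FALSE))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- modelConfig(obj$config$architecture,
                     nClasses = obj$config$nClasses,
                     hidden = obj$config$hidden, heads = obj$config$heads,
                     poolRatio = obj$config$poolRatio,
                     depth = obj$config$depth,
                     activation = obj$config$activation,
                     dropout = obj$config$dropout)
  skeleton <- buildModel(cfg, obj$inDim, seed = 0L)
  new("GNNModel", config = cfg, inDim = as.integer(obj$inDim),
      params = .fillParams(skeleton@params, as.numeric(obj$values)))
}
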