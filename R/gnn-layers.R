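# Graph neural network layer primitives: forward passes and analytic
# backward passes for GCN propagation, multi-head graph attention, and
# top-k graph pooling/unpooling. All operate on dense V x d feature
# matrices with a sparse or edge-list graph representation.

# -- activations ----------------------------------------------------------

.activation <- function(name) {
  switch(name,
    elu = list(f = function(z) ifelse(z > 0, z, expm1(z)),
               grad = function(z, fz) ifelse(z > 0, 1, fz + 1)),
    relu = list(f = function(z) pmax(z, 0),
                grad = function(z, fz) (z > 0) * 1),
    tanh = list(f = tanh,
                grad = function(z, fz) 1 - fz^2),
    identity = list(f = identity,
                    grad = function(z, fz) array(1, dim(z))),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# -- graph caches ---------------------------------------------------------

# Symmetrically degree-normalized adjacency with self-loops:
# S = D^(-1/2) (A + I) D^(-1/2), as a sparse matrix.
.normAdjFromEdges <- function(edges, V) {
  i <- c(edges[, 1L], edges[, 2L], seq_len(V))
  j <- c(edges[, 2L], edges[, 1L], seq_len(V))
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = V) + 1
  w <- 1 / sqrt(deg[i] * deg[j])
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(V, V))
}

#' Normalized adjacency operator of a vertex graph
#'
#' Returns the GCN propagation matrix
#' \code{S = D^(-1/2) (A + I) D^(-1/2)} (self-loops added, symmetric
#' degree normalization) as a sparse matrix.
#'
#' @param graph A \linkS4class{VertexGraph}.
#' @return A sparse V x V matrix.
#' @export
gcnNormAdjacency <- function(graph) {
  .normAdjFromEdges(graph@edges, nNodes(graph))
}

# Directed edge index for attention: every (target, source) pair with
# source in N(target) + self-loop, plus a per-target group index for
# softmax normalization. Self-loops guarantee every node appears as a
# target and as a source, so rowsum(..., group) yields rows 1..V in order.
.gatEdgeIndex <- function(graph) {
  e <- graph@edges
  V <- nNodes(graph)
  dst <- c(e[, 1L], e[, 2L], seq_len(V))
  src <- c(e[, 2L], e[, 1L], seq_len(V))
  o <- order(dst, src)
  dst <- dst[o]; src <- src[o]
  list(dst = dst, src = src, V = V,
       groups = split(seq_along(dst), dst))
}

.groupMax <- function(x, ed) {
  vapply(ed$groups, function(ix) max(x[ix]), numeric(1L))
}

# Precomputed per-graph structures needed by each architecture.
.graphCache <- function(graph, architecture) {
  switch(architecture,
    gcn = list(S = gcnNormAdjacency(graph)),
    gat = list(ed = .gatEdgeIndex(graph)),
    gunet = list(S = gcnNormAdjacency(graph), edges = graph@edges,
                 V = nNodes(graph)))
}

# -- GCN layer ------------------------------------------------------------

#' One GCN propagation step
#'
#' Computes \code{act(S H W + b)} with \code{S} the symmetrically
#' normalized self-looped adjacency. \code{gcnLayer} is the plain forward
#' convenience; the internal forward/backward pair carries the caches used
#' for analytic gradients during training.
#'
#' @param H V x d feature matrix.
#' @param graph A \linkS4class{VertexGraph}.
#' @param W d x d' weight matrix.
#' @param b length-d' bias vector.
#' @param activation Activation name (default "identity").
#' @return V x d' output features.
#' @export
gcnLayer <- function(H, graph, W, b, activation = "identity") {
  if (ncol(H) != nrow(W))
    stop(sprintf("feature dimension %d does not match weight rows %d",
                 ncol(H), nrow(W)), call. = FALSE)
  .gcnForward(H, gcnNormAdjacency(graph), W, b, .activation(activation))$out
}

.gcnForward <- function(H, S, W, b, act) {
  M <- as.matrix(S %*% H)
  Z <- M %*% W
  Z <- Z + rep(b, each = nrow(Z))
  out <- act$f(Z)
  list(out = out, M = M, Z = Z)
}

.gcnBackward <- function(dOut, cache, S, W, act) {
  dZ <- dOut * act$grad(cache$Z, cache$out)
  list(dH = as.matrix(S %*% (dZ %*% t(W))),
       dW = crossprod(cache$M, dZ),
       db = colSums(dZ))
}

# -- GAT layer ------------------------------------------------------------

#' One multi-head graph attention step
#'
#' Per head h with weight \code{W_h} and attention vectors
#' \code{aDst_h, aSrc_h}: attention logits over each target's neighborhood
#' (self-loop included) are
#' \code{e_ij = LeakyReLU(aDst . W h_i + aSrc . W h_j)} (slope 0.2),
#' normalized by a softmax over \code{j in N(i) + {i}}, and features are
#' aggregated as \code{sum_j alpha_ij W h_j}. Heads are concatenated
#' (hidden layers) or averaged (\code{average = TRUE}, output layer), a
#' bias is added and the activation applied.
#'
#' @param H V x d feature matrix.
#' @param graph A \linkS4class{VertexGraph}.
#' @param params List with \code{W}, \code{aSrc}, \code{aDst} (lists, one
#'   per head) and bias \code{b}.
#' @param activation Activation name.
#' @param average Average heads instead of concatenating.
#' @param returnAttention Also return the per-edge attention coefficients.
#' @return V x d'' output features; if \code{returnAttention}, a list with
#'   \code{out}, \code{alpha} (list per head) and the edge index.
#' @export
gatLayer <- function(H, graph, params, activation = "identity",
                     average = FALSE, returnAttention = FALSE) {
  if (ncol(H) != nrow(params$W[[1L]]))
    stop(sprintf("feature dimension %d does not match weight rows %d",
                 ncol(H), nrow(params$W[[1L]])), call. = FALSE)
  ed <- .gatEdgeIndex(graph)
  fw <- .gatForward(H, ed, params, .activation(activation), average)
  if (!returnAttention) return(fw$out)
  list(out = fw$out, alpha = lapply(fw$heads, `[[`, "alpha"),
       dst = ed$dst, src = ed$src)
}

.gatForward <- function(H, ed, params, act, average = FALSE) {
  nh <- length(params$W)
  heads <- vector("list", nh)
  raw <- NULL
  for (h in seq_len(nh)) {
    Wh <- H %*% params$W[[h]]
    q1 <- as.vector(Wh %*% params$aDst[[h]])
    q2 <- as.vector(Wh %*% params$aSrc[[h]])
    sRaw <- q1[ed$dst] + q2[ed$src]
    sAct <- ifelse(sRaw > 0, sRaw, 0.2 * sRaw)
    gm <- .groupMax(sAct, ed)
    ex <- exp(sAct - gm[ed$dst])
    denom <- rowsum(ex, ed$dst)[, 1L]
    alpha <- ex / denom[ed$dst]
    agg <- rowsum(alpha * Wh[ed$src, , drop = FALSE], ed$dst)
    dimnames(agg) <- NULL
    heads[[h]] <- list(Wh = Wh, sRaw = sRaw, alpha = alpha, agg = agg)
    raw <- if (average) {
      if (is.null(raw)) agg / nh else raw + agg / nh
    } else {
      if (is.null(raw)) agg else cbind(raw, agg)
    }
  }
  Z <- raw + rep(params$b, each = nrow(raw))
  list(out = act$f(Z), Z = Z, heads = heads)
}

.gatBackward <- function(dOut, cache, H, ed, params, act, average = FALSE) {
  nh <- length(params$W)
  dZ <- dOut * act$grad(cache$Z, cache$out %||% act$f(cache$Z))
  db <- colSums(dZ)
  dH <- matrix(0, nrow(H), ncol(H))
  dWs <- vector("list", nh); dASrc <- vector("list", nh)
  dADst <- vector("list", nh)
  wOut <- ncol(params$W[[1L]])
  for (h in seq_len(nh)) {
    hc <- cache$heads[[h]]
    dAgg <- if (average) dZ / nh else
      dZ[, (h - 1L) * wOut + seq_len(wOut), drop = FALSE]
    dAggDst <- dAgg[ed$dst, , drop = FALSE]
    WhSrc <- hc$Wh[ed$src, , drop = FALSE]
    dAlpha <- rowSums(dAggDst * WhSrc)
    dWh <- rowsum(hc$alpha * dAggDst, ed$src)
    inner <- rowsum(hc$alpha * dAlpha, ed$dst)[, 1L]
    dS <- hc$alpha * (dAlpha - inner[ed$dst])
    dSRaw <- dS * ifelse(hc$sRaw > 0, 1, 0.2)
    g1 <- rowsum(dSRaw, ed$dst)[, 1L]
    g2 <- rowsum(dSRaw, ed$src)[, 1L]
    dWh <- dWh + outer(g1, params$aDst[[h]]) + outer(g2, params$aSrc[[h]])
    dADst[[h]] <- as.vector(crossprod(hc$Wh, g1))
    dASrc[[h]] <- as.vector(crossprod(hc$Wh, g2))
    dWs[[h]] <- crossprod(H, dWh)
    dH <- dH + dWh %*% t(params$W[[h]])
  }
  list(dH = dH, dW = dWs, daSrc = dASrc, daDst = dADst, db = db)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- top-k pooling / unpooling -------------------------------------------

#' Top-k graph pooling
#'
#' Scores every node by the projection \code{y = H p / ||p||}, keeps the
#' \code{ceiling(ratio * V)} highest-scoring nodes (ties broken toward the
#' lower index), gates the retained features by \code{tanh(y)}, and
#' induces the subgraph on the retained nodes.
#'
#' @param H V x d feature matrix.
#' @param edges E x 2 undirected edge matrix (i < j).
#' @param p length-d projection vector.
#' @param ratio Keep ratio in (0, 1].
#' @return List with \code{H} (k x d gated features), \code{idx} (retained
#'   original indices, ascending), \code{edges} (relabeled induced
#'   subgraph), \code{score} (all V scores) and internals used by the
#'   backward pass.
#' @export
topkPool <- function(H, edges, p, ratio) {
  V <- nrow(H)
  k <- as.integer(ceiling(ratio * V))
  if (k < 1L)
    stop("pooled graph would be empty; increase the pooling ratio",
         call. = FALSE)
  np <- sqrt(sum(p^2))
  if (np < 1e-12) np <- 1e-12
  u <- p / np
  y <- as.vector(H %*% u)
  ord <- order(-y, seq_len(V))
  idx <- sort(ord[seq_len(k)])
  gate <- tanh(y[idx])
  Hp <- H[idx, , drop = FALSE] * gate
  if (nrow(edges) > 0L) {
    m <- edges[, 1L] %in% idx & edges[, 2L] %in% idx
    sub <- cbind(match(edges[m, 1L], idx), match(edges[m, 2L], idx))
  } else {
    sub <- matrix(integer(), 0L, 2L)
  }
  storage.mode(sub) <- "integer"
  list(H = Hp, idx = idx, edges = sub, score = y, gate = gate, u = u,
       np = np, Hin = H)
}

.topkPoolBackward <- function(dHp, cache) {
  V <- nrow(cache$Hin)
  dH <- matrix(0, V, ncol(cache$Hin))
  dH[cache$idx, ] <- dHp * cache$gate
  dGate <- rowSums(dHp * cache$Hin[cache$idx, , drop = FALSE])
  dy <- numeric(V)
  dy[cache$idx] <- dGate * (1 - cache$gate^2)
  dH <- dH + outer(dy, cache$u)
  du <- as.vector(crossprod(cache$Hin, dy))
  dp <- (du - cache$u * sum(cache$u * du)) / cache$np
  list(dH = dH, dp = dp)
}

#' Graph unpooling
#'
#' Scatters pooled node features back to their recorded original indices;
#' all other rows are zero.
#'
#' @param Hp k x d pooled feature matrix.
#' @param idx Retained original indices recorded by \code{\link{topkPool}}.
#' @param V Original node count.
#' @return V x d matrix.
#' @export
topkUnpool <- function(Hp, idx, V) {
  out <- matrix(0, V, ncol(Hp))
  out[idx, ] <- Hp
  out
}
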