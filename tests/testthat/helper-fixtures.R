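# Shared fixtures built in code, memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

# Small full-featured cohort on the 642-vertex hemisphere.
smallCohort <- function(n = 6L, seed = 3L, connectivity = TRUE,
                        subdivisions = 3L, K = 35L) {
  key <- sprintf("coh_%d_%d_%d_%d_%d", n, seed, connectivity, subdivisions, K)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- suppressMessages(generateCohort(
      cohortParams(nSubjects = n, seed = seed, connectivity = connectivity,
                   subdivisions = subdivisions, K = K)))
  .fixtureCache[[key]]
}

# Random simple undirected graph on n nodes (edge prob p), as VertexGraph.
randomGraph <- function(n, p = 0.3) {
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  storage.mode(e) <- "integer"
  new("VertexGraph", nodeCount = as.integer(n), edges = e)
}

# Dense-matrix GCN oracle: act(S H W + b) with S computed densely.
denseGcnOracle <- function(H, graph, W, b) {
  V <- nNodes(graph)
  A <- matrix(0, V, V)
  e <- graphEdges(graph)
  if (nrow(e)) {
    A[e] <- 1
    A[e[, 2:1, drop = FALSE]] <- 1
  }
  A <- A + diag(V)
  d <- rowSums(A)
  S <- diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  S %*% H %*% W + matrix(b, V, length(b), byrow = TRUE)
}

# Dense per-node loop GAT oracle (single set of head params).
denseGatOracle <- function(H, graph, W, aSrc, aDst) {
  V <- nNodes(graph)
  A <- matrix(FALSE, V, V)
  e <- graphEdges(graph)
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(A) <- TRUE
  Wh <- H %*% W
  out <- matrix(0, V, ncol(W))
  for (i in seq_len(V)) {
    nb <- which(A[i, ])
    logit <- vapply(nb, function(j) {
      s <- sum(aDst * Wh[i, ]) + sum(aSrc * Wh[j, ])
      if (s > 0) s else 0.2 * s
    }, numeric(1L))
    alpha <- exp(logit - max(logit))
    alpha <- alpha / sum(alpha)
    out[i, ] <- colSums(alpha * Wh[nb, , drop = FALSE])
  }
  out
}
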