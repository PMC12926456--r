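# GNN propagation rules: dense-matrix oracles, attention properties,
# pooling mechanics, parameter counting, equivariance, analytic gradients.

test_that("GCN layer on an edgeless graph is a plain dense layer", {
  set.seed(1)
  g <- new("VertexGraph", nodeCount = 5L, edges = matrix(integer(), 0, 2))
  H <- matrix(rnorm(20), 5, 4)
  W <- matrix(rnorm(12), 4, 3); b <- rnorm(3)
  expect_equal(gcnLayer(H, g, W, b), H %*% W +
                 matrix(b, 5, 3, byrow = TRUE))
})

test_that("GCN on a 2-node single-edge graph averages the two rows", {
  g <- new("VertexGraph", nodeCount = 2L,
           edges = matrix(c(1L, 2L), 1))
  H <- rbind(c(1, 3), c(5, 7))
  out <- gcnLayer(H, g, diag(2), c(0, 0))
  expect_equal(out, rbind(colMeans(H), colMeans(H)))
})

test_that("GCN and GAT forwards match dense brute-force oracles", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    g <- randomGraph(n, p = 0.3)
    d <- sample(2:6, 1); dOut <- sample(2:5, 1)
    H <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * dOut), d, dOut); b <- rnorm(dOut)
    expect_equal(gcnLayer(H, g, W, b),
                 denseGcnOracle(H, g, W, b), tolerance = 1e-6)
    aS <- rnorm(dOut); aD <- rnorm(dOut)
    params <- list(W = list(W), aSrc = list(aS), aDst = list(aD),
                   b = numeric(dOut))
    expect_equal(unname(gatLayer(H, g, params)),
                 denseGatOracle(H, g, W, aS, aD), tolerance = 1e-6)
  }
})

test_that("GCN layers validate feature/weight dimensions", {
  g <- randomGraph(4)
  expect_error(gcnLayer(matrix(0, 4, 3), g, matrix(0, 2, 2), c(0, 0)),
               "dimension")
})

test_that("attention rows are a proper softmax over each neighborhood", {
  set.seed(5)
  g <- randomGraph(12, p = 0.4)
  d <- 4
  H <- matrix(rnorm(12 * d), 12, d)
  params <- list(W = list(matrix(rnorm(d * 3), d, 3)),
                 aSrc = list(rnorm(3)), aDst = list(rnorm(3)),
                 b = numeric(3))
  at <- gatLayer(H, g, params, returnAttention = TRUE)
  sums <- rowsum(at$alpha[[1L]], at$dst)[, 1L]
  expect_equal(unname(sums), rep(1, 12), tolerance = 1e-6)
  # identical features -> uniform attention 1/(deg+1)
  Hc <- matrix(1, 12, d)
  atc <- gatLayer(Hc, g, params, returnAttention = TRUE)
  deg <- nodeDegrees(g)
  expect_equal(unname(atc$alpha[[1L]]), 1 / (deg[atc$dst] + 1),
               tolerance = 1e-9)
})

test_that("an isolated node attends only to itself", {
  g <- new("VertexGraph", nodeCount = 3L, edges = matrix(c(1L, 2L), 1))
  H <- matrix(rnorm(6), 3, 2)
  W <- matrix(rnorm(4), 2, 2)
  params <- list(W = list(W), aSrc = list(rnorm(2)), aDst = list(rnorm(2)),
                 b = c(0, 0))
  at <- gatLayer(H, g, params, returnAttention = TRUE)
  self <- at$alpha[[1L]][at$dst == 3L]
  expect_equal(unname(self), 1)
  expect_equal(at$out[3L, ], (H %*% W)[3L, ])
})

test_that("top-k pooling keeps the brute-force top scorers and unpools back", {
  set.seed(3)
  g <- meshToGraph(buildIcosphere(1))
  H <- matrix(rnorm(42 * 5), 42, 5)
  p <- rnorm(5)
  pool <- topkPool(H, graphEdges(g), p, ratio = 0.5)
  expect_length(pool$idx, 21L)    # ceiling(0.5 * 42)
  y <- as.vector(H %*% p / sqrt(sum(p^2)))
  expect_setequal(pool$idx, order(-y)[1:21])
  # gating: retained rows are tanh(score)-scaled inputs
  expect_equal(pool$H, H[pool$idx, ] * tanh(y[pool$idx]))
  # unpool restores the original node count with zeros elsewhere
  up <- topkUnpool(pool$H, pool$idx, 42L)
  expect_equal(nrow(up), 42L)
  expect_true(all(up[-pool$idx, ] == 0))
  expect_equal(up[pool$idx, ], pool$H)
  # ratio 0.5 on 10 nodes -> 5
  expect_length(topkPool(H[1:10, ], matrix(integer(), 0, 2), p,
                         0.5)$idx, 5L)
})

test_that("tie scores resolve toward the lower vertex index", {
  H <- matrix(1, 6, 2)                 # all scores equal
  pool <- topkPool(H, matrix(integer(), 0, 2), c(1, 1), ratio = 0.5)
  expect_equal(pool$idx, 1:3)
})

test_that("parameter counts equal the closed-form sums", {
  K <- 7L
  # GCN widths [w]: in*w + w + w*K + K
  for (inDim in c(5L, 20L)) {
    w <- 16L
    m <- buildModel(modelConfig("gcn", nClasses = K, hidden = w), inDim,
                    seed = 1)
    expect_equal(countParameters(m), inDim * w + w + w * K + K)
  }
  # growing in_dim by 642 raises the count by exactly 642 * firstWidth
  cfg <- modelConfig("gcn", nClasses = K, hidden = c(32L, 16L))
  c5 <- countParameters(buildModel(cfg, 5L, seed = 1))
  c647 <- countParameters(buildModel(cfg, 647L, seed = 1))
  expect_equal(c647 - c5, 642L * 32L)
  # closed forms for 10 random configs across architectures
  set.seed(10)
  for (i in 1:10) {
    inDim <- sample(3:50, 1); K <- sample(2:9, 1)
    arch <- sample(c("gcn", "gat", "gunet"), 1)
    if (arch == "gunet") {
      w <- sample(4:20, 1); depth <- sample(1:3, 1)
      m <- buildModel(modelConfig("gunet", nClasses = K, hidden = w,
                                  depth = depth), inDim, seed = i)
      expected <- (inDim * w + w) +
        depth * (w + w * w + w) +          # p + enc GCN (W, b)
        depth * (w * w + w) +              # dec GCN
        (w * K + K)
    } else if (arch == "gat") {
      w <- sample(4:20, 1); nh <- sample(1:4, 1)
      m <- buildModel(modelConfig("gat", nClasses = K, hidden = w,
                                  heads = nh), inDim, seed = i)
      expected <- nh * (inDim * w + 2 * w) + nh * w +      # hidden layer
        nh * (nh * w * K + 2 * K) + K                      # averaged output
    } else {
      ws <- sample(4:20, 2)
      m <- buildModel(modelConfig("gcn", nClasses = K, hidden = ws),
                      inDim, seed = i)
      expected <- inDim * ws[1] + ws[1] + ws[1] * ws[2] + ws[2] +
        ws[2] * K + K
    }
    expect_equal(countParameters(m), expected)
  }
  expect_error(modelConfig("transformer", nClasses = 5L),
               "should be one of")
})

test_that("all three forwards are permutation-equivariant", {
  set.seed(21)
  g <- meshToGraph(buildIcosphere(1))
  V <- nNodes(g); d <- 6L; K <- 4L
  H <- matrix(rnorm(V * d), V, d)
  perm <- sample(V)
  e <- graphEdges(g)
  pe <- cbind(pmin(perm[e[, 1]], perm[e[, 2]]),
              pmax(perm[e[, 1]], perm[e[, 2]]))
  pe <- pe[order(pe[, 1], pe[, 2]), ]
  storage.mode(pe) <- "integer"
  gPerm <- new("VertexGraph", nodeCount = V, edges = pe)
  Hp <- H
  Hp[perm, ] <- H
  for (arch in c("gcn", "gat", "gunet")) {
    cfg <- modelConfig(arch, nClasses = K, hidden = 8L, heads = 2L,
                       depth = 2L)
    m <- buildModel(cfg, d, seed = 3)
    out <- unname(modelLogits(m, H, g))
    outP <- unname(modelLogits(m, Hp, gPerm))
    expect_equal(outP[perm, ], out, tolerance = 1e-8,
                 info = arch)
  }
})

test_that("outputs are finite and constant-input GCN stays constant on regular graphs", {
  # 2-regular ring graph
  n <- 8L
  e <- cbind(1:n, c(2:n, 1L))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), ]
  storage.mode(e) <- "integer"
  ring <- new("VertexGraph", nodeCount = n, edges = e)
  H <- matrix(1, n, 3)
  W <- matrix(rnorm(6), 3, 2)
  out <- gcnLayer(H, ring, W, c(0.5, -0.5))
  expect_true(all(is.finite(out)))
  expect_equal(out, out[rep(1L, n), ])
})

test_that("analytic gradients match finite differences for every architecture", {
  set.seed(42)
  g <- meshToGraph(buildIcosphere(1))
  V <- nNodes(g); d <- 5L; K <- 4L
  H <- matrix(rnorm(V * d), V, d)
  y <- sample(1:K, V, replace = TRUE)
  for (arch in c("gcn", "gat", "gunet")) {
    cfg <- modelConfig(arch, nClasses = K, hidden = if (arch == "gcn")
      c(8L, 6L) else 8L, heads = 3L, depth = 2L)
    model <- buildModel(cfg, d, seed = 7)
    gc <- cortexGNN:::.graphCache(g, arch)
    fw <- cortexGNN:::.forwardModel(model, H, gc, training = TRUE)
    ce <- softmaxCrossEntropy(fw$logits, y)
    gr <- cortexGNN:::.backwardModel(model, fw, ce$grad, H, gc)
    flatG <- unlist(gr, use.names = FALSE)
    p0 <- unlist(model@params, use.names = FALSE)
    idx <- sort(sample(length(p0), 40))
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      lossAt <- function(val) {
        pp <- p0; pp[i] <- val
        m2 <- model
        m2@params <- cortexGNN:::.fillParams(model@params, pp)
        softmaxCrossEntropy(
          cortexGNN:::.forwardModel(m2, H, gc)$logits, y)$loss
      }
      (lossAt(p0[i] + eps) - lossAt(p0[i] - eps)) / (2 * eps)
    }, numeric(1L))
    relErr <- max(abs(num - flatG[idx]) /
                    pmax(1e-4, abs(num) + abs(flatG[idx])))
    expect_lt(relErr, 1e-4)
  }
})

test_that("model checkpoints round trip through JSON", {
  cfg <- modelConfig("gat", nClasses = 5L, hidden = 6L, heads = 2L)
  m <- buildModel(cfg, 7L, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_equal(m2@params, m@params, tolerance = 1e-12)
  expect_equal(m2@config@architecture, "gat")
  g <- randomGraph(9)
  H <- matrix(rnorm(63), 9, 7)
  expect_equal(modelLogits(m2, H, g), modelLogits(m, H, g),
               tolerance = 1e-10)
})
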