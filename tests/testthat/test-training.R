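# Split plans, Dice scoring, paired tests, the training loop, ablation.

test_that("97 ids split into 8 holdout and folds 18/18/18/18/17", {
  ids <- sprintf("sub-%03d", 1:97)
  plan <- makeSplits(ids, seed = 4L)
  expect_length(plan$holdout, 8L)
  expect_equal(sort(lengths(plan$folds), decreasing = TRUE),
               c(18L, 18L, 18L, 18L, 17L))
  all <- c(plan$holdout, unlist(plan$folds))
  expect_setequal(all, ids)
  expect_equal(length(all), 97L)       # pairwise disjoint
  expect_identical(makeSplits(ids, seed = 4L), plan)
  expect_false(identical(makeSplits(ids, seed = 5L)$holdout, plan$holdout))
  expect_error(makeSplits(ids[1:10], nHoldout = 8L, k = 5L), "exceeds")
})

test_that("dice matches hand-counted confusion sets and conventions", {
  expect_true(all(diceScore(1:5, 1:5)$perRegion == 1))
  expect_equal(diceScore(rep(0L, 4), rep(1L, 4))$macro, 0)
  # truth [0,0,1,1], pred [0,1,1,1]: Dice_0 = 2/3, Dice_1 = 4/5
  d <- diceScore(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L))
  expect_equal(unname(d$perRegion), c(2 / 3, 4 / 5))
  expect_equal(d$macro, 11 / 15)
  expect_error(diceScore(1:3, 1:4), "length")
  # region absent from both is skipped; unknown label excluded
  d2 <- diceScore(c(1L, 1L, 9L), c(1L, 2L, 9L), unknown = 9L)
  expect_setequal(names(d2$perRegion), c("1", "2"))
  expect_equal(unname(d2$perRegion["2"]), 0)
})

test_that("dice is symmetric and invariant to bijective relabeling", {
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:6, 40, replace = TRUE)
    b <- sample(1:6, 40, replace = TRUE)
    expect_equal(diceScore(a, b)$perRegion, diceScore(b, a)$perRegion)
    relab <- sample(101:106)
    expect_equal(diceScore(relab[a], relab[b])$macro,
                 diceScore(a, b)$macro)
  }
})

test_that("paired t-test matches the closed-form t CDF and conventions", {
  d <- c(0.1, 0.2, -0.05, 0.15, 0.1)
  a <- runif(5); b <- a - d
  res <- pairedTTest(a, b)
  tManual <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, tManual, tolerance = 1e-12)
  expect_equal(res$p, 2 * (1 - pt(abs(tManual), df = 4)),
               tolerance = 1e-12)
  expect_message(eq <- pairedTTest(a, a), "p = 1")
  expect_equal(eq$p, 1)
  expect_equal(eq$t, 0)
  expect_message(cst <- pairedTTest(a + 1, a), "machine minimum")
  expect_equal(cst$p, .Machine$double.xmin)
  expect_true(is.infinite(cst$t))
})

test_that("training solves a linearly separable toy to near-perfect Dice", {
  set.seed(6)
  # edgeless graph: S = I, so the GCN is a plain dense classifier and
  # separability guarantees an attainable perfect fit
  V <- 42L; K <- 3L
  g <- new("VertexGraph", nodeCount = V, edges = matrix(integer(), 0, 2))
  labs <- sample(1:K, V, replace = TRUE)
  oneHot <- diag(K)[labs, ] + matrix(rnorm(V * K, 0, 0.01), V, K)
  feats <- list(oneHot, diag(K)[labs, ] + matrix(rnorm(V * K, 0, 0.01), V, K))
  labsL <- list(as.integer(labs), as.integer(labs))
  fit <- trainModel(feats, labsL, g, modelConfig("gcn", nClasses = K,
                                                 hidden = 16L),
                    hyperParams(epochs = 60L, augmentSigma = 0, seed = 1L),
                    trainIdx = 1L, valIdx = 2L)
  expect_gte(tail(fit$history$trainDice, 1L), 0.99)
})

test_that("a GCN can overfit a single subject", {
  coh <- smallCohort(n = 2L, subdivisions = 2L, K = 8L,
                     connectivity = FALSE)
  subs <- cohortSubjects(coh)
  g <- meshToGraph(subjectMesh(subs[[1L]]))
  spec <- featureSpec(TRUE, TRUE, TRUE, FALSE)
  feats <- cohortMinMax(lapply(subs, assembleFeatures, spec = spec))$scaled
  labs <- lapply(subs, subjectLabels)
  fit <- trainModel(feats, labs, g,
                    modelConfig("gcn", nClasses = 8L, hidden = c(64L, 32L)),
                    hyperParams(epochs = 200L, seed = 2L),
                    trainIdx = 1L, valIdx = integer())
  expect_gte(tail(fit$history$trainDice, 1L), 0.95)
})

test_that("training is bit-identical under a fixed seed", {
  set.seed(9)
  g <- meshToGraph(buildIcosphere(1))
  V <- nNodes(g)
  labs <- list(as.integer(voronoiParcellate(g, K = 3L, seed = 2L)))
  feats <- list(matrix(runif(V * 4), V, 4))
  run <- function() trainModel(feats, labs, g,
                               modelConfig("gat", nClasses = 3L,
                                           hidden = 6L, heads = 2L),
                               hyperParams(epochs = 5L, seed = 123L),
                               trainIdx = 1L)
  f1 <- run(); f2 <- run()
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$history, f2$history)
})

test_that("the plateau scheduler reduces the learning rate on stalls", {
  set.seed(10)
  g <- meshToGraph(buildIcosphere(0))
  V <- nNodes(g)
  labs <- list(sample(1:2, V, replace = TRUE))
  feats <- list(matrix(rnorm(V * 3), V, 3))   # unlearnable noise
  fit <- trainModel(feats, labs, g,
                    modelConfig("gcn", nClasses = 2L, hidden = 4L),
                    hyperParams(epochs = 30L, lr = 1, augmentSigma = 0.5,
                                plateauPatience = 2L, seed = 3L),
                    trainIdx = 1L)
  expect_lt(tail(fit$history$lr, 1L), 1)
})

test_that("ablation emits one populated cell per spec x config", {
  coh <- smallCohort(n = 6L, subdivisions = 2L, K = 8L)
  res <- suppressMessages(runAblation(
    coh,
    specs = list(featureSpec(), featureSpec(TRUE, TRUE, TRUE, TRUE)),
    configs = list(gcn = modelConfig("gcn", nClasses = 8L,
                                     hidden = c(16L, 8L))),
    hyper = hyperParams(epochs = 8L, seed = 1L),
    nHoldout = 2L, k = 2L))
  expect_equal(nrow(res$table), 2L)
  expect_true(all(res$table$meanDice >= 0 & res$table$meanDice <= 1))
  expect_equal(res$table$folds, c(2L, 2L))
  sc <- ablationSubjectScores(res, "coords", "gcn")
  expect_length(sc, 2L)
  # identical seeds reproduce the table
  res2 <- suppressMessages(runAblation(
    coh,
    specs = list(featureSpec(), featureSpec(TRUE, TRUE, TRUE, TRUE)),
    configs = list(gcn = modelConfig("gcn", nClasses = 8L,
                                     hidden = c(16L, 8L))),
    hyper = hyperParams(epochs = 8L, seed = 1L),
    nHoldout = 2L, k = 2L))
  expect_identical(res$table, res2$table)
})
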