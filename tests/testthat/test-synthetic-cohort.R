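# Voronoi parcellation, planted morphometry, block connectivity, cohort
# determinism.

test_that("voronoi parcellation matches an exhaustive BFS oracle", {
  mesh <- buildIcosphere(1)
  graph <- meshToGraph(mesh)
  labs <- voronoiParcellate(mesh, K = 6L, seed = 11L)
  seeds <- attr(labs, "seeds")
  # independent oracle: breadth-first hop distances by frontier expansion
  adj <- lapply(seq_len(nNodes(graph)), function(i) integer())
  for (r in seq_len(nEdges(graph))) {
    e <- graphEdges(graph)[r, ]
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    adj[[e[2L]]] <- c(adj[[e[2L]]], e[1L])
  }
  bfs <- function(start) {
    dist <- rep(Inf, nNodes(graph))
    dist[start] <- 0
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- dist[frontier[1L]] + 1
      frontier <- nxt
    }
    dist
  }
  D <- t(vapply(seeds, bfs, numeric(nNodes(graph))))
  oracle <- apply(D, 2L, which.min)
  expect_equal(as.vector(labs), as.vector(oracle))
})

test_that("K=35 parcels on the 642-vertex sphere are nonempty and connected", {
  mesh <- buildIcosphere(3)
  graph <- meshToGraph(mesh)
  labs <- voronoiParcellate(mesh, K = 35L, seed = 2L)
  expect_equal(length(labs), 642L)
  expect_equal(sort(unique(labs)), 1:35)
  g <- igraph::make_graph(edges = as.vector(t(graphEdges(graph))),
                          n = nNodes(graph), directed = FALSE)
  for (k in 1:35) {
    sub <- igraph::induced_subgraph(g, which(labs == k))
    expect_true(igraph::is_connected(sub))
  }
})

test_that("degenerate parcellations behave per contract", {
  mesh <- buildIcosphere(1)
  expect_true(all(voronoiParcellate(mesh, K = 1L, seed = 1L) == 1L))
  expect_error(voronoiParcellate(mesh, K = 43L, seed = 1L), "exceeds")
})

test_that("noise-free thickness equals the region base exactly", {
  mesh <- buildIcosphere(1)
  labs <- voronoiParcellate(mesh, K = 4L, seed = 5L)
  p <- cohortParams(nSubjects = 2L, K = 4L, subdivisions = 1L,
                    ageSlope = 0, thicknessNoiseSd = 0,
                    subjectOffsetSd = 0, seed = 9L)
  fields <- cortexGNN:::.cohortFields(mesh, labs, p, 17L)
  out <- synthMorphometry(mesh, labs, age = 30, params = p, seed = 1L,
                          fields = fields)
  expect_equal(out$thickness, fields$base[labs])
})

test_that("curvature is negative on outward bumps, positive in pits", {
  coh <- smallCohort(n = 2L, connectivity = FALSE)
  s <- cohortSubjects(coh)[[1L]]
  base <- coh@metadata$baseMesh
  # radial deviation of the subject mesh reveals the displacement field
  dev <- sqrt(rowSums(meshVertices(subjectMesh(s))^2)) -
    sqrt(rowSums(meshVertices(base)^2))
  curv <- subjectCurvature(s)
  top <- order(dev, decreasing = TRUE)[1:20]    # strongest gyral crowns
  bottom <- order(dev)[1:20]                    # deepest sulcal pits
  expect_true(all(curv[top] < 0))
  expect_true(all(curv[bottom] > 0))
  expect_lt(cor(dev, curv), -0.8)
})

test_that("nonpositive thickness is clipped at 0.1 mm with a message", {
  mesh <- buildIcosphere(1)
  labs <- voronoiParcellate(mesh, K = 3L, seed = 5L)
  p <- cohortParams(nSubjects = 2L, K = 3L, subdivisions = 1L,
                    baseThicknessRange = c(0.2, 0.3), thicknessNoiseSd = 2,
                    subjectOffsetSd = 0, seed = 9L)
  expect_message(
    out <- synthMorphometry(mesh, labs, age = 30, params = p, seed = 2L),
    "clipped")
  expect_true(all(out$thickness > 0))
  expect_true(any(out$thickness == 0.1))
})

test_that("noise-free connectivity is block-constant and symmetric at region level", {
  mesh <- buildIcosphere(1)
  labs <- voronoiParcellate(mesh, K = 4L, seed = 5L)
  p <- cohortParams(nSubjects = 2L, K = 4L, subdivisions = 1L,
                    connNoiseSd = 0, seed = 9L)
  tpl <- cortexGNN:::.connTemplate(4L, p, 13L)
  expect_equal(tpl, t(tpl))
  expect_true(all(tpl >= 0))
  expect_true(all(diag(tpl) > max(tpl - diag(diag(tpl)))))
  M <- synthConnectivity(labs, p, seed = 1L, template = tpl)
  for (a in 1:4) for (b in 1:4) {
    block <- M[labs == a, labs == b]
    expect_true(all(block == tpl[a, b]))
  }
})

test_that("each vertex row has its maximum-mean block in its own region", {
  coh <- smallCohort(n = 2L)
  s <- cohortSubjects(coh)[[1L]]
  labs <- subjectLabels(s)
  conn <- subjectConnectivity(s)
  low <- coh@metadata$left$lowresLabels
  blockMeans <- vapply(1:35, function(k)
    rowMeans(conn[, low == k, drop = FALSE]), numeric(nrow(conn)))
  expect_equal(max.col(blockMeans, ties.method = "first"), as.vector(labs))
})

test_that("nearest-centroid on raw connectivity rows recovers >= 90% of labels", {
  coh <- smallCohort(n = 2L)
  s <- cohortSubjects(coh)[[1L]]
  labs <- as.vector(subjectLabels(s))
  conn <- subjectConnectivity(s)
  centroids <- t(vapply(1:35, function(k)
    colMeans(conn[labs == k, , drop = FALSE]), numeric(ncol(conn))))
  pred <- apply(conn, 1L, function(r)
    which.min(colSums((t(centroids) - r)^2)))
  expect_gte(mean(pred == labs), 0.9)
})

test_that("cohorts are deterministic under the master seed and vary across seeds", {
  p <- cohortParams(nSubjects = 3L, subdivisions = 1L, K = 5L, seed = 21L)
  c1 <- suppressMessages(generateCohort(p))
  c2 <- suppressMessages(generateCohort(p))
  expect_identical(
    lapply(cohortSubjects(c1), subjectThickness),
    lapply(cohortSubjects(c2), subjectThickness))
  expect_identical(cohortDemographics(c1), cohortDemographics(c2))
  c3 <- suppressMessages(generateCohort(
    cohortParams(nSubjects = 3L, subdivisions = 1L, K = 5L, seed = 22L)))
  expect_false(identical(subjectThickness(cohortSubjects(c1)[[1L]]),
                         subjectThickness(cohortSubjects(c3)[[1L]])))
})

test_that("cohort invariants: default size, shared demographics, age range", {
  expect_equal(cohortParams()$nSubjects, 97L)
  expect_error(cohortParams(nSubjects = 1L), ">= 2")
  p <- cohortParams(nSubjects = 4L, subdivisions = 1L, K = 5L,
                    hemispheres = c("left", "right"), seed = 8L)
  coh <- suppressMessages(generateCohort(p))
  expect_length(cohortSubjects(coh), 8L)
  demo <- cohortDemographics(coh)
  expect_equal(nrow(demo), 4L)
  expect_true(all(demo$age >= 22 & demo$age <= 35))
  expect_true(all(demo$mmse %in% 28:30))
  # left/right records of one individual share demographics
  left <- cohortSubjects(cohortHemisphere(coh, "left"))
  right <- cohortSubjects(cohortHemisphere(coh, "right"))
  expect_equal(vapply(left, function(s) s@age, 0),
               vapply(right, function(s) s@age, 0))
})

test_that("cohort-mean thickness vs age lands in the Fisher interval of r = -0.35", {
  # analytic 95% sampling interval of r at the planted population value
  coh <- smallCohort(n = 97L, seed = 5L, connectivity = FALSE)
  tbl <- regionFeatureTable(coh, "thickness")
  demo <- cohortDemographics(coh)
  r <- correlateRegions(tbl, setNames(demo$age, demo$subject))$overall$r
  zBounds <- atanh(-0.35) + c(-1, 1) * qnorm(0.975) / sqrt(97 - 3)
  expect_gte(r, tanh(zBounds[1L]))
  expect_lte(r, tanh(zBounds[2L]))
})
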