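# Region aggregation, demographic correlation, Bonferroni control,
# segmentation-source comparison, age-prediction RMSE.

test_that("region means follow the arithmetic and absence contract", {
  expect_equal(regionMeans(c(1, 1, 3, 3), c(1L, 1L, 2L, 2L)), c(1, 3))
  # region with no vertices is NA (absent), not zero
  m <- regionMeans(c(1, 2), c(1L, 3L), K = 3L)
  expect_true(is.na(m[2L]))
  expect_error(regionMeans(1:3, 1:2), "length")
})

test_that("two hemispheres at K = 35 give a length-70 feature vector", {
  coh <- smallCohort(n = 3L, subdivisions = 2L, K = 35L,
                     connectivity = FALSE, seed = 12L)
  # duplicate as a right hemisphere to avoid a second heavy generation
  subs <- cohortSubjects(coh)
  right <- lapply(subs, function(s)
    corticalSubject(subjectId(s), "right", subjectMesh(s),
                    subjectLabels(s), subjectThickness(s),
                    subjectCurvature(s), age = s@age, mmse = s@mmse,
                    education = s@education))
  both <- new("CorticalCohort", subjects = c(subs, right),
              params = coh@params, metadata = coh@metadata)
  wide <- tableToWide(regionFeatureTable(both, "thickness"))
  expect_equal(dim(wide), c(3L, 70L))
})

test_that("predicted labels missing a region propagate NA, and tests skip it", {
  coh <- smallCohort(n = 3L, subdivisions = 2L, K = 8L,
                     connectivity = FALSE, seed = 12L)
  subs <- cohortSubjects(coh)
  pred <- lapply(subs, function(s) {
    l <- subjectLabels(s)
    l[l == 7L] <- 6L           # region 7 never predicted
    l
  })
  tbl <- regionFeatureTable(coh, "thickness", labelSource = pred, K = 8L)
  wide <- tableToWide(tbl)
  expect_true(all(is.na(wide[, "left_7"])))
  demo <- cohortDemographics(coh)
  expect_warning(
    res <- correlateRegions(tbl, setNames(demo$age, demo$subject)),
    "zero-variance|insufficient")
  expect_true(is.na(res$regions$r[res$regions$region == 7L]))
})

test_that("exactly linear data give r = 1 with vanishing p", {
  coh <- smallCohort(n = 6L, subdivisions = 1L, K = 5L,
                     connectivity = FALSE, seed = 13L)
  tbl <- regionFeatureTable(coh, "thickness")
  ages <- setNames(seq(22, 35, length.out = 6),
                   unique(tbl$subject))
  tbl$value <- 2 + 0.5 * ages[tbl$subject]   # exact linear relation
  res <- correlateRegions(tbl, ages)
  expect_equal(res$overall$r, 1, tolerance = 1e-12)
  expect_lt(res$overall$p, 1e-10)
  # affine rescaling leaves r unchanged (sign follows the scale)
  tbl2 <- tbl; tbl2$value <- -3 * tbl$value + 7
  expect_equal(correlateRegions(tbl2, ages)$overall$r, -1,
               tolerance = 1e-12)
})

test_that("permuted covariates produce a calibrated null", {
  set.seed(31)
  n <- 30L
  x <- rnorm(n)
  hits <- 0L
  for (i in 1:1000) {
    p <- cor.test(x, sample(rnorm(n)))$p.value
    hits <- hits + (p < 0.05)
  }
  # binomial 95% interval around 0.05 at 1000 draws
  expect_gte(hits, qbinom(0.025, 1000, 0.05))
  expect_lte(hits, qbinom(0.975, 1000, 0.05))
})

test_that("planted negative age effect is recovered on one 97-subject cohort", {
  coh <- smallCohort(n = 97L, seed = 5L, connectivity = FALSE)
  tbl <- regionFeatureTable(coh, "thickness")
  demo <- cohortDemographics(coh)
  res <- correlateRegions(tbl, setNames(demo$age, demo$subject))
  expect_lt(res$overall$r, 0)
  expect_lt(res$overall$p, 0.05)
  # MMSE near ceiling: no cohort-level association by construction
  resM <- correlateRegions(tbl, setNames(demo$mmse, demo$subject))
  expect_gt(resM$overall$p, 0.001)
})

test_that("bonferroni threshold is alpha/m with the documented guards", {
  expect_equal(bonferroniThreshold(0.05, 35), 0.05 / 35)
  expect_equal(round(bonferroniThreshold(0.05, 35), 4), 0.0014)
  expect_equal(bonferroniThreshold(0.3, 1), 0.3)
  expect_error(bonferroniThreshold(0.05, 0), "positive")
  ms <- 1:20
  expect_true(all(diff(vapply(ms, bonferroniThreshold, 0,
                              alpha = 0.05)) < 0))
})

test_that("wilcoxon comparison matches exhaustive sign enumeration at n = 6", {
  pA <- c(0.30, 0.25, 0.07, 0.52, 0.28, 0.47)
  pB <- c(0.18, 0.20, 0.10, 0.30, 0.20, 0.30)   # distinct |differences|
  res <- compareSources(pA, pB)
  d <- pA - pB
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  # enumerate all 2^6 sign assignments of the ranks
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  dist <- as.vector(signs %*% rk)
  pEnum <- min(1, 2 * min(mean(dist <= W), mean(dist >= W)))
  expect_equal(res$p, pEnum, tolerance = 1e-12)
  # identical profiles -> p = 1 by convention
  expect_message(tie <- compareSources(pA, pA), "p = 1")
  expect_equal(tie$p, 1)
  # a large constant shift is detected
  expect_lt(compareSources(pA, pA + 0.5)$p, 0.05)
})

test_that("age RMSE: mean baseline tracks the age s.d., signal is recoverable, noise floors", {
  set.seed(17)
  n <- 60L
  ages <- runif(n, 22, 35)
  # pure-noise features: every regressor at or above 0.9 * sd
  Xnoise <- matrix(rnorm(n * 10), n, 10)
  for (kind in c("mean", "ridge", "tree", "knn", "mlp")) {
    res <- agePredictionRmse(Xnoise, ages, kind = kind, seed = 2L)
    expect_gte(res$rmse, 0.9 * sd(ages))
  }
  base <- agePredictionRmse(Xnoise, ages, kind = "mean", seed = 2L)
  expect_equal(base$rmse, sd(ages), tolerance = 0.05 * sd(ages))
  # exact linear signal in one region: ridge gets well under 0.1 * sd
  Xsig <- cbind(ages * 0.5 - 3, matrix(rnorm(n * 3, sd = 0.01), n, 3))
  sig <- agePredictionRmse(Xsig, ages, kind = "ridge", seed = 2L)
  expect_lt(sig$rmse, 0.1 * sd(ages))
  # missing regions are imputed with a message
  Xmiss <- Xsig; Xmiss[3:5, 2] <- NA
  expect_message(agePredictionRmse(Xmiss, ages, kind = "ridge", seed = 2L),
                 "imputed")
})
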