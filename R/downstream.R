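# Downstream analyses: region-wise aggregation, demographic correlation
# with Bonferroni control, segmentation-source comparison, and
# cross-validated age-prediction RMSE.

#' Per-region mean of a per-vertex attribute
#'
#' @param values Numeric per-vertex attribute (e.g. thickness).
#' @param labels Integer parcel labels (1..K), same length.
#' @param K Number of regions (default: max label).
#' @return Numeric vector of length K; regions with no vertices are NA
#'   (absent), never zero.
#' @examples
#' regionMeans(c(1, 1, 3, 3), c(1, 1, 2, 2))  # 1, 3
#' @export
regionMeans <- function(values, labels, K = max(labels)) {
  if (length(values) != length(labels))
    stop("attribute and label vectors differ in length", call. = FALSE)
  vapply(seq_len(K), function(r) {
    v <- values[labels == r]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
}

#' Region-wise feature table of a cohort
#'
#' For every subject record, the mean attribute value in each of the K
#' regions of its hemisphere. The attribute is cortical thickness (mm) or
#' conductance (a vertex's mean over its 642 connectivity columns).
#' Labels come either from the reference (generated) parcellation or from
#' a supplied list of predicted label vectors, which is exactly the
#' swap-only-the-label-source design used to compare segmentation methods.
#' Missing regions are recorded as NA, not zero.
#'
#' @param cohort A \linkS4class{CorticalCohort}.
#' @param attribute "thickness" or "conductance".
#' @param labelSource "reference", or a list of integer label vectors
#'   parallel to \code{cohortSubjects(cohort)}.
#' @param K Regions per hemisphere (default: max reference label).
#' @return Long data frame (subject, hemisphere, region, value), classed
#'   "regionFeatureTable".
#' @export
regionFeatureTable <- function(cohort, attribute = c("thickness",
                                                     "conductance"),
                               labelSource = "reference", K = NULL) {
  attribute <- match.arg(attribute)
  subjects <- cohortSubjects(cohort)
  labs <- if (identical(labelSource, "reference"))
    lapply(subjects, subjectLabels)
  else {
    stopifnot(is.list(labelSource), length(labelSource) == length(subjects))
    labelSource
  }
  if (is.null(K)) K <- max(vapply(labs, max, 0L))
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    vals <- switch(attribute,
      thickness = subjectThickness(s),
      conductance = {
        conn <- subjectConnectivity(s)
        if (ncol(conn) == 0L)
          stop(sprintf("subject %s has no connectivity map", subjectId(s)),
               call. = FALSE)
        rowMeans(conn)
      })
    data.frame(subject = subjectId(s), hemisphere = subjectHemisphere(s),
               region = seq_len(K), value = regionMeans(vals, labs[[i]], K),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("regionFeatureTable", "data.frame"))
}

#' Wide subject x region matrix of a region feature table
#'
#' Columns are hemisphere-tagged regions; with K = 35 and both hemispheres
#' this is the length-70 feature vector per subject. Missing regions stay
#' NA.
#'
#' @param table A "regionFeatureTable".
#' @return Numeric matrix, subjects x (hemisphere, region) columns.
#' @export
tableToWide <- function(table) {
  ids <- unique(table$subject)
  cols <- unique(paste(table$hemisphere, table$region, sep = "_"))
  out <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
  out[cbind(match(table$subject, ids),
            match(paste(table$hemisphere, table$region, sep = "_"), cols))] <-
    table$value
  out
}

#' Region-wise Pearson correlation with a demographic covariate
#'
#' For every (hemisphere, region): Pearson r between the subjects' region
#' mean values and the covariate, with the two-sided p from the t
#' transform on n - 2 degrees of freedom. Additionally, per hemisphere, a
#' cohort-level result correlating the across-region average (regions
#' weighted equally) with the covariate. Zero-variance inputs yield NA
#' with a warning.
#'
#' @param table A "regionFeatureTable".
#' @param covariate Named numeric vector (names = subject ids) or a
#'   numeric vector parallel to \code{unique(table$subject)}.
#' @return List with \code{regions} (data frame: hemisphere, region, r, p,
#'   n) and \code{overall} (data frame: hemisphere, r, p, n).
#' @export
correlateRegions <- function(table, covariate) {
  ids <- unique(table$subject)
  if (length(ids) < 3L)
    stop("need at least 3 subjects to correlate", call. = FALSE)
  cov <- if (!is.null(names(covariate))) covariate[ids]
         else { stopifnot(length(covariate) == length(ids)); covariate }
  corOne <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(cov[ok]) == 0) {
      warning("zero-variance or insufficient data; correlation undefined",
              call. = FALSE)
      return(c(NA_real_, NA_real_, sum(ok)))
    }
    ct <- stats::cor.test(x[ok], cov[ok], method = "pearson")
    c(unname(ct$estimate), ct$p.value, sum(ok))
  }
  regionRows <- list(); overallRows <- list()
  for (h in unique(table$hemisphere)) {
    sub <- table[table$hemisphere == h, ]
    wide <- tableToWide(sub)[ids, , drop = FALSE]
    res <- t(apply(wide, 2L, corOne))
    regionRows[[h]] <- data.frame(
      hemisphere = h, region = as.integer(sub$region[seq_len(ncol(wide))]),
      r = res[, 1L], p = res[, 2L], n = as.integer(res[, 3L]),
      row.names = NULL, stringsAsFactors = FALSE)
    ov <- corOne(rowMeans(wide, na.rm = TRUE))
    overallRows[[h]] <- data.frame(hemisphere = h, r = ov[1L], p = ov[2L],
                                   n = as.integer(ov[3L]),
                                   stringsAsFactors = FALSE)
  }
  list(regions = do.call(rbind, c(regionRows, make.row.names = FALSE)),
       overall = do.call(rbind, c(overallRows, make.row.names = FALSE)))
}

#' Bonferroni-corrected significance threshold
#'
#' \code{alpha / m}; with alpha = 0.05 over m = 35 regions this is the
#' usual per-hemisphere cortical threshold 0.0014.
#'
#' @param alpha Family-wise error rate, in (0, 1].
#' @param m Number of comparisons (>= 1).
#' @return The corrected threshold.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (length(m) != 1L || !is.numeric(m) || is.na(m) || m < 1)
    stop("'m' must be a positive number of comparisons", call. = FALSE)
  if (length(alpha) != 1L || !is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  alpha / m
}

# -- age prediction -------------------------------------------------------

.fitRegressor <- function(kind, X, y) {
  switch(kind,
    mean = {
      mu <- mean(y)
      function(Xn) rep(mu, nrow(Xn))
    },
    ridge = {
      fit <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = 5)
      function(Xn) as.vector(stats::predict(fit, Xn, s = "lambda.min"))
    },
    tree = {
      df <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., data = df)
      function(Xn) stats::predict(fit, data.frame(Xn))
    },
    knn = {
      if (!requireNamespace("caret", quietly = TRUE))
        stop("the 'knn' regressor requires the caret package",
             call. = FALSE)
      fit <- caret::knnreg(X, y, k = 5)
      function(Xn) stats::predict(fit, Xn)
    },
    mlp = {
      fit <- nnet::nnet(X, y, size = 8, linout = TRUE, decay = 0.01,
                        maxit = 300, trace = FALSE)
      function(Xn) as.vector(stats::predict(fit, Xn))
    },
    stop(sprintf("unknown regressor kind '%s'", kind), call. = FALSE))
}

#' Cross-validated age-prediction RMSE from region features
#'
#' Predicts age from the subject x region feature matrix (length 70 for
#' K = 35 over two hemispheres) with a small regressor menu, reporting the
#' out-of-fold RMSE. The mean-baseline RMSE -- an out-of-fold estimate of
#' the age standard deviation -- is reported alongside as the reference a
#' useful predictor must beat. Missing regions are imputed by the
#' training-fold mean (with a message).
#'
#' @param X Subject x region matrix (e.g. from \code{\link{tableToWide}}).
#' @param ages Numeric ages, parallel to the rows of X.
#' @param kind One of "mean", "ridge", "tree", "knn", "mlp".
#' @param cvFolds Number of cross-validation folds.
#' @param seed RNG seed for the fold assignment (and stochastic fitters).
#' @return List with \code{rmse}, \code{baselineRmse}, \code{sdAge},
#'   \code{kind} and \code{folds}.
#' @export
agePredictionRmse <- function(X, ages, kind = c("ridge", "mean", "tree",
                                                "knn", "mlp"),
                              cvFolds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(ages))
  cvFolds <- .checkCount(cvFolds, "cvFolds", 2L)
  if (nrow(X) < 2L * cvFolds)
    stop("need at least 2 subjects per fold", call. = FALSE)
  set.seed(seed)
  foldId <- sample(rep(seq_len(cvFolds), length.out = nrow(X)))
  pred <- numeric(nrow(X)); base <- numeric(nrow(X))
  nImputed <- 0L
  for (f in seq_len(cvFolds)) {
    te <- foldId == f
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    mu <- colMeans(Xtr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in seq_len(ncol(X))) {
      miss <- is.na(Xtr[, j]); nImputed <- nImputed + sum(miss)
      Xtr[miss, j] <- mu[j]
      missTe <- is.na(Xte[, j]); nImputed <- nImputed + sum(missTe)
      Xte[missTe, j] <- mu[j]
    }
    model <- .fitRegressor(kind, Xtr, ages[!te])
    pred[te] <- model(Xte)
    base[te] <- mean(ages[!te])
  }
  if (nImputed > 0L)
    message(sprintf("agePredictionRmse: imputed %d missing region value(s) by training-fold means",
                    nImputed))
  list(rmse = .rmse(ages, pred), baselineRmse = .rmse(ages, base),
       sdAge = stats::sd(ages), kind = kind, folds = cvFolds)
}
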