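# Synthetic cohort generation and cohort disk I/O.

#' Parameters of the synthetic cortical cohort
#'
#' Returns the validated parameter list controlling
#' \code{\link{generateCohort}}. The defaults emulate the statistical
#' structure of a healthy young-adult cohort: 97 individuals aged 22-35,
#' 35 parcels per hemisphere on a 642-vertex (subdivision-3 icosphere)
#' surface, thickness with a planted negative age slope calibrated so the
#' population-level correlation of cohort-mean thickness with age is
#' \code{targetAgeCorrelation} (default -0.35), near-ceiling MMSE (28-30,
#' making MMSE correlations null by construction), and block-structured
#' nonnegative conductance maps whose noise is well below the
#' within/between-region contrast.
#'
#' When \code{subjectOffsetSd} is NULL it is derived from the target
#' correlation: with ages uniform on \code{ageRange} the cohort-mean
#' thickness has slope variance \code{beta^2 var(age)}, vertex-noise
#' variance \code{sd_th^2 / V}, and subject-offset variance \code{s^2}; the
#' offset s.d. is solved so that
#' \code{r = beta sd(age) / sqrt(beta^2 var(age) + s^2 + sd_th^2/V)} equals
#' the target.
#'
#' @param nSubjects Number of individuals (default 97).
#' @param K Parcels per hemisphere (default 35).
#' @param subdivisions Icosphere subdivision level (default 3, V = 642).
#' @param radius Mesh radius, mm.
#' @param hemispheres Character subset of c("left", "right").
#' @param ageRange Uniform age range in years.
#' @param ageSlope Planted thickness-age slope, mm/year, negative; scalar
#'   or per-region vector (recycled to K).
#' @param targetAgeCorrelation Population-level thickness-age Pearson r.
#' @param thicknessNoiseSd Vertex-level thickness noise s.d., mm.
#' @param subjectOffsetSd Subject-level thickness offset s.d., mm (NULL =
#'   derive from \code{targetAgeCorrelation}).
#' @param baseThicknessRange Range of per-region thickness baselines, mm.
#' @param bumpAmplitude Radial displacement amplitude of gyral/sulcal
#'   bumps, mm.
#' @param bumpWidth Bump kernel width in graph hops.
#' @param curvatureScale Curvature magnitude at a full bump, 1/mm.
#' @param curvatureNoiseSd Curvature noise s.d., 1/mm.
#' @param rotationSd Per-subject rigid rotation angle s.d., radians.
#' @param coordNoiseSd Per-vertex radial coordinate noise s.d., mm.
#' @param connWithin,connBetween Within-region conductance strength and
#'   upper bound of between-region strengths (arbitrary conductance units).
#' @param connNoiseSd Conductance noise s.d. (same units).
#' @param connectivity Generate connectivity maps? (Set FALSE for cheap
#'   morphometry-only cohorts.)
#' @param mmseValues,mmseProbs Discrete MMSE distribution.
#' @param eduValues,eduProbs Discrete education-years distribution.
#' @param seed Master seed; all per-subject seeds derive from it via
#'   \code{\link{deriveSeed}}.
#' @return A classed list of parameters.
#' @export
cohortParams <- function(nSubjects = 97L, K = 35L, subdivisions = 3L,
                         radius = 50, hemispheres = "left",
                         ageRange = c(22, 35), ageSlope = -0.03,
                         targetAgeCorrelation = -0.35,
                         thicknessNoiseSd = 0.3, subjectOffsetSd = NULL,
                         baseThicknessRange = c(1.5, 4.5),
                         bumpAmplitude = 2, bumpWidth = 2,
                         curvatureScale = 0.3, curvatureNoiseSd = 0.02,
                         rotationSd = 0.05, coordNoiseSd = 0.5,
                         connWithin = 2, connBetween = 0.5,
                         connNoiseSd = 0.1, connectivity = TRUE,
                         mmseValues = 28:30, mmseProbs = c(0.2, 0.3, 0.5),
                         eduValues = 12:21,
                         eduProbs = c(0.08, 0.08, 0.12, 0.12, 0.2, 0.15,
                                      0.1, 0.06, 0.05, 0.04),
                         seed = 1L) {
  nSubjects <- .checkCount(nSubjects, "nSubjects", min = 2L)
  K <- .checkCount(K, "K", min = 1L)
  subdivisions <- .checkCount(subdivisions, "subdivisions")
  stopifnot(all(hemispheres %in% c("left", "right")), length(hemispheres) >= 1L)
  if (any(ageSlope > 0))
    warning("positive 'ageSlope' plants a thickness increase with age")
  V <- 10L * 4L^subdivisions + 2L
  ageMean <- mean(ageRange)
  ageVar <- diff(ageRange)^2 / 12
  if (is.null(subjectOffsetSd)) {
    beta <- mean(rep_len(ageSlope, K))
    need <- (beta * sqrt(ageVar) / abs(targetAgeCorrelation))^2
    s2 <- need - beta^2 * ageVar - thicknessNoiseSd^2 / V
    subjectOffsetSd <- sqrt(max(s2, 1e-8))
  }
  p <- list(nSubjects = nSubjects, K = K, subdivisions = subdivisions,
            radius = radius, hemispheres = hemispheres, ageRange = ageRange,
            ageMean = ageMean, ageSlope = ageSlope,
            targetAgeCorrelation = targetAgeCorrelation,
            thicknessNoiseSd = thicknessNoiseSd,
            subjectOffsetSd = subjectOffsetSd,
            baseThicknessRange = baseThicknessRange,
            bumpAmplitude = bumpAmplitude, bumpWidth = bumpWidth,
            curvatureScale = curvatureScale,
            curvatureNoiseSd = curvatureNoiseSd, rotationSd = rotationSd,
            coordNoiseSd = coordNoiseSd, connWithin = connWithin,
            connBetween = connBetween, connNoiseSd = connNoiseSd,
            connectivity = isTRUE(connectivity), mmseValues = mmseValues,
            mmseProbs = mmseProbs, eduValues = eduValues,
            eduProbs = eduProbs, seed = .checkCount(seed, "seed", min = 0L))
  class(p) <- c("CohortParams", "list")
  p
}

#' Generate a fully synthetic cortical cohort
#'
#' Deterministic given the master seed: cohort-level draws (parcellation,
#' region thickness baselines, bump amplitudes, connectivity template,
#' demographics) and per-subject draws (morphometry, connectivity noise,
#' mesh jitter) each use child seeds derived via \code{\link{deriveSeed}},
#' so any subject can be regenerated independently. Left and right
#' hemisphere records of one individual share age/MMSE/education.
#'
#' @param params A \code{\link{cohortParams}} list.
#' @return A \linkS4class{CorticalCohort}.
#' @examples
#' coh <- generateCohort(cohortParams(nSubjects = 3, subdivisions = 1,
#'                                    K = 5, connectivity = FALSE))
#' coh
#' @export
generateCohort <- function(params = cohortParams()) {
  stopifnot(inherits(params, "CohortParams"))
  if (params$nSubjects < 2L)
    stop("'nSubjects' must be at least 2", call. = FALSE)
  n <- params$nSubjects
  baseMesh <- buildIcosphere(params$subdivisions, radius = params$radius)
  master <- params$seed

  # fsaverage3 column grid for connectivity (identical to the cohort mesh
  # when subdivisions = 3)
  lowMesh <- if (params$subdivisions == 3L) baseMesh else buildIcosphere(3L)

  set.seed(deriveSeed(master, 0L, 1L))
  ages <- stats::runif(n, params$ageRange[1L], params$ageRange[2L])
  mmse <- sample(params$mmseValues, n, replace = TRUE, prob = params$mmseProbs)
  edu <- sample(params$eduValues, n, replace = TRUE, prob = params$eduProbs)

  metadata <- list(baseMesh = baseMesh)
  subjects <- list()
  for (h in seq_along(params$hemispheres)) {
    hemi <- params$hemispheres[h]
    labels <- voronoiParcellate(baseMesh, params$K,
                                seed = deriveSeed(master, 0L, 10L + h))
    lowresLabels <- if (params$subdivisions == 3L) labels else
      voronoiParcellate(lowMesh, params$K,
                        seed = deriveSeed(master, 0L, 10L + h))
    fields <- .cohortFields(baseMesh, labels, params,
                            deriveSeed(master, 0L, 20L + h))
    template <- if (params$connectivity)
      .connTemplate(params$K, params, deriveSeed(master, 0L, 30L + h))
    metadata[[hemi]] <- list(labels = labels, lowresLabels = lowresLabels,
                             fields = fields, template = template)
    for (i in seq_len(n)) {
      morpho <- synthMorphometry(baseMesh, labels, ages[i], params,
                                 seed = deriveSeed(master, i, 3L * h),
                                 fields = fields)
      conn <- if (params$connectivity)
        synthConnectivity(labels, params,
                          seed = deriveSeed(master, i, 3L * h + 1L),
                          template = template, lowresLabels = lowresLabels)
      mesh <- .jitterMesh(baseMesh, morpho$field, params,
                          seed = deriveSeed(master, i, 3L * h + 2L))
      subjects[[length(subjects) + 1L]] <- corticalSubject(
        id = sprintf("sub-%03d", i), hemisphere = hemi, mesh = mesh,
        labels = labels, thickness = morpho$thickness,
        curvature = morpho$curvature, connectivity = conn,
        age = ages[i], mmse = mmse[i], education = edu[i])
    }
  }
  new("CorticalCohort", subjects = subjects, params = unclass(params),
      metadata = metadata)
}

# -- cohort disk I/O ------------------------------------------------------

#' Write / read a cohort directory
#'
#' \code{writeCohort} lays a cohort out as a manifest CSV
#' (\code{subject_id, hemisphere, age, mmse, education} plus file-path
#' columns) and per-subject files in the package's surface formats:
#' FreeSurfer binary surfaces, curv overlays for thickness/curvature,
#' annot label files, and header-carrying dense text matrices for
#' connectivity. \code{readCohort} reconstructs the
#' \linkS4class{CorticalCohort}.
#'
#' @param cohort A \linkS4class{CorticalCohort}.
#' @param dir Target/source directory.
#' @return \code{writeCohort}: the directory, invisibly;
#'   \code{readCohort}: a \linkS4class{CorticalCohort}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohortSubjects(cohort), function(s) {
    stem <- sprintf("%s_%s", subjectId(s),
                    if (subjectHemisphere(s) == "left") "lh" else "rh")
    paths <- list(surface = sprintf("%s.surf", stem),
                  labels = sprintf("%s.annot", stem),
                  thickness = sprintf("%s.thickness", stem),
                  curvature = sprintf("%s.curv", stem),
                  connectivity = sprintf("%s.conn.txt", stem))
    writeSurface(subjectMesh(s), file.path(dir, paths$surface))
    writeLabels(subjectLabels(s), file.path(dir, paths$labels),
                K = max(subjectLabels(s)))
    writeOverlay(subjectThickness(s), file.path(dir, paths$thickness),
                 format = "curv", nFaces = nFaces(subjectMesh(s)))
    writeOverlay(subjectCurvature(s), file.path(dir, paths$curvature),
                 format = "curv", nFaces = nFaces(subjectMesh(s)))
    hasConn <- ncol(subjectConnectivity(s)) > 0L
    if (hasConn)
      writeConnectivity(subjectConnectivity(s),
                        file.path(dir, paths$connectivity))
    data.frame(subject_id = subjectId(s),
               hemisphere = subjectHemisphere(s), age = s@age,
               mmse = s@mmse, education = s@education,
               surface = paths$surface, labels = paths$labels,
               thickness = paths$thickness, curvature = paths$curvature,
               connectivity = if (hasConn) paths$connectivity else "",
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mesh <- readSurface(file.path(dir, row$surface))
    conn <- if (nzchar(row$connectivity))
      readConnectivity(file.path(dir, row$connectivity))
    corticalSubject(
      id = row$subject_id, hemisphere = row$hemisphere, mesh = mesh,
      labels = readLabels(file.path(dir, row$labels), mesh = mesh),
      thickness = readOverlay(file.path(dir, row$thickness), mesh = mesh),
      curvature = readOverlay(file.path(dir, row$curvature), mesh = mesh),
      connectivity = conn, age = row$age, mmse = row$mmse,
      education = row$education)
  })
  new("CorticalCohort", subjects = subjects, params = list(),
      metadata = list())
}
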