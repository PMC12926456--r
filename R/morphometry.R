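# Synthetic per-vertex morphometry: thickness with a planted age effect and
# signed curvature derived from a smooth radial bump field.

# Cohort-level morphometry fields shared by all subjects of one hemisphere:
# per-region thickness baselines, per-region bump amplitudes (sign decides
# gyrus vs sulcus), and hop distances from each region seed.
.cohortFields <- function(mesh, labels, params, seed) {
  K <- max(labels)
  graph <- meshToGraph(mesh)
  seeds <- attr(labels, "seeds")
  if (is.null(seeds)) {
    # one representative vertex per region when seeds were not recorded
    seeds <- vapply(seq_len(K), function(k) which(labels == k)[1L], 0L)
  }
  set.seed(seed)
  base <- stats::runif(K, params$baseThicknessRange[1L],
                       params$baseThicknessRange[2L])
  sign <- sample(c(-1, 1), K, replace = TRUE)
  amp <- sign * params$bumpAmplitude * stats::runif(K, 0.6, 1)
  list(base = base, bumpAmp = amp, seedDist = .seedDistances(graph, seeds))
}

# Smooth radial bump field (mm): positive = outward displacement (gyral
# crown), negative = inward (sulcal pit).
.bumpField <- function(fields, params) {
  w <- params$bumpWidth
  kern <- exp(-fields$seedDist^2 / (2 * w^2))     # K x V
  as.vector(fields$bumpAmp %*% kern)
}

#' Generate synthetic thickness and curvature for one subject
#'
#' Thickness at vertex v is
#' \code{base(label(v)) + slope(label(v)) * (age - ageMean) + u + e(v)},
#' where \code{base} are per-region baselines drawn once per cohort in a
#' plausible range (default 1.5-4.5 mm), \code{slope} is the planted
#' (negative) age slope in mm/year, \code{u} is a subject-level offset
#' capturing between-subject thickness variation, and \code{e} is i.i.d.
#' vertex noise. Values falling at or below zero are clipped at 0.1 mm
#' (with a message). Curvature is derived from a smooth radial bump field:
#' outward-displaced vertices (gyral crowns) receive negative curvature,
#' inward-displaced vertices (sulcal pits) positive, on top of the convex
#' sphere's \code{-1/radius} baseline.
#'
#' @param mesh The hemisphere \linkS4class{SurfaceMesh}.
#' @param labels Integer parcel labels (1..K) for the mesh.
#' @param age Subject age in years.
#' @param params A \code{\link{cohortParams}} list.
#' @param seed Subject-level RNG seed.
#' @param fields Optional precomputed cohort-level fields (from the cohort
#'   generator); derived deterministically from \code{params$seed} when
#'   absent.
#' @return List with \code{thickness} (mm), \code{curvature} (1/mm),
#'   \code{field} (radial displacement, mm) and \code{subjectOffset} (mm).
#' @export
synthMorphometry <- function(mesh, labels, age, params, seed, fields = NULL) {
  V <- nVertices(mesh)
  stopifnot(length(labels) == V)
  if (is.null(fields))
    fields <- .cohortFields(mesh, labels, params,
                            deriveSeed(params$seed, 0L, 99L))
  K <- max(labels)
  slope <- rep_len(params$ageSlope, K)
  set.seed(seed)
  subjectOffset <- stats::rnorm(1L, 0, params$subjectOffsetSd)
  thickness <- fields$base[labels] +
    slope[labels] * (age - params$ageMean) +
    subjectOffset +
    stats::rnorm(V, 0, params$thicknessNoiseSd)
  nClip <- sum(thickness <= 0)
  if (nClip > 0L) {
    message(sprintf("synthMorphometry: clipped %d nonpositive thickness value(s) at 0.1 mm",
                    nClip))
    thickness[thickness <= 0] <- 0.1
  }
  field <- .bumpField(fields, params)
  curvature <- -params$curvatureScale * field / params$bumpAmplitude -
    1 / params$radius +
    stats::rnorm(V, 0, params$curvatureNoiseSd)
  list(thickness = thickness, curvature = curvature, field = field,
       subjectOffset = subjectOffset)
}

# Subject-specific mesh: base sphere displaced radially by the bump field
# plus vertex noise, then rigidly rotated by small random angles. Gives
# every subject its own coordinate realization (the real cohort's meshes
# live in native space) while preserving the shared graph topology.
.jitterMesh <- function(baseMesh, field, params, seed) {
  v <- meshVertices(baseMesh)
  r <- sqrt(rowSums(v^2))
  dirs <- v / r
  set.seed(seed)
  newR <- r + field + stats::rnorm(nrow(v), 0, params$coordNoiseSd)
  ang <- stats::rnorm(3L, 0, params$rotationSd)
  cx <- cos(ang[1L]); sx <- sin(ang[1L])
  cy <- cos(ang[2L]); sy <- sin(ang[2L])
  cz <- cos(ang[3L]); sz <- sin(ang[3L])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  coords <- (dirs * newR) %*% t(Rz %*% Ry %*% Rx)
  colnames(coords) <- c("x", "y", "z")
  surfaceMesh(coords, meshFaces(baseMesh))
}
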