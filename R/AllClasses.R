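#' @import methods
NULL

# SurfaceMesh -------------------------------------------------------------

#' SurfaceMesh: a triangular cortical surface
#'
#' Holds vertex coordinates (mm, RAS convention) and the triangle list of a
#' cortical surface mesh. Faces index vertices 1-based, the native R
#' convention; file dialects that store 0-based indices (FreeSurfer binary
#' surfaces, OFF) are converted at the I/O boundary.
#'
#' @slot vertices numeric matrix, V x 3, columns x/y/z in mm.
#' @slot faces integer matrix, F x 3, 1-based vertex indices.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    msg <- character()
    if (ncol(v) != 3L) msg <- c(msg, "vertices must have 3 columns")
    if (ncol(f) != 3L && nrow(f) > 0L) msg <- c(msg, "faces must have 3 columns")
    if (nrow(f) > 0L) {
      if (any(f < 1L) || any(f > nrow(v)))
        msg <- c(msg, "face indices must lie in [1, V]")
      if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
        msg <- c(msg, "faces must not repeat a vertex")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a SurfaceMesh
#'
#' @param vertices numeric V x 3 matrix of coordinates (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @return A \linkS4class{SurfaceMesh}.
#' @examples
#' m <- surfaceMesh(diag(3), matrix(1:3, 1))
#' nVertices(m)
#' @export
surfaceMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  if (length(faces) == 0L) faces <- matrix(integer(), 0L, 3L)
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces)
}

#' @describeIn surfaceMesh Number of vertices.
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @describeIn surfaceMesh Number of triangular faces.
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @describeIn surfaceMesh Vertex coordinate matrix (V x 3).
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn surfaceMesh Face index matrix (F x 3, 1-based).
#' @export
meshFaces <- function(mesh) mesh@faces

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nVertices(object), nFaces(object)))
})

# VertexGraph -------------------------------------------------------------

#' VertexGraph: the unweighted graph of a surface mesh
#'
#' A simple undirected graph over mesh vertices: one node per vertex, one
#' edge per unique triangle edge. No self-loops, no multi-edges; edges are
#' stored once with the smaller index first.
#'
#' @slot nodeCount integer, number of nodes.
#' @slot edges integer matrix, E x 2, each row an unordered pair (i < j).
#' @export
setClass("VertexGraph",
  representation(nodeCount = "integer", edges = "matrix"),
  validity = function(object) {
    e <- object@edges
    msg <- character()
    if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > object@nodeCount))
        msg <- c(msg, "edge endpoints must lie in [1, nodeCount]")
      if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
      if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "edges must be stored (i < j)")
      if (anyDuplicated(e)) msg <- c(msg, "duplicate edges are not allowed")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn meshToGraph Number of nodes.
#' @export
nNodes <- function(graph) graph@nodeCount

#' @describeIn meshToGraph Number of undirected edges.
#' @export
nEdges <- function(graph) nrow(graph@edges)

#' @describeIn meshToGraph Edge matrix (E x 2, i < j).
#' @export
graphEdges <- function(graph) graph@edges

#' @describeIn meshToGraph Per-node degree vector.
#' @export
nodeDegrees <- function(graph) {
  tabulate(c(graph@edges[, 1L], graph@edges[, 2L]), nbins = graph@nodeCount)
}

setMethod("show", "VertexGraph", function(object) {
  cat(sprintf("VertexGraph: %d nodes, %d edges\n",
              nNodes(object), nEdges(object)))
})

# Convert to an igraph object (used for shortest-path queries).
.asIgraph <- function(graph) {
  igraph::make_graph(edges = as.vector(t(graph@edges)),
                     n = graph@nodeCount, directed = FALSE)
}

# FeatureSpec -------------------------------------------------------------

#' FeatureSpec: which attributes enter the per-vertex feature vector
#'
#' The feature ablation switches: vertex coordinates (3 columns), cortical
#' thickness (1), mean curvature (1), and the dense conductance connectivity
#' vector (642 columns on the fsaverage3 grid). At least one flag must be
#' set. The assembled dimension is
#' \code{3*coords + thickness + curvature + 642*conductance}.
#'
#' @slot coords,thickness,curvature,conductance logical flags.
#' @export
setClass("FeatureSpec",
  representation(coords = "logical", thickness = "logical",
                 curvature = "logical", conductance = "logical"),
  validity = function(object) {
    if (!any(object@coords, object@thickness, object@curvature,
             object@conductance))
      "at least one feature flag must be set" else TRUE
  })

#' Construct a FeatureSpec
#'
#' @param coords Include the (x, y, z) vertex coordinates.
#' @param thickness Include cortical thickness (mm).
#' @param curvature Include signed mean curvature (1/mm).
#' @param conductance Include the length-642 conductance connectivity vector.
#' @return A \linkS4class{FeatureSpec}.
#' @examples
#' featureDim(featureSpec(conductance = TRUE))  # 3 + 642
#' @export
featureSpec <- function(coords = TRUE, thickness = FALSE, curvature = FALSE,
                        conductance = FALSE) {
  new("FeatureSpec", coords = isTRUE(coords), thickness = isTRUE(thickness),
      curvature = isTRUE(curvature), conductance = isTRUE(conductance))
}

#' @describeIn featureSpec Dimension of the assembled feature vector.
#' @param spec A \linkS4class{FeatureSpec}.
#' @param conductanceCols Number of connectivity columns (642 on fsaverage3).
#' @export
featureDim <- function(spec, conductanceCols = 642L) {
  3L * spec@coords + spec@thickness + spec@curvature +
    as.integer(conductanceCols) * spec@conductance
}

#' @describeIn featureSpec Short human-readable tag, e.g. "coords+conductance".
#' @export
featureSetLabel <- function(spec) {
  paste(c("coords", "thickness", "curvature", "conductance")[
    c(spec@coords, spec@thickness, spec@curvature, spec@conductance)],
    collapse = "+")
}

setMethod("show", "FeatureSpec", function(object) {
  cat(sprintf("FeatureSpec: %s (d = %d)\n", featureSetLabel(object),
              featureDim(object)))
})

# CorticalSubject ---------------------------------------------------------

#' CorticalSubject: one hemisphere of one individual
#'
#' Bundles the per-hemisphere data of a subject: the pial-surface mesh, the
#' parcellation labels (integer 1..K), per-vertex thickness (mm) and signed
#' mean curvature (1/mm), the dense V x 642 conductance connectivity map,
#' and the (hemisphere-shared) demographics.
#'
#' @slot id character subject identifier.
#' @slot hemisphere "left" or "right".
#' @slot mesh the subject's \linkS4class{SurfaceMesh}.
#' @slot labels integer vector of parcel labels (length V).
#' @slot thickness numeric vector, mm (length V, positive).
#' @slot curvature numeric vector, 1/mm, negative on gyral crowns.
#' @slot connectivity numeric matrix V x 642 of nonnegative conductances
#'   (0-column matrix when connectivity was not generated/loaded).
#' @slot age numeric, years.
#' @slot mmse integer, Mini-Mental State Exam score (0-30).
#' @slot education numeric, years of education.
#' @export
setClass("CorticalSubject",
  representation(id = "character", hemisphere = "character",
                 mesh = "SurfaceMesh", labels = "integer",
                 thickness = "numeric", curvature = "numeric",
                 connectivity = "matrix", age = "numeric",
                 mmse = "integer", education = "numeric"),
  validity = function(object) {
    v <- nVertices(object@mesh)
    msg <- character()
    if (!object@hemisphere %in% c("left", "right"))
      msg <- c(msg, "hemisphere must be 'left' or 'right'")
    for (fld in c("labels", "thickness", "curvature")) {
      if (length(slot(object, fld)) != v)
        msg <- c(msg, sprintf("%s must have one value per vertex (%d)", fld, v))
    }
    if (ncol(object@connectivity) > 0L && nrow(object@connectivity) != v)
      msg <- c(msg, "connectivity must have one row per vertex")
    if (ncol(object@connectivity) > 0L && any(object@connectivity < 0))
      msg <- c(msg, "conductance values must be nonnegative")
    if (any(object@thickness <= 0)) msg <- c(msg, "thickness must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a CorticalSubject
#'
#' @param id Subject identifier.
#' @param hemisphere "left" or "right".
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @param labels Integer parcel labels, one per vertex.
#' @param thickness,curvature Per-vertex morphometry vectors.
#' @param connectivity V x 642 nonnegative matrix (or NULL).
#' @param age,mmse,education Demographics.
#' @return A \linkS4class{CorticalSubject}.
#' @export
corticalSubject <- function(id, hemisphere, mesh, labels, thickness, curvature,
                            connectivity = NULL, age = NA_real_,
                            mmse = NA_integer_, education = NA_real_) {
  if (is.null(connectivity))
    connectivity <- matrix(numeric(), nVertices(mesh), 0L)
  new("CorticalSubject", id = as.character(id), hemisphere = hemisphere,
      mesh = mesh, labels = as.integer(labels),
      thickness = as.numeric(thickness), curvature = as.numeric(curvature),
      connectivity = connectivity, age = as.numeric(age),
      mmse = as.integer(mmse), education = as.numeric(education))
}

#' @describeIn corticalSubject Subject identifier.
#' @param subject A \linkS4class{CorticalSubject}.
#' @export
subjectId <- function(subject) subject@id

#' @describeIn corticalSubject Hemisphere ("left"/"right").
#' @export
subjectHemisphere <- function(subject) subject@hemisphere

#' @describeIn corticalSubject Parcellation labels (integer, 1..K).
#' @export
subjectLabels <- function(subject) subject@labels

#' @describeIn corticalSubject Per-vertex thickness (mm).
#' @export
subjectThickness <- function(subject) subject@thickness

#' @describeIn corticalSubject Per-vertex signed curvature (1/mm).
#' @export
subjectCurvature <- function(subject) subject@curvature

#' @describeIn corticalSubject Connectivity map (V x 642), possibly 0-column.
#' @export
subjectConnectivity <- function(subject) subject@connectivity

#' @describeIn corticalSubject The subject's mesh.
#' @export
subjectMesh <- function(subject) subject@mesh

setMethod("show", "CorticalSubject", function(object) {
  cat(sprintf(
    "CorticalSubject %s (%s hemisphere): V = %d, %d parcels, age %.1f\n",
    object@id, object@hemisphere, nVertices(object@mesh),
    length(unique(object@labels)), object@age))
})

# CorticalCohort ----------------------------------------------------------

#' CorticalCohort: a list of subjects plus cohort-level metadata
#'
#' @slot subjects list of \linkS4class{CorticalSubject}.
#' @slot params the \code{cohortParams()} list used to generate the cohort
#'   (empty list for cohorts read from disk).
#' @slot metadata cohort-level generated quantities (parcellations, region
#'   thickness bases, connectivity templates, base mesh) keyed by hemisphere.
#' @export
setClass("CorticalCohort",
  representation(subjects = "list", params = "list", metadata = "list"),
  validity = function(object) {
    ok <- vapply(object@subjects, is, logical(1L), class2 = "CorticalSubject")
    if (!all(ok)) "all elements of subjects must be CorticalSubject" else TRUE
  })

#' @describeIn generateCohort List of \linkS4class{CorticalSubject} records.
#' @param cohort A \linkS4class{CorticalCohort}.
#' @export
cohortSubjects <- function(cohort) cohort@subjects

#' @describeIn generateCohort Subset the cohort to one hemisphere.
#' @param hemisphere "left" or "right".
#' @export
cohortHemisphere <- function(cohort, hemisphere) {
  keep <- vapply(cohort@subjects, subjectHemisphere, "") == hemisphere
  new("CorticalCohort", subjects = cohort@subjects[keep],
      params = cohort@params, metadata = cohort@metadata)
}

#' @describeIn generateCohort Unique subject ids in the cohort.
#' @export
cohortIds <- function(cohort) {
  unique(vapply(cohort@subjects, subjectId, ""))
}

#' @describeIn generateCohort Per-individual demographics table.
#' @export
cohortDemographics <- function(cohort) {
  ids <- vapply(cohort@subjects, subjectId, "")
  keep <- !duplicated(ids)
  data.frame(
    subject = ids[keep],
    age = vapply(cohort@subjects[keep], function(s) s@age, 0),
    mmse = vapply(cohort@subjects[keep], function(s) s@mmse, 0L),
    education = vapply(cohort@subjects[keep], function(s) s@education, 0),
    stringsAsFactors = FALSE)
}

setMethod("show", "CorticalCohort", function(object) {
  hemi <- table(vapply(object@subjects, subjectHemisphere, ""))
  cat(sprintf("CorticalCohort: %d subject records (%s)\n",
              length(object@subjects),
              paste(sprintf("%s: %d", names(hemi), hemi), collapse = ", ")))
})

# GNNModel ----------------------------------------------------------------

#' GNNModel: a graph neural network node classifier
#'
#' A trained (or freshly initialized) model: the architecture configuration,
#' the input feature dimension, and the parameter arrays (nested list of
#' numeric matrices/vectors). Built by \code{\link{buildModel}}.
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot inDim integer, input feature dimension.
#' @slot params nested list of numeric parameter arrays.
#' @export
setClass("GNNModel",
  representation(config = "ANY", inDim = "integer", params = "list"))

setMethod("show", "GNNModel", function(object) {
  cat(sprintf("GNNModel: %s, in_dim = %d, %d classes, %s trainable parameters\n",
              toupper(object@config@architecture), object@inDim,
              object@config@nClasses,
              format(countParameters(object), big.mark = ",")))
})

# ModelConfig -------------------------------------------------------------

#' ModelConfig: architecture family and layer sizes
#'
#' @slot architecture one of "gcn", "gat", "gunet".
#' @slot hidden integer vector of hidden widths. For "gunet" a single width
#'   is used at every level of the encoder/decoder.
#' @slot heads integer, attention heads (GAT only).
#' @slot poolRatio numeric in (0, 1], top-k pooling keep ratio (Graph U-Net).
#' @slot depth integer, number of pooling levels (Graph U-Net).
#' @slot activation activation name ("elu", "relu", "tanh", "identity").
#' @slot nClasses integer, number of output parcels K.
#' @slot dropout numeric in [0, 1), feature dropout rate during training.
#' @export
setClass("ModelConfig",
  representation(architecture = "character", hidden = "integer",
                 heads = "integer", poolRatio = "numeric", depth = "integer",
                 activation = "character", nClasses = "integer",
                 dropout = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@architecture %in% c("gcn", "gat", "gunet"))
      msg <- c(msg, "unknown architecture (use 'gcn', 'gat' or 'gunet')")
    if (any(object@hidden < 1L)) msg <- c(msg, "hidden widths must be positive")
    if (object@heads < 1L) msg <- c(msg, "heads must be >= 1")
    if (object@poolRatio <= 0 || object@poolRatio > 1)
      msg <- c(msg, "poolRatio must lie in (0, 1]")
    if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
    if (object@dropout < 0 || object@dropout >= 1)
      msg <- c(msg, "dropout must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Construct a ModelConfig
#'
#' Defaults follow the package's reference setup: two hidden layers of 512
#' and 256 units for GCN/GAT, 4 attention heads, and a narrower Graph U-Net
#' (width 128, depth 3, pool ratio 0.5) since the U-Net touches every level
#' of the pooled hierarchy.
#'
#' @param architecture "gcn", "gat" or "gunet".
#' @param nClasses Number of parcels K (output classes).
#' @param hidden Hidden widths (single width for "gunet").
#' @param heads Attention heads (GAT).
#' @param poolRatio Top-k keep ratio in (0, 1] (Graph U-Net).
#' @param depth Pooling depth (Graph U-Net).
#' @param activation Activation function name.
#' @param dropout Feature dropout rate during training.
#' @return A \linkS4class{ModelConfig}.
#' @examples
#' modelConfig("gat", nClasses = 35)
#' @export
modelConfig <- function(architecture = c("gcn", "gat", "gunet"), nClasses,
                        hidden = NULL, heads = 4L, poolRatio = 0.5,
                        depth = 3L, activation = "elu", dropout = 0) {
  architecture <- match.arg(architecture)
  if (is.null(hidden))
    hidden <- if (architecture == "gunet") 128L else c(512L, 256L)
  new("ModelConfig", architecture = architecture,
      hidden = as.integer(hidden), heads = as.integer(heads),
      poolRatio = as.numeric(poolRatio), depth = as.integer(depth),
      activation = activation, nClasses = as.integer(nClasses),
      dropout = as.numeric(dropout))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %s, hidden [%s], K = %d\n",
              toupper(object@architecture),
              paste(object@hidden, collapse = ", "), object@nClasses))
})
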