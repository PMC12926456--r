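# Icosphere generation and mesh -> graph conversion.

#' Build an icosphere mesh by recursive icosahedron subdivision
#'
#' Starts from the regular icosahedron (12 vertices, 20 faces) inscribed in
#' the unit sphere; each subdivision splits every triangle into four via
#' edge midpoints, deduplicated by exact vertex-index pairs, and projects
#' the new vertices back onto the sphere. The result has
#' \code{V = 10 * 4^s + 2} vertices and \code{F = 20 * 4^s} faces; at
#' \code{s = 3} this is the 642-vertex hemisphere grid (fsaverage3
#' resolution) on which dense connectivity maps are defined.
#'
#' @param subdivisions Nonnegative integer, at most 7.
#' @param radius Sphere radius in mm (default 50, roughly brain scale).
#' @return A \linkS4class{SurfaceMesh}.
#' @examples
#' nVertices(buildIcosphere(3))  # 642
#' @export
buildIcosphere <- function(subdivisions, radius = 50) {
  if (length(subdivisions) != 1L || !is.numeric(subdivisions) ||
      is.na(subdivisions) || subdivisions != round(subdivisions) ||
      subdivisions < 0)
    stop("'subdivisions' must be a single nonnegative integer", call. = FALSE)
  if (subdivisions > 7)
    stop("'subdivisions' > 7 refused: mesh would be excessively large",
         call. = FALSE)
  radius <- .checkScalar(radius, "radius", lower = 1e-12)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2))

  for (s in seq_len(subdivisions)) {
    # midpoint cache keyed by the exact (sorted) index pair, never by
    # floating-point coordinates
    midKey <- new.env(parent = emptyenv())
    nv <- nrow(v)
    extra <- matrix(0, 3L * nrow(f), 3L)
    nExtra <- 0L
    midpoint <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      idx <- midKey[[key]]
      if (!is.null(idx)) return(idx)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nExtra <<- nExtra + 1L
      extra[nExtra, ] <<- m
      idx <- nv + nExtra
      midKey[[key]] <- idx
      idx
    }
    newF <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4L * t - 3L, ] <- c(a, ab, ca)
      newF[4L * t - 2L, ] <- c(b, bc, ab)
      newF[4L * t - 1L, ] <- c(c, ca, bc)
      newF[4L * t,      ] <- c(ab, bc, ca)
    }
    v <- rbind(v, extra[seq_len(nExtra), , drop = FALSE])
    f <- newF
  }
  colnames(v) <- c("x", "y", "z")
  surfaceMesh(v * radius, f)
}

#' Convert a surface mesh to its unweighted vertex graph
#'
#' One node per mesh vertex, one undirected edge per unique triangle edge.
#' The result is independent of face ordering and winding; for a closed
#' triangular mesh \code{E = 3F/2}.
#'
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @return A \linkS4class{VertexGraph}.
#' @examples
#' g <- meshToGraph(buildIcosphere(0))
#' nEdges(g)  # 30, every node degree 5
#' @export
meshToGraph <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  f <- meshFaces(mesh)
  if (nrow(f) == 0L)
    return(new("VertexGraph", nodeCount = nVertices(mesh),
               edges = matrix(integer(), 0L, 2L)))
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  storage.mode(e) <- "integer"
  new("VertexGraph", nodeCount = nVertices(mesh), edges = e)
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for every closed genus-0 surface such as an icosphere.
#'
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @return Integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mesh) {
  nVertices(mesh) - nEdges(meshToGraph(mesh)) + nFaces(mesh)
}
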