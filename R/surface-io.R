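# Readers/writers for FreeSurfer binary surface, curv, and annot dialects,
# plus plain-text fallbacks (OFF meshes, one-value-per-line overlays,
# vertex_id,label CSV). FreeSurfer files are big-endian and 0-based; both
# conventions are converted at this boundary.

.TRIANGLE_MAGIC <- c(255L, 255L, 254L)
.CURV_MAGIC <- c(255L, 255L, 255L)

# -- low-level big-endian readers on a raw buffer -------------------------

.reader <- function(path) {
  n <- file.size(path)
  if (is.na(n)) stop(sprintf("file not found: %s", path), call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$raw <- readBin(path, "raw", n = n)
  env$off <- 0L
  env$path <- path
  env
}

.need <- function(rd, nbytes, what) {
  if (rd$off + nbytes > length(rd$raw))
    stop(sprintf("truncated %s in '%s': need %d bytes at byte offset %d",
                 what, rd$path, nbytes, rd$off), call. = FALSE)
}

.rdBytes <- function(rd, n, what = "bytes") {
  .need(rd, n, what)
  out <- rd$raw[rd$off + seq_len(n)]
  rd$off <- rd$off + n
  out
}

.rdInt <- function(rd, n, what = "int32") {
  .need(rd, 4L * n, what)
  out <- readBin(rd$raw[(rd$off + 1L):(rd$off + 4L * n)], "integer",
                 n = n, size = 4L, endian = "big")
  rd$off <- rd$off + 4L * n
  out
}

.rdFloat <- function(rd, n, what = "float32") {
  .need(rd, 4L * n, what)
  out <- readBin(rd$raw[(rd$off + 1L):(rd$off + 4L * n)], "numeric",
                 n = n, size = 4L, endian = "big")
  rd$off <- rd$off + 4L * n
  out
}

.wrInt <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "big")
.wrFloat <- function(con, x) writeBin(as.numeric(x), con, size = 4L, endian = "big")

# -- FreeSurfer binary surface -------------------------------------------

.readFsSurface <- function(path) {
  rd <- .reader(path)
  magic <- as.integer(.rdBytes(rd, 3L, "magic number"))
  if (!identical(magic, .TRIANGLE_MAGIC))
    stop(sprintf(
      "'%s': bad magic number [%s] at byte offset 0 (expected FreeSurfer triangle magic ff ff fe)",
      path, paste(sprintf("%02x", magic), collapse = " ")), call. = FALSE)
  # comment line terminated by "\n\n"
  prev <- as.raw(0L)
  repeat {
    b <- .rdBytes(rd, 1L, "creator comment")
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    prev <- b
  }
  vcount <- .rdInt(rd, 1L, "vertex count")
  fcount <- .rdInt(rd, 1L, "face count")
  if (vcount < 0L || fcount < 0L)
    stop(sprintf("'%s': negative vertex/face count at byte offset %d",
                 path, rd$off - 8L), call. = FALSE)
  verts <- matrix(.rdFloat(rd, 3L * vcount, "vertex coordinates"),
                  ncol = 3L, byrow = TRUE)
  faces <- matrix(.rdInt(rd, 3L * fcount, "face indices"),
                  ncol = 3L, byrow = TRUE) + 1L
  colnames(verts) <- c("x", "y", "z")
  surfaceMesh(verts, faces)
}

.writeFsSurface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(.TRIANGLE_MAGIC), con)
  writeBin(charToRaw("created by cortexGNN\n\n"), con)
  .wrInt(con, nVertices(mesh))
  .wrInt(con, nFaces(mesh))
  .wrFloat(con, as.vector(t(meshVertices(mesh))))
  .wrInt(con, as.vector(t(meshFaces(mesh))) - 1L)
  invisible(path)
}

# -- OFF text meshes ------------------------------------------------------

.readOff <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || toupper(lines[1L]) != "OFF")
    stop(sprintf("'%s': not an OFF file (missing OFF header)", path),
         call. = FALSE)
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  body <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  verts <- matrix(body[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
  rest <- body[-seq_len(3L * nv)]
  faces <- matrix(rest[seq_len(4L * nf)], ncol = 4L, byrow = TRUE)
  if (any(faces[, 1L] != 3L))
    stop(sprintf("'%s': only triangular OFF faces are supported", path),
         call. = FALSE)
  colnames(verts) <- c("x", "y", "z")
  surfaceMesh(verts, faces[, 2:4, drop = FALSE] + 1L)
}

.writeOff <- function(mesh, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nVertices(mesh), nFaces(mesh)), con)
  v <- meshVertices(mesh)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  f <- meshFaces(mesh) - 1L
  writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read / write surface meshes
#'
#' \code{readSurface} auto-detects FreeSurfer binary triangle files (by
#' their 3-byte magic number) and OFF text meshes. \code{writeSurface}
#' chooses the dialect from \code{format}, or from the file extension
#' (".off" writes OFF, anything else FreeSurfer binary).
#'
#' @param path File path.
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @param format "auto", "freesurfer" or "off".
#' @return \code{readSurface}: a \linkS4class{SurfaceMesh};
#'   \code{writeSurface}: the path, invisibly.
#' @export
readSurface <- function(path, format = c("auto", "freesurfer", "off")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 3L)
    format <- if (length(head) == 3L &&
                  identical(as.integer(head), .TRIANGLE_MAGIC))
      "freesurfer" else "off"
  }
  switch(format, freesurfer = .readFsSurface(path), off = .readOff(path))
}

#' @rdname readSurface
#' @export
writeSurface <- function(mesh, path, format = c("auto", "freesurfer", "off")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.off$", path, ignore.case = TRUE)) "off" else "freesurfer"
  switch(format, freesurfer = .writeFsSurface(mesh, path),
         off = .writeOff(mesh, path))
}

# -- curv overlays --------------------------------------------------------

#' Read / write per-vertex scalar overlays
#'
#' Supports the FreeSurfer "curv" binary dialect (new format, 3-byte magic
#' ff ff ff) and a plain-text fallback with one value per line. When a mesh
#' is supplied to \code{readOverlay}, the overlay length is validated
#' against the vertex count.
#'
#' @param path File path.
#' @param values Numeric vector, one value per vertex.
#' @param mesh Optional \linkS4class{SurfaceMesh} for length validation.
#' @param format "auto", "curv" (FreeSurfer binary) or "text".
#' @return \code{readOverlay}: numeric vector; \code{writeOverlay}: the
#'   path, invisibly.
#' @export
readOverlay <- function(path, mesh = NULL, format = c("auto", "curv", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 3L)
    format <- if (length(head) == 3L &&
                  identical(as.integer(head), .CURV_MAGIC)) "curv" else "text"
  }
  vals <- if (format == "curv") {
    rd <- .reader(path)
    magic <- as.integer(.rdBytes(rd, 3L, "magic number"))
    if (!identical(magic, .CURV_MAGIC))
      stop(sprintf(
        "'%s': bad magic number [%s] at byte offset 0 (expected curv magic ff ff ff)",
        path, paste(sprintf("%02x", magic), collapse = " ")), call. = FALSE)
    vnum <- .rdInt(rd, 1L, "vertex count")
    .rdInt(rd, 1L, "face count")
    vpv <- .rdInt(rd, 1L, "values per vertex")
    if (vpv != 1L)
      stop(sprintf("'%s': unsupported values-per-vertex %d at byte offset %d",
                   path, vpv, rd$off - 4L), call. = FALSE)
    .rdFloat(rd, vnum, "overlay values")
  } else {
    as.numeric(readLines(path))
  }
  if (!is.null(mesh) && length(vals) != nVertices(mesh))
    stop(sprintf("overlay length %d does not match mesh vertex count %d",
                 length(vals), nVertices(mesh)), call. = FALSE)
  vals
}

#' @rdname readOverlay
#' @param nFaces Face count recorded in the curv header (metadata only).
#' @export
writeOverlay <- function(values, path, format = c("auto", "curv", "text"),
                         nFaces = 0L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(txt|csv)$", path, ignore.case = TRUE))
      "text" else "curv"
  if (format == "curv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(.CURV_MAGIC), con)
    .wrInt(con, length(values))
    .wrInt(con, nFaces)
    .wrInt(con, 1L)
    .wrFloat(con, values)
  } else {
    writeLines(sprintf("%.9g", values), path)
  }
  invisible(path)
}

# -- annot label files ----------------------------------------------------

# Labels are 1..K in memory. On disk each parcel k gets the RGB-packed
# code of colortable entry k; NA vertices get code 0.
.labelColor <- function(k) {
  c(k %% 256L, (k %/% 256L) %% 256L, (k %/% 65536L) %% 256L)
}

.readFsAnnot <- function(path) {
  rd <- .reader(path)
  n <- .rdInt(rd, 1L, "vertex count")
  if (n < 0L)
    stop(sprintf("'%s': negative vertex count at byte offset 0", path),
         call. = FALSE)
  pairs <- .rdInt(rd, 2L * n, "vertex/annotation pairs")
  vert <- pairs[seq(1L, 2L * n, by = 2L)] + 1L
  code <- pairs[seq(2L, 2L * n, by = 2L)]
  codes <- integer(n)
  codes[vert] <- code
  if (rd$off >= length(rd$raw)) {        # no colortable: raw codes
    labs <- match(codes, sort(unique(codes)))
    return(as.integer(labs))
  }
  tag <- .rdInt(rd, 1L, "colortable tag")
  if (tag != 1L)
    stop(sprintf("'%s': unsupported tag %d at byte offset %d",
                 path, tag, rd$off - 4L), call. = FALSE)
  nEntries <- .rdInt(rd, 1L, "colortable entry count")
  if (nEntries < 0L)
    stop(sprintf("'%s': versioned colortables are not supported (byte offset %d)",
                 path, rd$off - 4L), call. = FALSE)
  fnLen <- .rdInt(rd, 1L, "colortable filename length")
  .rdBytes(rd, fnLen, "colortable filename")
  entryCode <- integer(nEntries)
  for (i in seq_len(nEntries)) {
    nameLen <- .rdInt(rd, 1L, "structure name length")
    .rdBytes(rd, nameLen, "structure name")
    rgba <- .rdInt(rd, 4L, "structure color")
    entryCode[i] <- rgba[1L] + rgba[2L] * 256L + rgba[3L] * 65536L
  }
  labs <- match(codes, entryCode)
  as.integer(labs)
}

.writeFsAnnot <- function(labels, path, K = max(labels, na.rm = TRUE)) {
  n <- length(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  .wrInt(con, n)
  codes <- integer(n)
  ok <- !is.na(labels)
  rgb <- vapply(seq_len(K), .labelColor, integer(3L))
  codes[ok] <- rgb[1L, labels[ok]] + rgb[2L, labels[ok]] * 256L +
    rgb[3L, labels[ok]] * 65536L
  inter <- integer(2L * n)
  inter[seq(1L, 2L * n, by = 2L)] <- seq_len(n) - 1L
  inter[seq(2L, 2L * n, by = 2L)] <- codes
  .wrInt(con, inter)
  .wrInt(con, 1L)                         # colortable tag
  .wrInt(con, K)
  fname <- "cortexGNN.ctab"
  .wrInt(con, nchar(fname))
  writeBin(charToRaw(fname), con)
  for (k in seq_len(K)) {
    name <- sprintf("parcel_%03d", k)
    .wrInt(con, nchar(name))
    writeBin(charToRaw(name), con)
    .wrInt(con, c(.labelColor(k), 0L))
  }
  invisible(path)
}

#' Read / write per-vertex parcellation labels
#'
#' Supports the FreeSurfer annot binary dialect (with an embedded
#' colortable) and a two-column \code{vertex_id,label} CSV fallback with
#' 0-based vertex ids on disk. In memory labels are integers 1..K;
#' unlabeled vertices are NA.
#'
#' @param path File path.
#' @param labels Integer label vector (1..K, NA allowed).
#' @param mesh Optional \linkS4class{SurfaceMesh} for length validation.
#' @param K Number of parcels recorded in the annot colortable.
#' @param format "auto", "annot" or "csv".
#' @return \code{readLabels}: integer vector; \code{writeLabels}: the path,
#'   invisibly.
#' @export
readLabels <- function(path, mesh = NULL, format = c("auto", "annot", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "annot"
  labs <- if (format == "annot") {
    .readFsAnnot(path)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("vertex_id", "label") %in% names(df)))
      stop(sprintf("'%s': label CSV must have columns vertex_id,label", path),
           call. = FALSE)
    out <- rep(NA_integer_, max(df$vertex_id) + 1L)
    out[df$vertex_id + 1L] <- as.integer(df$label)
    out
  }
  if (!is.null(mesh) && length(labs) != nVertices(mesh))
    stop(sprintf("label count %d does not match mesh vertex count %d",
                 length(labs), nVertices(mesh)), call. = FALSE)
  labs
}

#' @rdname readLabels
#' @export
writeLabels <- function(labels, path, K = max(labels, na.rm = TRUE),
                        format = c("auto", "annot", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "annot"
  if (format == "annot") {
    .writeFsAnnot(as.integer(labels), path, K = K)
  } else {
    utils::write.csv(
      data.frame(vertex_id = seq_along(labels) - 1L, label = labels),
      path, row.names = FALSE)
  }
  invisible(path)
}

# -- dense connectivity matrices -----------------------------------------

#' Read / write dense connectivity maps
#'
#' Plain-text layout: a header line \code{"connectivity <nrow> <ncol>"}
#' followed by one whitespace-separated row per line (row-major).
#'
#' @param path File path.
#' @param mat Numeric matrix (V x 642 conductance map).
#' @return \code{readConnectivity}: numeric matrix;
#'   \code{writeConnectivity}: the path, invisibly.
#' @export
readConnectivity <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  header <- strsplit(trimws(readLines(con, n = 1L)), "\\s+")[[1L]]
  if (length(header) != 3L || header[1L] != "connectivity")
    stop(sprintf("'%s': missing 'connectivity <nrow> <ncol>' header", path),
         call. = FALSE)
  nr <- as.integer(header[2L]); nc <- as.integer(header[3L])
  vals <- scan(con, n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("'%s': expected %d values, found %d", path, nr * nc,
                 length(vals)), call. = FALSE)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' @rdname readConnectivity
#' @export
writeConnectivity <- function(mat, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("connectivity %d %d", nrow(mat), ncol(mat)), con)
  writeLines(apply(mat, 1L, function(r) paste(sprintf("%.9g", r),
                                              collapse = " ")), con)
  invisible(path)
}
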