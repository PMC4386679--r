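# Mesh and point-cloud file I/O: PLY (ASCII + binary little-endian),
# OBJ (v/f records), STL (ASCII + binary), and plain-text point clouds.
# Face indices are 1-based in memory; OBJ files are 1-based on disk already,
# PLY files are 0-based and converted at the boundary.

.meshFormatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "stl")) ext
  else stop("cannot infer mesh format from extension: ", path)
}

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`, `"auto"` (by extension).
#' @param triangulate if TRUE (default) non-triangular faces are fan
#'   triangulated with a warning; if FALSE they are rejected.
#' @param weld for STL, merge duplicate vertices (default TRUE).
#' @return a [TriangleMesh-class]; vertices are in file units.
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj", "stl"),
                     triangulate = TRUE, weld = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") format <- .meshFormatFromPath(path)
  switch(format,
         obj = .readOBJ(path, triangulate),
         stl = .readSTL(path, weld),
         ply = .readPLY(path, triangulate))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path.
#' @param format `"ply"`, `"obj"`, `"stl"` or `"auto"` (by extension).
#' @param binary for PLY/STL, write the binary dialect (default FALSE).
#' @return invisibly, `path`.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl"),
                      binary = FALSE) {
  stopifnot(is(mesh, "TriangleMesh"))
  validObject(mesh)
  if (nVertices(mesh) == 0L) stop("refusing to write an empty mesh")
  format <- match.arg(format)
  if (format == "auto") format <- .meshFormatFromPath(path)
  switch(format,
         obj = .writeOBJ(mesh, path),
         stl = .writeSTL(mesh, path, binary),
         ply = .writePLY(mesh, path, binary))
  invisible(path)
}

.fanTriangulate <- function(polys, triangulate) {
  # polys: list of integer vectors (>= 3 vertices each)
  sizes <- lengths(polys)
  if (any(sizes > 3L)) {
    if (!triangulate) stop("non-triangular face found and triangulate = FALSE")
    warning("non-triangular faces fan-triangulated")
  }
  out <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    if (length(p) == 3L) out[[i]] <- matrix(p, 1L, 3L)
    else out[[i]] <- cbind(p[1L], p[2:(length(p) - 1L)], p[3:length(p)])
  }
  do.call(rbind, out)
}

.readOBJ <- function(path, triangulate) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  V <- if (length(vl)) {
    toks <- strsplit(trimws(sub("^v", "", vl)), "\\s+")
    t(vapply(toks, function(x) as.numeric(x[1:3]), numeric(3)))
  } else matrix(numeric(0), 0, 3)
  polys <- lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x))
    idx[idx < 0L] <- nrow(V) + 1L + idx[idx < 0L]  # negative = relative
    idx
  })
  Fm <- if (length(polys)) .fanTriangulate(polys, triangulate)
        else matrix(integer(0), 0, 3)
  TriangleMesh(V, Fm)
}

.writeOBJ <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# vessim OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh@vertices[, 1],
                     mesh@vertices[, 2], mesh@vertices[, 3]), con)
  if (nFaces(mesh))
    writeLines(sprintf("f %d %d %d", mesh@faces[, 1], mesh@faces[, 2],
                       mesh@faces[, 3]), con)
}

.weldVertices <- function(V, Fm, digits = 9) {
  key <- paste(signif(V[, 1], digits), signif(V[, 2], digits),
               signif(V[, 3], digits))
  first <- !duplicated(key)
  map <- match(key, key[first])
  TriangleMesh(V[first, , drop = FALSE],
               matrix(map[Fm], ncol = 3L))
}

.readSTL <- function(path, weld) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  ntri <- if (sz >= 84) readBin(con, "integer", 1L, 4L, endian = "little")
          else -1L
  isBinary <- (sz == 84 + 50 * ntri)
  if (isBinary) {
    rec <- readBin(con, "raw", 50L * ntri)
    close(con)
    dim(rec) <- c(50L, ntri)
    coords <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                      12L * ntri, size = 4L, endian = "little")
    m <- matrix(coords, nrow = 12L)  # nx ny nz v1 v2 v3 (xyz each)
    V <- matrix(as.vector(m[4:12, ]), ncol = 3L, byrow = TRUE)
  } else {
    close(con)
    ln <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
    toks <- strsplit(trimws(sub("vertex", "", vl)), "\\s+")
    V <- t(vapply(toks, function(x) as.numeric(x[1:3]), numeric(3)))
  }
  if (nrow(V) %% 3L != 0L) stop("corrupt STL: vertex count not divisible by 3")
  Fm <- matrix(seq_len(nrow(V)), ncol = 3L, byrow = TRUE)
  mesh <- TriangleMesh(V, Fm)
  if (weld) .weldVertices(V, Fm) else mesh
}

.writeSTL <- function(mesh, path, binary) {
  V <- mesh@vertices; Fm <- mesh@faces
  e1 <- V[Fm[, 2], ] - V[Fm[, 1], ]
  e2 <- V[Fm[, 3], ] - V[Fm[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
  n <- n / nn
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(nrow(Fm), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(Fm))) {
      writeBin(as.numeric(c(n[i, ], t(V[Fm[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid vessim", con)
    for (i in seq_len(nrow(Fm))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         V[Fm[i, ], 1], V[Fm[i, ], 2], V[Fm[i, ], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vessim", con)
  }
}

.plyTypeSize <- function(t) {
  switch(t, char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
         short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
         int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
         float = 4L, float32 = 4L, double = 8L, float64 = 8L,
         stop("unsupported PLY property type: ", t))
}
.plyTypeWhat <- function(t) {
  if (t %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
}

.parsePLYHeader <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  lines <- character(0); nbytes <- 0L
  repeat {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("unterminated PLY header")
      nbytes <- nbytes + 1L
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    line <- trimws(rawToChar(chars))
    lines <- c(lines, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format\\s+", "", grep("^format", lines, value = TRUE)[1])
  fmt <- strsplit(fmt, "\\s+")[[1]][1]
  elements <- list(); cur <- NULL
  for (line in lines) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[tok[5]]] <- list(list = TRUE, countType = tok[3],
                                    itemType = tok[4])
      else cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements, headerBytes = nbytes)
}

.readPLY <- function(path, triangulate, wantNormals = FALSE) {
  h <- .parsePLYHeader(path)
  ve <- h$elements[["vertex"]]
  fe <- h$elements[["face"]]
  if (is.null(ve)) stop("PLY file has no vertex element")
  propNames <- names(ve$props)
  if (h$format == "ascii") {
    ln <- readLines(path, warn = FALSE)
    start <- which(ln == "end_header")[1]
    body <- ln[(start + 1L):length(ln)]
    vlines <- body[seq_len(ve$count)]
    vt <- strsplit(trimws(vlines), "\\s+")
    vm <- t(vapply(vt, function(x) as.numeric(x[seq_along(propNames)]),
                   numeric(length(propNames))))
    if (length(propNames) == 1L) vm <- t(vm)
    colnames(vm) <- propNames
    polys <- list()
    if (!is.null(fe) && fe$count > 0L) {
      flines <- body[ve$count + seq_len(fe$count)]
      polys <- lapply(strsplit(trimws(flines), "\\s+"), function(x) {
        k <- as.integer(x[1])
        as.integer(x[1L + seq_len(k)]) + 1L
      })
    }
  } else if (h$format == "binary_little_endian") {
    sz <- file.info(path)$size
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", h$headerBytes)
    types <- vapply(ve$props, function(p) p$type, "")
    sizes <- vapply(types, .plyTypeSize, 1L)
    if (length(unique(types)) != 1L)
      stop("mixed vertex property types in binary PLY are not supported")
    vals <- readBin(con, .plyTypeWhat(types[1]),
                    ve$count * length(propNames), size = sizes[1],
                    endian = "little")
    vm <- matrix(vals, ncol = length(propNames), byrow = TRUE)
    colnames(vm) <- propNames
    polys <- list()
    if (!is.null(fe) && fe$count > 0L) {
      fp <- fe$props[[1]]
      polys <- vector("list", fe$count)
      for (i in seq_len(fe$count)) {
        k <- readBin(con, "integer", 1L, .plyTypeSize(fp$countType),
                     endian = "little", signed = .plyTypeSize(fp$countType) > 2)
        idx <- readBin(con, .plyTypeWhat(fp$itemType), k,
                       .plyTypeSize(fp$itemType), endian = "little")
        polys[[i]] <- as.integer(idx) + 1L
      }
    }
  } else stop("unsupported PLY format: ", h$format)
  V <- vm[, c("x", "y", "z"), drop = FALSE]
  dimnames(V) <- NULL
  if (wantNormals) {
    if (!all(c("nx", "ny", "nz") %in% colnames(vm)))
      stop("PLY file carries no nx/ny/nz normals")
    N <- vm[, c("nx", "ny", "nz"), drop = FALSE]
    dimnames(N) <- NULL
    nr <- sqrt(rowSums(N^2)); nr[nr == 0] <- 1
    return(new("OrientedPointCloud", points = V, normals = N / nr))
  }
  Fm <- if (length(polys)) .fanTriangulate(polys, triangulate)
        else matrix(integer(0), 0, 3)
  TriangleMesh(V, Fm)
}

.writePLY <- function(mesh, path, binary, normals = NULL) {
  V <- mesh@vertices; Fm <- mesh@faces
  hasN <- !is.null(normals)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment vessim export",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           if (hasN) c("property float nx", "property float ny",
                       "property float nz"),
           sprintf("element face %d", nrow(Fm)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    block <- if (hasN) cbind(V, normals) else V
    writeBin(as.numeric(t(block)), con, size = 4L, endian = "little")
    if (nrow(Fm)) for (i in seq_len(nrow(Fm))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(Fm[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    if (hasN)
      writeLines(sprintf("%.9g %.9g %.9g %.9g %.9g %.9g",
                         V[, 1], V[, 2], V[, 3],
                         normals[, 1], normals[, 2], normals[, 3]), con)
    else
      writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    if (nrow(Fm))
      writeLines(sprintf("3 %d %d %d", Fm[, 1] - 1L, Fm[, 2] - 1L,
                         Fm[, 3] - 1L), con)
  }
}

#' Read a point cloud from PLY or whitespace-delimited text
#'
#' Text files carry 3 columns (x y z) or 6 (x y z nx ny nz); PLY files must
#' carry `nx, ny, nz` vertex properties to yield normals.
#'
#' @param path file path.
#' @param format `"ply"`, `"txt"` or `"auto"` (by extension; non-PLY
#'   extensions are treated as text).
#' @return an [OrientedPointCloud-class]; for 3-column input the normals are
#'   filled with placeholder +z vectors and should be re-estimated with
#'   [estimateNormals()].
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "txt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "ply") "ply" else "txt"
  if (format == "ply") return(.readPLY(path, TRUE, wantNormals = TRUE))
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (ncol(m) == 3L) {
    N <- matrix(rep(c(0, 0, 1), each = nrow(m)), ncol = 3L)
  } else if (ncol(m) == 6L) {
    N <- m[, 4:6, drop = FALSE]
    nr <- sqrt(rowSums(N^2)); nr[nr == 0] <- 1
    N <- N / nr
  } else stop("point-cloud text file must have 3 or 6 columns")
  new("OrientedPointCloud", points = m[, 1:3, drop = FALSE], normals = N)
}

#' Write a point cloud to PLY or text
#'
#' @param cloud an [OrientedPointCloud-class].
#' @param path output path.
#' @param format `"ply"`, `"txt"` or `"auto"`.
#' @param binary write binary PLY.
#' @return invisibly, `path`.
#' @export
writePointCloud <- function(cloud, path, format = c("auto", "ply", "txt"),
                            binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "ply") "ply" else "txt"
  if (format == "ply") {
    fake <- TriangleMesh(cloud@points, matrix(integer(0), 0, 3))
    .writePLY(fake, path, binary, normals = cloud@normals)
  } else {
    m <- cbind(cloud@points, cloud@normals)
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
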