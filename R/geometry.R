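# Differential-geometry primitives shared by the contraction and rendering
# code: signed volume, cotangent Laplacian, one-ring areas, edge topology.

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rowNorm <- function(a) sqrt(rowSums(a^2))

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

#' Signed volume of a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedra to the origin: positive for a
#' closed, outward-wound mesh. Open or inconsistently wound meshes yield the
#' signed sum as-is; the contraction loop only needs a monotone shrinkage
#' measure, so that value is returned, documented, rather than rejected.
#'
#' @param mesh a [TriangleMesh-class].
#' @return signed volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; Fm <- mesh@faces
  if (nrow(Fm) == 0L) return(0)
  a <- V[Fm[, 1], , drop = FALSE]
  b <- V[Fm[, 2], , drop = FALSE]
  cc <- V[Fm[, 3], , drop = FALSE]
  sum(rowSums(a * .rowCross(b, cc))) / 6
}

#' Face areas and per-vertex one-ring areas
#'
#' The one-ring area of a vertex is the summed area of its incident faces.
#'
#' @param mesh a [TriangleMesh-class].
#' @return list with `faceAreas` (length m) and `oneRing` (length n).
#' @keywords internal
.meshAreas <- function(mesh) {
  V <- mesh@vertices; Fm <- mesh@faces
  e1 <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  e2 <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  fa <- 0.5 * .rowNorm(.rowCross(e1, e2))
  oneRing <- numeric(nrow(V))
  for (k in 1:3) {
    t <- tapply(fa, Fm[, k], sum)
    oneRing[as.integer(names(t))] <- oneRing[as.integer(names(t))] + t
  }
  list(faceAreas = fa, oneRing = oneRing)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [TriangleMesh-class].
#' @return integer e x 2 matrix, each row sorted, plus an attribute
#'   `"count"` with the number of incident faces per edge.
#' @keywords internal
.meshEdges <- function(mesh) {
  Fm <- mesh@faces
  E <- rbind(Fm[, c(1, 2)], Fm[, c(2, 3)], Fm[, c(3, 1)])
  E <- cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  key <- (E[, 1] - 1) * nrow(mesh@vertices) + E[, 2]
  first <- !duplicated(key)
  out <- E[first, , drop = FALSE]
  attr(out, "count") <- as.integer(table(factor(key, levels = key[first])))
  out
}

#' Is a mesh watertight?
#'
#' TRUE when every edge is shared by exactly two faces with consistent
#' winding (each directed half-edge appears exactly once).
#'
#' @param mesh a [TriangleMesh-class].
#' @return logical.
#' @export
isWatertight <- function(mesh) {
  Fm <- mesh@faces
  if (nrow(Fm) == 0L) return(FALSE)
  H <- rbind(Fm[, c(1, 2)], Fm[, c(2, 3)], Fm[, c(3, 1)])
  n <- nrow(mesh@vertices)
  keyDir <- (H[, 1] - 1) * n + H[, 2]
  if (anyDuplicated(keyDir)) return(FALSE)          # inconsistent winding
  keyUnd <- (pmin(H[, 1], H[, 2]) - 1) * n + pmax(H[, 1], H[, 2])
  all(table(keyUnd) == 2L)                          # closed
}

#' Cotangent Laplacian of a triangle mesh
#'
#' Off-diagonal weight w_ij = (cot a_ij + cot b_ij) / 2 over the one or two
#' faces sharing edge ij; diagonal entries make every row sum to zero.
#' Cotangents are clamped to |cot| <= cot(clampDeg degrees) so the
#' contraction solve stays well conditioned on sliver triangles.
#'
#' @param mesh a [TriangleMesh-class]; must be edge-manifold.
#' @param clampDeg clamping angle in degrees (default 1).
#' @return a sparse symmetric `Matrix` with zero row sums.
#' @export
cotanLaplacian <- function(mesh, clampDeg = 1) {
  V <- mesh@vertices; Fm <- mesh@faces
  E <- .meshEdges(mesh)
  cnt <- attr(E, "count")
  if (any(cnt > 2L)) {
    bad <- which(cnt > 2L)[1]
    stop(sprintf("non-manifold edge (%d, %d) with %d incident faces",
                 E[bad, 1], E[bad, 2], cnt[bad]))
  }
  cap <- 1 / tan(clampDeg * pi / 180)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in 1:3) {
    # corner k is opposite the edge (k+1, k+2)
    a <- Fm[, k]; b <- Fm[, k %% 3 + 1]; cc <- Fm[, (k + 1) %% 3 + 1]
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    w <- V[cc, , drop = FALSE] - V[a, , drop = FALSE]
    cr <- .rowNorm(.rowCross(u, w))
    cr[cr < 1e-300] <- 1e-300
    cot <- rowSums(u * w) / cr
    cot <- pmin(pmax(cot, -cap), cap)
    ii <- c(ii, b); jj <- c(jj, cc); xx <- c(xx, cot / 2)
  }
  n <- nrow(V)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xx, xx),
                            dims = c(n, n))
  Matrix::forceSymmetric(W - Matrix::Diagonal(n, Matrix::rowSums(W)))
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; watertight by
#' construction. Used as an analytic test solid for volume and ray-thickness
#' checks.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 1-to-4 subdivision rounds (default 3).
#' @param center sphere center.
#' @return a [TriangleMesh-class].
#' @export
makeIcosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  Fm <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
              c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
              c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    n <- nrow(V)
    E <- rbind(Fm[, c(1, 2)], Fm[, c(2, 3)], Fm[, c(3, 1)])
    E <- cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
    key <- (E[, 1] - 1) * n + E[, 2]
    uk <- unique(key)
    mid <- (V[E[!duplicated(key), 1], , drop = FALSE] +
            V[E[!duplicated(key), 2], , drop = FALSE]) / 2
    midIdx <- n + match(key, uk)
    V <- rbind(V, mid)
    m <- nrow(Fm)
    ab <- midIdx[1:m]; bc <- midIdx[m + 1:m]; ca <- midIdx[2 * m + 1:m]
    Fm <- rbind(cbind(Fm[, 1], ab, ca), cbind(Fm[, 2], bc, ab),
                cbind(Fm[, 3], ca, bc), cbind(ab, bc, ca))
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, center, "+")
  TriangleMesh(V, Fm)
}
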