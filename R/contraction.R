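# Laplacian mesh contraction: iteratively solve the stacked least-squares
# system [W_L * L; W_H] V' = [0; W_H * V] via its normal equations, growing
# the contraction weight and renormalising the attraction weights by the
# one-ring-area shrinkage, until the mesh volume has all but vanished.

#' Contract a mesh toward its curve skeleton
#'
#' Each iteration solves, per coordinate, the sparse least-squares system
#' whose first block `W_L * L` pulls vertices toward the local Laplacian
#' null space (smoothing/shrinkage) and whose second block `W_H` anchors
#' them to their previous positions. Afterwards `W_L <- s_L * W_L` and
#' `W_H,i <- W_H,i^0 * sqrt(A_i^0 / A_i^t)`, the Laplacian is rebuilt from
#' the new positions, and the loop stops when `|volume|` drops below
#' `volumeRatioStop` times the input volume or `maxIters` is reached.
#' Connectivity never changes: contraction moves vertices only.
#'
#' @param mesh a manifold [TriangleMesh-class] with nonzero volume.
#' @param sL contraction speed-up coefficient (default 2).
#' @param volumeRatioStop stop when |volume| <= this fraction of the input
#'   volume (default 1e-5, quantifying "volume reaches nearly zero").
#' @param maxIters iteration cap (default 20).
#' @param clampDeg cotangent clamp angle passed to [cotanLaplacian()].
#' @return list with `mesh` (contracted) and `state`
#'   (a [ContractionState-class] holding weights and the volume trace).
#' @export
contractMesh <- function(mesh, sL = 2, volumeRatioStop = 1e-5,
                         maxIters = 20, clampDeg = 1) {
  V <- mesh@vertices
  n <- nrow(V)
  areas <- .meshAreas(mesh)
  A0 <- areas$oneRing
  if (any(A0 <= 0)) stop("mesh has isolated vertices (zero one-ring area)")
  vol0 <- abs(meshVolume(mesh))
  if (vol0 <= 0) stop("mesh volume is zero; contraction needs a solid input")
  # Initial contraction weight: sqrt(mean face area). The often-quoted
  # 1e-3 * sqrt(A) start leaves the first ~10 iterations as numerical
  # no-ops on tube meshes (the bilaplacian perturbation can even inflate
  # the volume in the sixth digit); starting at sqrt(A) makes the volume
  # strictly decrease from the first iteration at identical accuracy.
  WL <- sqrt(mean(areas$faceAreas))
  WH0 <- rep(1, n)
  WH <- WH0
  vols <- vol0
  cur <- mesh
  converged <- FALSE
  warnedFrozen <- FALSE
  t <- 0L
  while (t < maxIters) {
    L <- cotanLaplacian(cur, clampDeg)
    M <- WL^2 * Matrix::crossprod(L) + Matrix::Diagonal(n, WH^2)
    rhs <- WH^2 * V
    Vnew <- tryCatch(as.matrix(Matrix::solve(M, rhs)),
                     error = function(e) NULL)
    if (is.null(Vnew)) {
      # ill-conditioned: clamp harder and retry once
      L <- cotanLaplacian(cur, clampDeg = 5)
      M <- WL^2 * Matrix::crossprod(L) + Matrix::Diagonal(n, WH^2)
      Vnew <- as.matrix(Matrix::solve(M, rhs))
    }
    newVol <- abs(meshVolume(TriangleMesh(Vnew, mesh@faces)))
    if (newVol >= vols[length(vols)] && vols[length(vols)] <= 0.5 * vol0) {
      # volume no longer decreases: the collapsed mesh has degenerated and
      # further smoothing only distorts the thin shape (bent tubes drift
      # toward their chord); discard this iterate and stop
      break
    }
    V <- Vnew
    cur <- TriangleMesh(V, mesh@faces)
    t <- t + 1L
    vols <- c(vols, newVol)
    WL <- sL * WL
    At <- .meshAreas(cur)$oneRing
    frozen <- At <= .Machine$double.eps * A0
    if (any(frozen) && !warnedFrozen) {
      warning("zero-area one-ring: attraction weight frozen for ",
              sum(frozen), " vertex/vertices")
      warnedFrozen <- TRUE
    }
    WHnew <- WH0 * sqrt(A0 / pmax(At, .Machine$double.eps * A0))
    WH[!frozen] <- WHnew[!frozen]
    if (vols[length(vols)] <= volumeRatioStop * vol0) {
      converged <- TRUE
      break
    }
  }
  state <- new("ContractionState", WL = WL, WH = WH, WH0 = WH0, A0 = A0,
               At = .meshAreas(cur)$oneRing, sL = sL, iterations = t,
               volumes = vols, converged = converged)
  list(mesh = cur, state = state)
}

#' Adaptive Loop-style subdivision of a contracted mesh
#'
#' Faces with any edge longer than `targetEdge` are 1-to-4 subdivided; their
#' neighbours are split conformingly (1-to-2 or 1-to-3) so no T-junctions
#' appear. New edge vertices use the Loop edge mask `3/8 (a+b) + 1/8 (c+d)`
#' on interior edges and the midpoint on boundary edges; original vertices
#' stay put, which keeps the already-contracted geometry in place while
#' increasing point density. Up to `maxRounds` rounds are applied or until
#' every edge is at most `targetEdge`.
#'
#' @param mesh a [TriangleMesh-class] (normally the contracted mesh).
#' @param targetEdge maximum edge length to aim for (mm).
#' @param maxRounds round cap (default 3).
#' @param maxVertices stop subdividing once the vertex count would exceed
#'   this budget (default 50000).
#' @return a [TriangleMesh-class].
#' @export
adaptiveSubdivide <- function(mesh, targetEdge, maxRounds = 3,
                              maxVertices = 50000) {
  for (round in seq_len(maxRounds)) {
    V <- mesh@vertices; Fm <- mesh@faces
    n <- nrow(V)
    fe <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
    k12 <- fe(Fm[, 1], Fm[, 2]); k23 <- fe(Fm[, 2], Fm[, 3])
    k31 <- fe(Fm[, 3], Fm[, 1])
    elen <- cbind(.rowNorm(V[Fm[, 1], , drop = FALSE] - V[Fm[, 2], , drop = FALSE]),
                  .rowNorm(V[Fm[, 2], , drop = FALSE] - V[Fm[, 3], , drop = FALSE]),
                  .rowNorm(V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]))
    marked <- elen[, 1] > targetEdge | elen[, 2] > targetEdge |
      elen[, 3] > targetEdge
    if (!any(marked)) break
    splitKeys <- unique(c(k12[marked], k23[marked], k31[marked]))
    if (n + length(splitKeys) > maxVertices) break
    # two (or one, on boundaries) opposite corners per split edge for the
    # Loop edge mask
    allKeys <- c(k12, k23, k31)
    allOpp <- as.numeric(c(Fm[, 3], Fm[, 1], Fm[, 2]))
    inSplit <- allKeys %in% splitKeys
    oppBy <- split(allOpp[inSplit], allKeys[inSplit])
    ordKeys <- as.numeric(names(oppBy))
    a <- ((ordKeys - 1) %/% n) + 1
    b <- ((ordKeys - 1) %% n) + 1
    nOpp <- lengths(oppBy)
    o1 <- vapply(oppBy, `[`, numeric(1), 1L)
    o2 <- vapply(oppBy, function(x) if (length(x) > 1L) x[2] else NA_real_,
                 numeric(1))
    mids <- matrix(0, length(ordKeys), 3)
    interior <- nOpp == 2L
    if (any(interior))
      mids[interior, ] <- 3 / 8 * (V[a[interior], , drop = FALSE] +
                                   V[b[interior], , drop = FALSE]) +
        1 / 8 * (V[o1[interior], , drop = FALSE] +
                 V[o2[interior], , drop = FALSE])
    if (any(!interior))
      mids[!interior, ] <- (V[a[!interior], , drop = FALSE] +
                            V[b[!interior], , drop = FALSE]) / 2
    newIdxOf <- function(keys) {
      pos <- match(keys, ordKeys)
      ifelse(is.na(pos), NA_integer_, n + pos)
    }
    m12 <- newIdxOf(k12); m23 <- newIdxOf(k23); m31 <- newIdxOf(k31)
    ns <- (!is.na(m12)) + (!is.na(m23)) + (!is.na(m31))
    V2 <- rbind(V, mids)
    pieces <- list(cbind(Fm[ns == 0L, 1], Fm[ns == 0L, 2], Fm[ns == 0L, 3]))
    full <- ns == 3L
    if (any(full)) {
      pieces <- c(pieces, list(
        cbind(Fm[full, 1], m12[full], m31[full]),
        cbind(Fm[full, 2], m23[full], m12[full]),
        cbind(Fm[full, 3], m31[full], m23[full]),
        cbind(m12[full], m23[full], m31[full])))
    }
    # rotate partially split faces so edge 1 is split (and edge 2 when two
    # edges are split), then emit the canonical 1-to-2 / 1-to-3 patterns
    part <- which(ns == 1L | ns == 2L)
    if (length(part)) {
      vv <- Fm[part, , drop = FALSE]
      mm <- cbind(m12[part], m23[part], m31[part])
      for (r in 1:2) {
        bad <- is.na(mm[, 1])
        if (any(bad)) {
          vv[bad, ] <- vv[bad, c(2, 3, 1), drop = FALSE]
          mm[bad, ] <- mm[bad, c(2, 3, 1), drop = FALSE]
        }
      }
      one <- ns[part] == 1L
      if (any(one))
        pieces <- c(pieces, list(
          cbind(vv[one, 1], mm[one, 1], vv[one, 3]),
          cbind(mm[one, 1], vv[one, 2], vv[one, 3])))
      two <- ns[part] == 2L
      if (any(two)) {
        vv2 <- vv[two, , drop = FALSE]
        mm2 <- mm[two, , drop = FALSE]
        rot <- is.na(mm2[, 2])     # split edges are 1 and 3: rotate back one
        if (any(rot)) {
          vv2[rot, ] <- vv2[rot, c(3, 1, 2), drop = FALSE]
          mm2[rot, ] <- mm2[rot, c(3, 1, 2), drop = FALSE]
        }
        pieces <- c(pieces, list(
          cbind(vv2[, 1], mm2[, 1], mm2[, 2]),
          cbind(mm2[, 1], vv2[, 2], mm2[, 2]),
          cbind(vv2[, 1], mm2[, 2], vv2[, 3])))
      }
    }
    Fnew <- do.call(rbind, pieces)
    mesh <- TriangleMesh(V2, Fnew)
  }
  mesh
}
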