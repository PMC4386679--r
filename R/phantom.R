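# Synthetic vascular phantoms with analytic ground truth: straight and bent
# swept tubes, and branched (Y / double-Y) phantoms meshed by marching
# tetrahedra over a capsule-union signed distance field. Every phantom
# returns a watertight mesh, the analytic centerlines/radii/junctions, and
# a matching VesselModel for collision queries.

.frameAlong <- function(stations) {
  # discrete rotation-minimizing frames along a polyline
  k <- nrow(stations)
  Tg <- matrix(0, k, 3)
  Tg[1, ] <- .unit(stations[2, ] - stations[1, ])
  for (i in 2:k)
    Tg[i, ] <- .unit(stations[i, ] - stations[i - 1L, ])
  if (k > 2) for (i in 2:(k - 1))
    Tg[i, ] <- .unit(stations[i + 1L, ] - stations[i - 1L, ])
  ref <- if (abs(Tg[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  N <- matrix(0, k, 3)
  N[1, ] <- .unit(ref - sum(ref * Tg[1, ]) * Tg[1, ])
  for (i in 2:k)
    N[i, ] <- .unit(N[i - 1L, ] - sum(N[i - 1L, ] * Tg[i, ]) * Tg[i, ])
  B <- .rowCross(Tg, N)
  list(T = Tg, N = N, B = B)
}

.sweepTube <- function(stations, radii, circumferential, jitterSd = 0,
                       seed = NULL) {
  k <- nrow(stations)
  fr <- .frameAlong(stations)
  ang <- 2 * pi * (seq_len(circumferential) - 1L) / circumferential
  V <- matrix(0, k * circumferential + 2L, 3)
  jit <- if (jitterSd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    stats::rnorm(k * circumferential, 0, jitterSd)
  } else numeric(k * circumferential)
  for (i in seq_len(k)) {
    rows <- (i - 1L) * circumferential + seq_len(circumferential)
    r <- radii[i] + jit[rows]
    V[rows, ] <- matrix(stations[i, ], circumferential, 3, byrow = TRUE) +
      r * (cos(ang) %o% fr$N[i, ] + sin(ang) %o% fr$B[i, ])
  }
  c0 <- k * circumferential + 1L                 # start cap center
  c1 <- k * circumferential + 2L                 # end cap center
  V[c0, ] <- stations[1, ]
  V[c1, ] <- stations[k, ]
  faces <- list()
  for (i in seq_len(k - 1L)) {
    a <- (i - 1L) * circumferential + seq_len(circumferential)
    b <- a %% circumferential + (i - 1L) * circumferential + 1L
    a2 <- a + circumferential
    b2 <- b + circumferential
    faces[[length(faces) + 1L]] <- cbind(a, b, b2)
    faces[[length(faces) + 1L]] <- cbind(a, b2, a2)
  }
  j <- seq_len(circumferential)
  jn <- j %% circumferential + 1L                # next index with wrap
  ring1 <- j
  ring2 <- (k - 1L) * circumferential + j
  ring2n <- (k - 1L) * circumferential + jn
  faces[[length(faces) + 1L]] <- cbind(c0, jn, j)        # start cap
  faces[[length(faces) + 1L]] <- cbind(c1, ring2, ring2n) # end cap
  Fm <- do.call(rbind, faces)
  mesh <- TriangleMesh(V, Fm)
  if (meshVolume(mesh) < 0) mesh@faces <- mesh@faces[, c(1, 3, 2)]
  mesh
}

# ---- marching tetrahedra over a signed distance field ---------------------

.segmentDistance <- function(P, A, B) {
  AB <- B - A
  len2 <- sum(AB^2)
  w <- sweep(P, 2, A)
  t <- pmin(pmax((w %*% AB) / len2, 0), 1)
  cp <- outer(as.numeric(t), AB) + matrix(A, nrow(P), 3, byrow = TRUE)
  sqrt(rowSums((P - cp)^2))
}

.capsuleUnionSDF <- function(segments) {
  # segments: list of list(A, B, r)
  function(P) {
    P <- as.matrix(P)
    d <- rep(Inf, nrow(P))
    for (s in segments)
      d <- pmin(d, .segmentDistance(P, s$A, s$B) - s$r)
    d
  }
}

.marchingTets <- function(sdf, lower, upper, h, smoothRounds = 2) {
  # snap the grid to the half-offset lattice (..., -h/2, h/2, ...): it is
  # symmetric about the coordinate planes, so symmetric geometries sample
  # symmetrically (an arbitrary grid offset skews the junction membrane
  # collapse), yet round-coordinate surfaces never coincide exactly with a
  # grid plane (exact tangency breeds degenerate tetrahedra)
  lower <- (floor(lower / h - 0.5) + 0.5) * h
  upper <- (ceiling(upper / h + 0.5) - 0.5) * h
  xs <- seq(lower[1], upper[1], by = h)
  ys <- seq(lower[2], upper[2], by = h)
  zs <- seq(lower[3], upper[3], by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(pts) <- NULL
  vals <- sdf(pts)
  vals[abs(vals) < 1e-9] <- 1e-9
  dx <- 1L; dy <- nx; dz <- nx * ny
  base <- as.vector(outer(outer(seq_len(nx - 1L),
                                (seq_len(ny - 1L) - 1L) * dy, "+"),
                          (seq_len(nz - 1L) - 1L) * dz, "+"))
  corner <- function(code) {
    base + (code %% 2L) * dx + ((code %/% 2L) %% 2L) * dy + (code %/% 4L) * dz
  }
  tets <- list(c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
               c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L))
  triEdges <- list()
  for (tt in tets) {
    A <- corner(tt[1]); B <- corner(tt[2]); C <- corner(tt[3]); D <- corner(tt[4])
    inside <- cbind(vals[A] < 0, vals[B] < 0, vals[C] < 0, vals[D] < 0)
    code <- inside %*% c(1L, 2L, 4L, 8L)
    ids <- cbind(A, B, C, D)
    emit <- function(sel, e1, e2, e3) {
      # e*: integer pairs into columns of ids
      if (!any(sel)) return(NULL)
      m <- ids[sel, , drop = FALSE]
      list(cbind(m[, e1[1]], m[, e1[2]]), cbind(m[, e2[1]], m[, e2[2]]),
           cbind(m[, e3[1]], m[, e3[2]]))
    }
    singles <- list(`1` = list(1L, c(1, 2), c(1, 3), c(1, 4)),
                    `2` = list(2L, c(2, 1), c(2, 3), c(2, 4)),
                    `4` = list(4L, c(3, 1), c(3, 2), c(3, 4)),
                    `8` = list(8L, c(4, 1), c(4, 2), c(4, 3)),
                    `14` = list(14L, c(1, 2), c(1, 3), c(1, 4)),
                    `13` = list(13L, c(2, 1), c(2, 3), c(2, 4)),
                    `11` = list(11L, c(3, 1), c(3, 2), c(3, 4)),
                    `7` = list(7L, c(4, 1), c(4, 2), c(4, 3)))
    for (cs in singles) {
      tr <- emit(code == cs[[1]], cs[[2]], cs[[3]], cs[[4]])
      if (!is.null(tr)) triEdges[[length(triEdges) + 1L]] <- tr
    }
    pairs <- list(list(3L, 1L, 2L, 3L, 4L),   # inside {A,B}, outside {C,D}
                  list(5L, 1L, 3L, 2L, 4L),   # inside {A,C}
                  list(9L, 1L, 4L, 2L, 3L),   # inside {A,D}
                  list(6L, 2L, 3L, 1L, 4L),   # inside {B,C}
                  list(10L, 2L, 4L, 1L, 3L),  # inside {B,D}
                  list(12L, 3L, 4L, 1L, 2L))  # inside {C,D}
    for (ps in pairs) {
      sel <- code == ps[[1]]
      if (!any(sel)) next
      p <- ps[[2]]; q <- ps[[3]]; r <- ps[[4]]; s <- ps[[5]]
      # quad (pr, ps, qs, qr) -> two triangles
      tr1 <- emit(sel, c(p, r), c(p, s), c(q, s))
      tr2 <- emit(sel, c(p, r), c(q, s), c(q, r))
      triEdges[[length(triEdges) + 1L]] <- tr1
      triEdges[[length(triEdges) + 1L]] <- tr2
    }
  }
  if (!length(triEdges))
    stop("marching tetrahedra produced no surface; check the grid bounds")
  E1 <- do.call(rbind, lapply(triEdges, `[[`, 1))
  E2 <- do.call(rbind, lapply(triEdges, `[[`, 2))
  E3 <- do.call(rbind, lapply(triEdges, `[[`, 3))
  allE <- rbind(E1, E2, E3)
  lo <- pmin(allE[, 1], allE[, 2])
  hi <- pmax(allE[, 1], allE[, 2])
  key <- (lo - 1) * length(vals) + hi
  uk <- unique(key)
  pos <- match(key, uk)
  firstIdx <- match(uk, key)
  la <- lo[firstIdx]; lb <- hi[firstIdx]
  t <- vals[la] / (vals[la] - vals[lb])
  Vsurf <- pts[la, , drop = FALSE] + t * (pts[lb, , drop = FALSE] -
                                          pts[la, , drop = FALSE])
  nt <- nrow(E1)
  Fm <- cbind(pos[seq_len(nt)], pos[nt + seq_len(nt)], pos[2L * nt + seq_len(nt)])
  good <- Fm[, 1] != Fm[, 2] & Fm[, 2] != Fm[, 3] & Fm[, 1] != Fm[, 3]
  Fm <- Fm[good, , drop = FALSE]
  Fm <- .orientFacesConsistently(Vsurf, Fm)
  mesh <- TriangleMesh(Vsurf, Fm)
  # two light uniform-Laplacian smoothing rounds: marching-tetrahedra
  # meshes carry sliver triangles whose clamped cotangent weights would
  # otherwise leave straggler vertices behind during contraction
  .smoothMesh(mesh, lambda = 0.5, rounds = smoothRounds)
}

# propagate a consistent winding over shared edges (BFS), then flip
# globally so the signed volume is positive (outward normals)
.orientFacesConsistently <- function(V, Fm) {
  m <- nrow(Fm)
  n <- nrow(V)
  ekey <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  keys <- cbind(ekey(Fm[, 1], Fm[, 2]), ekey(Fm[, 2], Fm[, 3]),
                ekey(Fm[, 3], Fm[, 1]))
  edgeFaces <- split(rep(seq_len(m), 3), as.vector(keys))
  visited <- rep(FALSE, m)
  for (start in seq_len(m)) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    while (length(queue)) {
      f <- queue[1]; queue <- queue[-1]
      vs <- Fm[f, ]
      dirEdges <- rbind(vs[c(1, 2)], vs[c(2, 3)], vs[c(3, 1)])
      fkeys <- ekey(dirEdges[, 1], dirEdges[, 2])
      for (e in 1:3) {
        nb <- edgeFaces[[as.character(fkeys[e])]]
        for (g in nb) {
          if (g == f || visited[g]) next
          gs <- Fm[g, ]
          gEdges <- rbind(gs[c(1, 2)], gs[c(2, 3)], gs[c(3, 1)])
          a <- dirEdges[e, 1]; b <- dirEdges[e, 2]
          same <- any(gEdges[, 1] == a & gEdges[, 2] == b)
          if (same) Fm[g, ] <- gs[c(1, 3, 2)]
          visited[g] <- TRUE
          queue <- c(queue, g)
        }
      }
    }
  }
  if (meshVolume(TriangleMesh(V, Fm)) < 0) Fm <- Fm[, c(1, 3, 2)]
  Fm
}

# uniform Laplacian smoothing (vertex -> neighbour mean, damped)
.smoothMesh <- function(mesh, lambda = 0.5, rounds = 2) {
  if (rounds < 1L) return(mesh)
  V <- mesh@vertices
  n <- nrow(V)
  E <- .meshEdges(mesh)
  A <- Matrix::sparseMatrix(i = c(E[, 1], E[, 2]), j = c(E[, 2], E[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  for (r in seq_len(rounds))
    V <- (1 - lambda) * V + lambda * as.matrix(A %*% V) / deg
  TriangleMesh(V, mesh@faces)
}

# ---- phantom constructors -------------------------------------------------

.densify <- function(A, B, n = 64L) {
  t <- seq(0, 1, length.out = n)
  outer(1 - t, A) + outer(t, B)
}

# append spherically tapered cap stations at the end of a branch polyline
.capBranch <- function(stations, r, radii = rep(r, nrow(stations))) {
  k <- nrow(stations)
  d <- .unit(stations[k, ] - stations[k - 1L, ])
  s <- r * c(0.3, 0.55, 0.75, 0.9, 0.995)
  caps <- sweep(outer(s, d), 2, stations[k, ], "+")
  list(stations = rbind(stations, caps),
       radii = c(radii, sqrt(pmax(r^2 - s^2, 1e-6))),
       entryArc = 0)
}

# prepend cap stations before the entry end; records the arc offset of the
# true entry plane so wire seeding can skip the cap
.capBranchStart <- function(stations, r, radii = rep(r, nrow(stations))) {
  k <- nrow(stations)
  d <- .unit(stations[1, ] - stations[2, ])
  s <- rev(r * c(0.3, 0.55, 0.75, 0.9, 0.995))
  caps <- sweep(outer(s, d), 2, stations[1, ], "+")
  list(stations = rbind(caps, stations),
       radii = c(sqrt(pmax(r^2 - s^2, 1e-6)), radii),
       entryArc = max(s))
}

# extend a polyline's free ends by the lumen radius: capsule-union phantoms
# carry spherical end caps whose skeleton runs toward the cap apex, so the
# analytic centerline covers them too
.extendCaps <- function(poly, r, atStart = TRUE, atEnd = TRUE) {
  k <- nrow(poly)
  if (atStart) {
    d <- .unit(poly[1, ] - poly[2, ])
    poly <- rbind(poly[1, ] + r * d, poly)
  }
  if (atEnd) {
    k <- nrow(poly)
    d <- .unit(poly[k, ] - poly[k - 1L, ])
    poly <- rbind(poly, poly[k, ] + r * d)
  }
  poly
}

#' Generate a synthetic vascular phantom
#'
#' Produces a watertight lumen surface mesh, the analytic ground truth
#' (centerlines, radii, junction positions, inside/outside predicate) and a
#' matching [VesselModel-class] for collision queries. Kinds:
#' \describe{
#'   \item{cylinder}{straight tube along +z: `radius`, `length`.}
#'   \item{torus_segment}{circular bend in the x-z plane starting at the
#'     origin heading +z: `lumenRadius`, `bendRadius`, `angle` (radians).}
#'   \item{y_bifurcation}{trunk along +z splitting at its end into two
#'     straight daughters: `lumenRadius`, `trunkLength`, `daughterLength`,
#'     `daughterAngle` (each daughter's angle off the trunk axis, in
#'     (0, pi/2]).}
#'   \item{composite}{arbitrary capsule-union tube network:
#'     `branches` = list of list(`polyline` k x 3, `radius`).}
#' }
#' Swept meshes are used for the unbranched kinds (resolution
#' `circumferential` x `axial`); branched kinds are meshed by marching
#' tetrahedra over the capsule-union signed distance field with grid step
#' `gridStep` (default `lumenRadius / 5`), which guarantees watertightness
#' across the junction blend.
#'
#' @param kind phantom kind, see above.
#' @param ... kind-specific parameters plus the common `kV`, `FRupture`,
#'   `jitterSd` (surface noise SD in mm, swept kinds only, default 0) and
#'   `seed` (jitter RNG seed; identical spec + seed is bit-identical).
#' @return list with `mesh` ([TriangleMesh-class]), `truth` (list:
#'   `centerlines`, `radii`, `junctions`, `inside` predicate function,
#'   `kind`) and `vessel` ([VesselModel-class]).
#' @export
makePhantom <- function(kind = c("cylinder", "torus_segment",
                                 "y_bifurcation", "composite"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  kV <- args$kV %||% 0.5
  FRupture <- args$FRupture %||% Inf
  jitterSd <- args$jitterSd %||% 0
  seed <- args$seed
  if (kind == "cylinder") {
    radius <- args$radius %||% 2
    len <- args$length %||% 40
    circ <- args$circumferential %||% 32L
    axial <- args$axial %||% 80L
    stations <- cbind(0, 0, seq(0, len, length.out = axial + 1L))
    radii <- rep(radius, axial + 1L)
    centerlines <- list(stations)
    junctions <- matrix(numeric(0), 0, 3)
  } else if (kind == "torus_segment") {
    radius <- args$lumenRadius %||% 2
    Rb <- args$bendRadius %||% 20
    ang <- args$angle %||% (pi / 2)
    if (Rb <= radius) stop("bend radius must exceed the lumen radius")
    circ <- args$circumferential %||% 32L
    axial <- args$axial %||% 80L
    t <- seq(0, ang, length.out = axial + 1L)
    stations <- cbind(Rb - Rb * cos(t), 0, Rb * sin(t))
    radii <- rep(radius, axial + 1L)
    centerlines <- list(stations)
    junctions <- matrix(numeric(0), 0, 3)
  } else if (kind == "y_bifurcation") {
    radius <- args$lumenRadius %||% 2
    Lt <- args$trunkLength %||% 20
    Ld <- args$daughterLength %||% 15
    da <- args$daughterAngle %||% (pi / 6)
    if (da <= 0 || da > pi / 2) stop("daughter angle must lie in (0, pi/2]")
    J <- c(0, 0, Lt)
    d1 <- J + Ld * c(sin(da), 0, cos(da))
    d2 <- J + Ld * c(-sin(da), 0, cos(da))
    segments <- list(list(A = c(0, 0, 0), B = J, r = radius),
                     list(A = J, B = d1, r = radius),
                     list(A = J, B = d2, r = radius))
    centerlines <- list(.densify(c(0, 0, 0), J),
                        .densify(J, d1), .densify(J, d2))
    radii <- lapply(centerlines, function(cl) rep(radius, nrow(cl)))
    junctions <- rbind(J)
    h <- args$gridStep %||% (radius / 5)
    sdf <- .capsuleUnionSDF(segments)
    pts <- do.call(rbind, lapply(segments, function(s) rbind(s$A, s$B)))
    mesh <- .marchingTets(sdf, apply(pts, 2, min) - radius - 2 * h,
                          apply(pts, 2, max) + radius + 2 * h, h)
    # free tube ends carry spherical caps: the centerline (and lumen)
    # extends into them
    freeStart <- c(TRUE, FALSE, FALSE)
    freeEnd <- c(FALSE, TRUE, TRUE)
    centerlines <- Map(function(cl, s, e) .extendCaps(cl, radius, s, e),
                       centerlines, freeStart, freeEnd)
    radii <- lapply(centerlines, function(cl) rep(radius, nrow(cl)))
    truth <- list(centerlines = centerlines, radii = radii,
                  junctions = junctions, kind = kind,
                  inside = function(P) sdf(P) < 0)
    # all free ends get spherically tapered lumen stations so containment
    # matches the capsule geometry; the entry branch records where the
    # proper lumen begins so wires are seeded at the entry plane, not at
    # the cap apex
    vesselBranches <- list(
      .capBranchStart(.densify(c(0, 0, 0), J), radius),
      .capBranch(.densify(J, d1), radius),
      .capBranch(.densify(J, d2), radius))
    vessel <- VesselModel(vesselBranches, kV = kV, FRupture = FRupture,
                          mesh = mesh)
    return(list(mesh = mesh, truth = truth, vessel = vessel))
  } else {
    branches <- args$branches
    if (is.null(branches)) stop("composite phantom needs `branches`")
    segments <- list()
    centerlines <- list()
    radii <- list()
    for (b in branches) {
      pl <- as.matrix(b$polyline)
      for (i in seq_len(nrow(pl) - 1L))
        segments[[length(segments) + 1L]] <-
          list(A = pl[i, ], B = pl[i + 1L, ], r = b$radius)
      dens <- do.call(rbind, lapply(seq_len(nrow(pl) - 1L), function(i)
        .densify(pl[i, ], pl[i + 1L, ], 32L)[if (i > 1) -1 else TRUE, ,
                                             drop = FALSE]))
      centerlines[[length(centerlines) + 1L]] <- dens
      radii[[length(radii) + 1L]] <- rep(b$radius, nrow(dens))
    }
    ends <- do.call(rbind, lapply(centerlines, function(cl)
      rbind(cl[1, ], cl[nrow(cl), ])))
    key <- paste(round(ends[, 1], 6), round(ends[, 2], 6), round(ends[, 3], 6))
    junctions <- ends[key %in% names(which(table(key) >= 2)), , drop = FALSE]
    junctions <- junctions[!duplicated(round(junctions, 6)), , drop = FALSE]
    rmax <- max(vapply(branches, function(b) b$radius, numeric(1)))
    h <- args$gridStep %||% (rmax / 5)
    sdf <- .capsuleUnionSDF(segments)
    pts <- do.call(rbind, lapply(segments, function(s) rbind(s$A, s$B)))
    mesh <- .marchingTets(sdf, apply(pts, 2, min) - rmax - 2 * h,
                          apply(pts, 2, max) + rmax + 2 * h, h)
    endKey <- function(p) paste(round(p, 6), collapse = " ")
    allEnds <- unlist(lapply(centerlines, function(cl)
      c(endKey(cl[1, ]), endKey(cl[nrow(cl), ]))))
    endCount <- table(allEnds)
    vesselBranches <- vector("list", length(centerlines))
    for (i in seq_along(centerlines)) {
      cl <- centerlines[[i]]
      r <- branches[[i]]$radius
      freeStart <- endCount[[endKey(cl[1, ])]] == 1L
      freeEnd <- endCount[[endKey(cl[nrow(cl), ])]] == 1L
      vb <- list(stations = cl, radii = rep(r, nrow(cl)), entryArc = 0)
      if (freeEnd) vb <- .capBranch(vb$stations, r, vb$radii)
      if (freeStart) vb <- .capBranchStart(vb$stations, r, vb$radii)
      vesselBranches[[i]] <- vb
      centerlines[[i]] <- .extendCaps(cl, r, atStart = freeStart,
                                      atEnd = freeEnd)
    }
    radii <- Map(function(cl, b) rep(b$radius, nrow(cl)), centerlines, branches)
    truth <- list(centerlines = centerlines, radii = radii,
                  junctions = junctions, kind = kind,
                  inside = function(P) sdf(P) < 0)
    vessel <- VesselModel(vesselBranches, kV = kV, FRupture = FRupture,
                          mesh = mesh)
    return(list(mesh = mesh, truth = truth, vessel = vessel))
  }
  # swept (unbranched) kinds
  mesh <- .sweepTube(stations, radii, circ, jitterSd, seed)
  sdfSwept <- .capsuleUnionSDF(lapply(seq_len(nrow(stations) - 1L),
                                      function(i) list(A = stations[i, ],
                                                       B = stations[i + 1L, ],
                                                       r = radius)))
  truth <- list(centerlines = centerlines, radii = list(radii),
                junctions = junctions, kind = kind,
                inside = function(P) sdfSwept(P) < 0)
  vessel <- VesselModel(list(list(stations = stations, radii = radii)),
                        kV = kV, FRupture = FRupture, mesh = mesh)
  list(mesh = mesh, truth = truth, vessel = vessel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Double-Y (two-junction) composite phantom
#'
#' A trunk that bifurcates, with one daughter bifurcating again; the two
#' junctions are separated by at least ten lumen radii so their joint
#' clusters stay distinct.
#'
#' @param lumenRadius lumen radius (mm).
#' @param trunkLength,connectorLength,daughterLength segment lengths (mm).
#' @param angle branch half-angle off the parent axis (radians).
#' @param ... passed to [makePhantom()] (`gridStep`, `kV`, ...).
#' @return as [makePhantom()].
#' @export
makeDoubleYPhantom <- function(lumenRadius = 2, trunkLength = 20,
                               connectorLength = 24, daughterLength = 15,
                               angle = pi / 6, ...) {
  J1 <- c(0, 0, trunkLength)
  u1 <- c(sin(angle), 0, cos(angle))
  u2 <- c(-sin(angle), 0, cos(angle))
  J2 <- J1 + connectorLength * u1
  tip1 <- J1 + daughterLength * u2
  w1 <- .axisRotation(c(0, 1, 0), angle) %*% u1
  w2 <- .axisRotation(c(0, 1, 0), -angle) %*% u1
  branches <- list(
    list(polyline = rbind(c(0, 0, 0), J1), radius = lumenRadius),
    list(polyline = rbind(J1, tip1), radius = lumenRadius),
    list(polyline = rbind(J1, J2), radius = lumenRadius),
    list(polyline = rbind(J2, J2 + daughterLength * as.numeric(w1)),
         radius = lumenRadius),
    list(polyline = rbind(J2, J2 + daughterLength * as.numeric(w2)),
         radius = lumenRadius))
  makePhantom("composite", branches = branches, ...)
}

#' Lay a guidewire along a vessel branch
#'
#' Builds a chain of nominal-length rods along the centerline of the given
#' branch from its entry end; all joints are strictly inside the lumen and
#' the total rest length equals `insertedLength` exactly.
#'
#' @param vessel a [VesselModel-class].
#' @param insertedLength wire length to lay in (mm); must not exceed the
#'   branch length.
#' @param nominalRod nominal rod length (mm, default 2).
#' @param branch branch index (default 1, the entry branch).
#' @param phi,C intrinsic bias angles and stiffnesses for [RodChain()].
#' @return a [RodChain-class].
#' @export
sampleGuidewireStart <- function(vessel, insertedLength, nominalRod = 2,
                                 branch = 1L, phi = 0, C = 1) {
  b <- vessel@branches[[branch]]
  s0 <- if (is.null(b$entryArc)) 0 else b$entryArc
  if (insertedLength > b$arc[length(b$arc)] - s0 + 1e-9)
    stop("inserted length exceeds the branch length")
  k <- max(1L, ceiling(insertedLength / nominalRod))
  st <- s0 + seq(0, insertedLength, length.out = k + 1L)
  P <- t(vapply(st, function(s) .polylineAt(b$stations, b$arc, s), numeric(3)))
  # arc-length stations give chords slightly shorter than the rest lengths
  # on curved centerlines; re-project so the rods are exactly rigid
  P <- .projectRods(P, diff(st))
  RodChain(P, phi = phi, C = C, restLengths = diff(st),
           insertedLength = insertedLength)
}
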