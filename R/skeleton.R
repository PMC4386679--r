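# Skeleton growing over classified branch points, cubic B-spline fitting of
# the resulting polylines, and the composed centerline-extraction pipeline,
# plus branch labeling of the surface and endoscopic camera-path sampling.

#' Grow a curve skeleton from classified points
#'
#' For every joint cluster, one seed per incident branch is found: branch
#' points in a shell around the cluster center are grouped into connected
#' components (step-radius adjacency), and the member of each component
#' nearest to the center becomes a seed. Each seed grows away from the
#' cluster center by repeatedly stepping to the centroid of the unvisited
#' branch points inside a forward cone of half-angle 60 degrees and radius
#' `2 * step`; a front stops when no candidates remain ahead or when it
#' comes within `step` of another front, in which case the two fronts merge
#' into one branch. Vessels without any joint cluster grow from their two
#' extremal points toward each other. Branch polylines join at cluster
#' centers, which become the skeleton junction nodes.
#'
#' @param classified a [ClassifiedPoints-class].
#' @param clusters list of [JointCluster-class] from [clusterJoints()]
#'   (may be empty for unbranched vessels).
#' @param step growth step length (mm); default half the classification
#'   radius.
#' @return a [CurveSkeleton-class] (without splines; see [fitBSpline()]).
#' @export
growSkeleton <- function(classified, clusters, step = classified@radius / 2) {
  P <- classified@points
  branchIdx <- which(classified@labels == "branch")
  if (!length(branchIdx))
    stop("mesh contracted to a blob; lower psi_f or check input")
  BP <- P[branchIdx, , drop = FALSE]
  nb <- nrow(BP)
  visited <- rep(FALSE, nb)
  cosCone <- cos(60 * pi / 180)
  fronts <- list()
  addFront <- function(origin, start, dir, seedIdx) {
    fronts[[length(fronts) + 1L]] <<- list(
      origin = origin, path = rbind(start), dir = dir, active = TRUE,
      mergedWith = NA_integer_)
    if (length(seedIdx)) visited[seedIdx] <<- TRUE
  }
  if (length(clusters)) {
    for (cid in seq_along(clusters)) {
      cl <- clusters[[cid]]
      center <- cl@center
      clR <- if (length(cl@members) > 1L)
        max(sqrt(rowSums(sweep(P[cl@members, , drop = FALSE], 2, center)^2)))
      else 0
      # seeds must sit outside the joint region proper: the collapsed
      # junction membrane has a line-like rim that classifies as branch
      # points, and seeding on (or growing through) the rim would drag
      # early nodes along it; everything within the exclusion radius is
      # marked visited so fronts bridge the junction zone directly
      d <- sqrt(rowSums(sweep(BP, 2, center)^2))
      Rx <- clR + step
      visited[d <= Rx] <- TRUE
      cand <- which(d > Rx & d <= Rx + 2 * step)
      if (!length(cand)) next
      # connected components of the candidate shell (step adjacency)
      Q <- BP[cand, , drop = FALSE]
      comp <- rep(0L, length(cand)); nc <- 0L
      for (s in seq_along(cand)) {
        if (comp[s] != 0L) next
        nc <- nc + 1L; comp[s] <- nc; queue <- s
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          d2 <- rowSums(sweep(Q, 2, Q[v, ])^2)
          nbr <- which(comp == 0L & d2 <= (1.5 * step)^2)
          comp[nbr] <- nc
          queue <- c(queue, nbr)
        }
      }
      for (k in seq_len(nc)) {
        mem <- cand[comp == k]
        seed <- mem[which.min(d[mem])]
        dir <- .unit(BP[seed, ] - center)
        f <- rbind(center, BP[seed, ])
        fronts[[length(fronts) + 1L]] <- list(
          origin = cid, path = f, dir = dir, active = TRUE,
          mergedWith = NA_integer_)
        visited[seed] <- TRUE
      }
    }
    if (!length(fronts))
      stop("mesh contracted to a blob; lower psi_f or check input")
  } else {
    ctr <- colMeans(BP)
    p1 <- which.max(rowSums(sweep(BP, 2, ctr)^2))
    p2 <- which.max(rowSums(sweep(BP, 2, BP[p1, ])^2))
    dir12 <- .unit(BP[p2, ] - BP[p1, ])
    addFront(0L, BP[p1, ], dir12, p1)
    addFront(0L, BP[p2, ], -dir12, p2)
  }
  frontTip <- function(f) f$path[nrow(f$path), ]
  mergeFronts <- function(a, b) {
    fronts[[a]]$active <<- FALSE
    fronts[[b]]$active <<- FALSE
    fronts[[a]]$mergedWith <<- b
    fronts[[b]]$mergedWith <<- a
  }
  maxSteps <- nb + 10L
  for (iter in seq_len(maxSteps)) {
    anyActive <- FALSE
    for (fi in seq_along(fronts)) {
      f <- fronts[[fi]]
      if (!f$active) next
      cur <- frontTip(f)
      d2 <- rowSums(sweep(BP, 2, cur)^2)
      ahead <- !visited & d2 > 1e-18 & d2 <= (2 * step)^2
      if (any(ahead)) {
        vv <- sweep(BP[ahead, , drop = FALSE], 2, cur)
        cosang <- (vv %*% f$dir) / sqrt(rowSums(vv^2))
        ahead[ahead] <- cosang >= cosCone
      }
      if (!any(ahead)) {
        # no points left in the growing direction: free end, unless another
        # front is just ahead of us
        merged <- FALSE
        for (fj in seq_along(fronts)) {
          if (fj == fi || !is.na(fronts[[fj]]$mergedWith)) next
          # never merge two fronts growing out of the same junction
          if (f$origin > 0L && fronts[[fj]]$origin == f$origin) next
          dmin <- min(sqrt(rowSums(sweep(fronts[[fj]]$path, 2, cur)^2)))
          if (dmin <= 2 * step) {
            mergeFronts(fi, fj); merged <- TRUE; break
          }
        }
        if (!merged) fronts[[fi]]$active <- FALSE
        next
      }
      anyActive <- TRUE
      nxt <- colMeans(BP[ahead, , drop = FALSE])
      visited[ahead] <- TRUE
      disp <- nxt - cur
      if (sqrt(sum(disp^2)) < 0.3 * step) {
        # consumed only a thin noisy shell: keep the direction, let the
        # cone reach farther points next round, create no node
        next
      }
      fronts[[fi]]$path <- rbind(f$path, nxt)
      # smoothed growing direction: average of the previous direction and
      # the direction of the last displacement (robust to the lateral
      # scatter of contracted points)
      fronts[[fi]]$dir <- .unit(f$dir + .unit(disp))
      # meet-and-stop: did we come within one step of another front?
      for (fj in seq_along(fronts)) {
        if (fj == fi || !fronts[[fj]]$active) next
        if (f$origin > 0L && fronts[[fj]]$origin == f$origin) next
        if (sqrt(sum((frontTip(fronts[[fj]]) - nxt)^2)) <= step) {
          mergeFronts(fi, fj)
          break
        }
      }
    }
    if (!anyActive) break
  }
  .assembleSkeleton(fronts, clusters, step)
}

# Least-squares intersection point of the incident branch directions: the
# cluster center is a biased junction estimator (the collapsed junction
# membrane is rarely symmetric), so the junction node is refined to the
# point nearest to the lines carried by the first few grown nodes of each
# incident front; the center remains the fallback.
.refineJunction <- function(fronts, cid, center, step) {
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  nlines <- 0L
  for (f in fronts) {
    if (f$origin != cid) next
    P <- f$path
    if (nrow(P) < 3L) next
    P <- P[2:min(nrow(P), 7L), , drop = FALSE]
    mu <- colMeans(P)
    u <- svd(sweep(P, 2, mu))$v[, 1]
    M <- diag(3) - u %o% u
    A <- A + M
    b <- b + M %*% mu
    nlines <- nlines + 1L
  }
  if (nlines < 2L || abs(det(A)) < 1e-9) return(center)
  x <- as.numeric(solve(A, b))
  if (sqrt(sum((x - center)^2)) > 6 * step) center else x
}

.assembleSkeleton <- function(fronts, clusters, step) {
  nodes <- matrix(numeric(0), 0, 3)
  junctionNode <- integer(length(clusters))
  addNode <- function(p) {
    nodes <<- rbind(nodes, p)
    nrow(nodes)
  }
  for (cid in seq_along(clusters))
    junctionNode[cid] <- addNode(.refineJunction(fronts, cid,
                                                 clusters[[cid]]@center,
                                                 step))
  branches <- list()
  consumed <- rep(FALSE, length(fronts))
  pathIdx <- function(path, origin, reverse = FALSE) {
    pts <- if (reverse) path[rev(seq_len(nrow(path))), , drop = FALSE] else path
    ids <- integer(nrow(pts))
    for (r in seq_len(nrow(pts))) ids[r] <- addNode(pts[r, ])
    # replace the origin endpoint by the shared junction node
    if (origin > 0L) {
      at <- if (reverse) length(ids) else 1L
      nodes <<- nodes[-ids[at], , drop = FALSE]
      shift <- ids > ids[at]
      ids[shift] <- ids[shift] - 1L
      ids[at] <- junctionNode[origin]
    }
    ids
  }
  for (fi in seq_along(fronts)) {
    if (consumed[fi]) next
    f <- fronts[[fi]]
    consumed[fi] <- TRUE
    if (!is.na(f$mergedWith)) {
      fj <- f$mergedWith
      consumed[fj] <- TRUE
      g <- fronts[[fj]]
      ids1 <- pathIdx(f$path, f$origin)
      ids2 <- pathIdx(g$path, g$origin, reverse = TRUE)
      branches[[length(branches) + 1L]] <- c(ids1, ids2)
    } else {
      branches[[length(branches) + 1L]] <- pathIdx(f$path, f$origin)
    }
  }
  # drop consecutive duplicates (can appear at merge seams)
  branches <- lapply(branches, function(b) {
    keep <- c(TRUE, sqrt(rowSums((nodes[b[-1], , drop = FALSE] -
                                  nodes[b[-length(b)], , drop = FALSE])^2)) > 1e-9)
    b[keep]
  })
  branches <- branches[lengths(branches) >= 2L]
  deg <- table(unlist(lapply(branches, function(b) c(b[1], b[length(b)]))))
  junc <- sort(as.integer(names(deg)[deg >= 3L]))
  dimnames(nodes) <- NULL
  new("CurveSkeleton", nodes = nodes, branches = branches,
      junctions = junc, splines = list(), radius = numeric(0))
}

#' Fit a cubic B-spline to a branch polyline
#'
#' Least-squares clamped B-spline with exact endpoint interpolation, using
#' chord-length parameterisation. With `smoothing = 0` the spline
#' interpolates every node (control-point count equals node count, interior
#' knots by parameter averaging); larger smoothing values reduce the number
#' of control points to roughly `n / (1 + smoothing)`. Branches with fewer
#' than 4 nodes fall back to a lower degree (quadratic, then linear).
#'
#' @param branch numeric k x 3 matrix of ordered polyline nodes.
#' @param smoothing non-negative smoothing factor (default 0, interpolating).
#' @return an object of class `"bspline"`: list with `knots`, `coef`
#'   (control points), `ord`, `range` and `maxDeviation` (max distance from
#'   the input nodes to the fitted curve at their parameters).
#' @export
fitBSpline <- function(branch, smoothing = 0) {
  X <- as.matrix(branch)
  n <- nrow(X)
  stopifnot(n >= 2L)
  ord <- min(4L, n)
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-n, , drop = FALSE])^2))
  t <- c(0, cumsum(seg))
  if (t[n] == 0) stop("degenerate branch: zero total length")
  nCtrl <- if (smoothing <= 0) n else max(ord, ceiling(n / (1 + smoothing)))
  nCtrl <- min(nCtrl, n)
  nInner <- nCtrl - ord
  inner <- if (nInner <= 0) numeric(0)
  else if (nCtrl == n) {
    vapply(seq_len(nInner), function(j) mean(t[(j + 1):(j + ord - 1)]),
           numeric(1))
  } else {
    stats::quantile(t, probs = seq_len(nInner) / (nInner + 1), names = FALSE)
  }
  knots <- c(rep(t[1], ord), inner, rep(t[n], ord))
  B <- splines::splineDesign(knots, t, ord = ord)
  # pin the endpoint control points to the endpoint nodes
  coef <- matrix(0, nCtrl, 3)
  coef[1, ] <- X[1, ]
  coef[nCtrl, ] <- X[n, ]
  if (nCtrl > 2L) {
    midIdx <- 2:(nCtrl - 1L)
    R <- X - B[, 1, drop = FALSE] %*% rbind(X[1, ]) -
      B[, nCtrl, drop = FALSE] %*% rbind(X[n, ])
    Bm <- B[, midIdx, drop = FALSE]
    coef[midIdx, ] <- qr.solve(Bm, R)
  }
  fit <- B %*% coef
  sp <- structure(list(knots = knots, coef = coef, ord = ord,
                       range = c(t[1], t[n]),
                       maxDeviation = max(sqrt(rowSums((fit - X)^2)))),
                  class = "bspline")
  sp
}

#' Evaluate a fitted B-spline
#'
#' @param sp a `"bspline"` object from [fitBSpline()].
#' @param t parameter values inside the spline's range.
#' @param deriv derivative order (0 = position).
#' @return numeric length(t) x 3 matrix.
#' @export
evalBSpline <- function(sp, t, deriv = 0) {
  t <- pmin(pmax(t, sp$range[1]), sp$range[2])
  B <- splines::splineDesign(sp$knots, t, ord = sp$ord,
                             derivs = rep(deriv, length(t)))
  B %*% sp$coef
}

#' Extract the centerline of a vessel mesh
#'
#' Runs the full pipeline: [contractMesh()], [adaptiveSubdivide()],
#' [classifyPoints()], [clusterJoints()], [growSkeleton()], then
#' [fitBSpline()] per branch. The per-node lumen radius is estimated as the
#' distance from each skeleton node to the nearest vertex of the original
#' surface mesh.
#'
#' @param mesh a watertight vessel [TriangleMesh-class].
#' @param psiF joint/branch threshold (default 0.8).
#' @param sL contraction speed-up (default 2).
#' @param volumeRatioStop contraction stop ratio (default 1e-5).
#' @param maxIters contraction iteration cap (default 20).
#' @param pcaRadius PCA/cluster radius (mm); default the mean distance from
#'   the contracted vertices to the original surface, i.e. the local lumen
#'   radius (radius-based because subdivision makes the density
#'   non-uniform; the neighbourhood must span the collapsed junction
#'   membrane, or a single junction fragments into several clusters).
#' @param step growth step; default 0.75x the PCA radius.
#' @param smoothing B-spline smoothing factor (default 0, interpolating).
#' @param subdivisionRounds max adaptive-subdivision rounds (default 2).
#' @return a [CurveSkeleton-class] with splines and per-node radii.
#' @export
extractCenterline <- function(mesh, psiF = 0.8, sL = 2,
                              volumeRatioStop = 1e-5, maxIters = 20,
                              pcaRadius = NULL, step = NULL, smoothing = 0,
                              subdivisionRounds = 2) {
  contr <- contractMesh(mesh, sL = sL, volumeRatioStop = volumeRatioStop,
                        maxIters = maxIters)
  cm <- contr$mesh
  E <- .meshEdges(cm)
  elen <- .rowNorm(cm@vertices[E[, 1], , drop = FALSE] -
                   cm@vertices[E[, 2], , drop = FALSE])
  meanEdge <- mean(elen)
  sub <- adaptiveSubdivide(cm, targetEdge = meanEdge,
                           maxRounds = subdivisionRounds,
                           maxVertices = 40000)
  Es <- .meshEdges(sub)
  elenS <- .rowNorm(sub@vertices[Es[, 1], , drop = FALSE] -
                    sub@vertices[Es[, 2], , drop = FALSE])
  # The classification scale must span the collapsed junction membrane,
  # whose extent is set by the lumen calibre, not the mesh resolution: use
  # the mean distance from contracted vertices to the original surface,
  # which is precisely the local lumen radius.
  if (is.null(pcaRadius))
    pcaRadius <- mean(.nearestDistance(cm@vertices, mesh@vertices))
  # growth cone reach is 2*step: at 1.5x the lumen radius the centroid
  # averages over the full local point tube, suppressing lateral scatter
  if (is.null(step)) step <- 0.75 * pcaRadius
  cls <- classifyPoints(sub@vertices, pcaRadius, psiF)
  clusters <- clusterJoints(cls, pcaRadius)
  skel <- growSkeleton(cls, clusters, step)
  skel@splines <- lapply(skel@branches, function(b)
    fitBSpline(skel@nodes[b, , drop = FALSE], smoothing))
  skel@radius <- .nearestDistance(skel@nodes, mesh@vertices)
  skel
}

# distance from each row of A to the nearest row of B (chunked)
.nearestDistance <- function(A, B, chunk = 256L) {
  out <- numeric(nrow(A))
  sqB <- rowSums(B^2)
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ablk <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ablk^2), sqB, "+") - 2 * Ablk %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# index of nearest row of B for each row of A
.nearestIndex <- function(A, B, chunk = 256L) {
  out <- integer(nrow(A))
  sqB <- rowSums(B^2)
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ablk <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ablk^2), sqB, "+") - 2 * Ablk %*% t(B)
    out[s:e] <- apply(d2, 1, which.min)
  }
  out
}

#' Label surface vertices by nearest skeleton branch
#'
#' Each mesh vertex receives the branch id of its nearest skeleton node
#' (junction nodes count for their lowest incident branch), decomposing the
#' vessel surface into anatomically meaningful parts.
#'
#' @param mesh the vessel surface [TriangleMesh-class].
#' @param skeleton a [CurveSkeleton-class] extracted from (or aligned with)
#'   the mesh.
#' @return integer vector of 1-based branch ids, one per vertex.
#' @export
labelBranches <- function(mesh, skeleton) {
  if (nrow(skeleton@nodes) == 0L || !length(skeleton@branches))
    stop("empty skeleton")
  nodeBranch <- rep(NA_integer_, nrow(skeleton@nodes))
  for (bi in rev(seq_along(skeleton@branches)))
    nodeBranch[skeleton@branches[[bi]]] <- bi
  used <- which(!is.na(nodeBranch))
  nearest <- .nearestIndex(mesh@vertices, skeleton@nodes[used, , drop = FALSE])
  nodeBranch[used][nearest]
}

#' Sample an endoscopic camera flight path along skeleton branches
#'
#' Concatenates the splines of the requested branches (which must form a
#' connected path, consecutive branches sharing an endpoint node) and
#' returns `nFrames` arc-length-uniform samples with unit tangents from the
#' spline derivative.
#'
#' @param skeleton a [CurveSkeleton-class] with fitted splines.
#' @param branchIds integer vector of branch indices, in traversal order.
#' @param nFrames number of samples.
#' @param dense internal arc-length table resolution per branch.
#' @return list with `positions` (nFrames x 3) and `tangents` (nFrames x 3,
#'   unit length).
#' @export
sampleCameraPath <- function(skeleton, branchIds, nFrames, dense = 400L) {
  stopifnot(nFrames >= 2L, length(branchIds) >= 1L)
  if (!length(skeleton@splines)) stop("skeleton has no fitted splines")
  ends <- lapply(skeleton@branches[branchIds], function(b)
    c(b[1], b[length(b)]))
  reversed <- logical(length(branchIds))
  if (length(branchIds) > 1L) {
    for (i in seq_along(branchIds)[-1]) {
      prev <- ends[[i - 1]]
      prevExit <- if (reversed[i - 1]) prev[1] else prev[2]
      if (ends[[i]][1] == prevExit) reversed[i] <- FALSE
      else if (ends[[i]][2] == prevExit) reversed[i] <- TRUE
      else stop("requested branches do not form a connected path")
    }
  }
  tables <- vector("list", length(branchIds))
  total <- 0
  for (i in seq_along(branchIds)) {
    sp <- skeleton@splines[[branchIds[i]]]
    tt <- seq(sp$range[1], sp$range[2], length.out = dense)
    if (reversed[i]) tt <- rev(tt)
    pts <- evalBSpline(sp, tt)
    arc <- c(0, cumsum(.rowNorm(diff(pts))))
    tables[[i]] <- list(sp = sp, t = tt, arc = total + arc,
                        rev = reversed[i])
    total <- total + arc[length(arc)]
  }
  targets <- seq(0, total, length.out = nFrames)
  pos <- matrix(0, nFrames, 3)
  tan <- matrix(0, nFrames, 3)
  for (k in seq_len(nFrames)) {
    s <- targets[k]
    i <- 1L
    while (i < length(tables) && s > tables[[i]]$arc[dense] + 1e-12)
      i <- i + 1L
    tb <- tables[[i]]
    tpar <- stats::approx(tb$arc, tb$t, xout = min(max(s, tb$arc[1]),
                                                   tb$arc[dense]))$y
    if (k == 1L) tpar <- tb$t[1]
    if (k == nFrames) tpar <- tables[[length(tables)]]$t[dense]
    if (k == nFrames) tb <- tables[[length(tables)]]
    pos[k, ] <- evalBSpline(tb$sp, tpar)
    d <- evalBSpline(tb$sp, tpar, deriv = 1)
    if (tb$rev) d <- -d
    tan[k, ] <- .unit(as.numeric(d))
  }
  list(positions = pos, tangents = tan)
}

#' Serialise a curve skeleton to JSON
#'
#' Writes nodes, branch polylines, junctions, spline coefficients and
#' per-node radii as a single JSON document.
#'
#' @param skeleton a [CurveSkeleton-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSkeletonJSON <- function(skeleton, path) {
  obj <- list(
    nodes = unname(as.matrix(skeleton@nodes)),
    branches = lapply(skeleton@branches, as.integer),
    junctions = as.integer(skeleton@junctions),
    radius = skeleton@radius,
    splines = lapply(skeleton@splines, function(sp)
      list(ord = sp$ord, knots = sp$knots,
           controlPoints = unname(sp$coef))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Export a curve skeleton as SWC
#'
#' SWC rows are `id type x y z radius parent` with 1-based ids; branch
#' traversal order defines parents, junction nodes are shared.
#'
#' @param skeleton a [CurveSkeleton-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSWC <- function(skeleton, path) {
  n <- nrow(skeleton@nodes)
  parent <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  order <- integer(0)
  for (b in skeleton@branches) {
    ids <- b
    if (any(seen[ids]) && !seen[ids[1]] && seen[ids[length(ids)]])
      ids <- rev(ids)
    for (k in seq_along(ids)) {
      v <- ids[k]
      if (!seen[v]) {
        parent[v] <- if (k == 1L) -1L else ids[k - 1L]
        seen[v] <- TRUE
        order <- c(order, v)
      }
    }
  }
  rad <- if (length(skeleton@radius)) skeleton@radius else rep(1, n)
  remap <- match(seq_len(n), order)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# SWC export (vessim): id type x y z radius parent", con)
  for (v in order) {
    p <- parent[v]
    writeLines(sprintf("%d 2 %.6f %.6f %.6f %.6f %d", remap[v],
                       skeleton@nodes[v, 1], skeleton@nodes[v, 2],
                       skeleton@nodes[v, 3], rad[v],
                       if (p == -1L) -1L else remap[p]), con)
  }
  invisible(path)
}
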