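# Local PCA classification of contracted points into joint vs branch points
# and BFS clustering of the joint points.

#' Largest-eigenvalue fraction of a local PCA neighbourhood
#'
#' For the neighbourhood of `points[queryIndex, ]` within `radius`, returns
#' `f = lambda1 / (lambda1 + lambda2 + lambda3)` with `lambda1 >= lambda2 >=
#' lambda3` the eigenvalues of the 3x3 covariance matrix of the neighbours.
#' `f` is near 1 on line-like runs, near 1/2 on planar patches and near 1/3
#' in isotropic blobs; its range is `[1/3, 1]`.
#'
#' @param points numeric n x 3 matrix.
#' @param queryIndex point whose neighbourhood is analysed.
#' @param radius neighbourhood radius (mm); at least 3 points must fall
#'   inside it (the query itself counts).
#' @param .neighbors optional precomputed neighbour indices (internal).
#' @return scalar f.
#' @export
pcaFeature <- function(points, queryIndex, radius, .neighbors = NULL) {
  nb <- if (is.null(.neighbors)) {
    d2 <- rowSums(sweep(points, 2, points[queryIndex, ])^2)
    which(d2 <= radius^2)
  } else .neighbors
  if (length(nb) < 3L)
    stop("fewer than 3 points within the PCA radius; enlarge the radius")
  P <- sweep(points[nb, , drop = FALSE], 2, colMeans(points[nb, , drop = FALSE]))
  ev <- eigen(crossprod(P) / length(nb), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  s <- sum(ev)
  if (s <= 0) return(1)  # coincident points: degenerate, fully "line-like"
  ev[1] / s
}

#' Classify contracted points as joint or branch points
#'
#' Computes the PCA feature f for every point and labels a point a joint
#' point iff `f < psiF` (a point with `f == psiF` exactly is a branch
#' point). The default threshold is 0.8.
#'
#' @param points numeric n x 3 matrix (contracted + subdivided mesh points).
#' @param radius PCA neighbourhood radius (mm).
#' @param psiF classification threshold (default 0.8).
#' @return a [ClassifiedPoints-class].
#' @export
classifyPoints <- function(points, radius, psiF = 0.8) {
  points <- as.matrix(points)
  nbs <- .radiusNeighborhoods(points, radius)
  f <- vapply(seq_len(nrow(points)), function(i) {
    if (length(nbs[[i]]) >= 3L)
      return(pcaFeature(points, i, radius, .neighbors = nbs[[i]]))
    # isolated point (can happen at contracted cap tips): widen locally
    r <- radius
    repeat {
      r <- 2 * r
      d2 <- rowSums(sweep(points, 2, points[i, ])^2)
      nb <- which(d2 <= r^2)
      if (length(nb) >= 3L) return(pcaFeature(points, i, r, .neighbors = nb))
    }
  }, numeric(1))
  labels <- ifelse(f < psiF, "joint", "branch")
  new("ClassifiedPoints", points = points, f = f, labels = labels,
      psiF = psiF, radius = radius)
}

#' Cluster joint points by BFS flood fill
#'
#' Starting from any unclustered joint point, a queue-based flood collects
#' every joint point reachable through the `neighborRadius` adjacency; the
#' resulting clusters partition the joint points. Cluster centers are the
#' arithmetic means of the member positions.
#'
#' @param classified a [ClassifiedPoints-class].
#' @param neighborRadius spatial adjacency radius (mm); defaults to the PCA
#'   radius used for classification.
#' @return list of [JointCluster-class] objects (empty if no joint points).
#' @export
clusterJoints <- function(classified, neighborRadius = classified@radius) {
  jointIdx <- which(classified@labels == "joint")
  if (!length(jointIdx)) return(list())
  P <- classified@points[jointIdx, , drop = FALSE]
  nbs <- .radiusNeighborhoods(P, neighborRadius)
  m <- length(jointIdx)
  clusterOf <- rep(0L, m)
  nclust <- 0L
  for (s in seq_len(m)) {
    if (clusterOf[s] != 0L) next
    nclust <- nclust + 1L
    clusterOf[s] <- nclust
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in nbs[[v]]) {
        if (clusterOf[u] == 0L) {
          clusterOf[u] <- nclust
          queue <- c(queue, u)
        }
      }
    }
  }
  lapply(seq_len(nclust), function(cid) {
    members <- jointIdx[clusterOf == cid]
    new("JointCluster", members = as.integer(members),
        center = colMeans(classified@points[members, , drop = FALSE]))
  })
}
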