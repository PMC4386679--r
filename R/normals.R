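# Point-cloud normal-field construction: covariance normals from k nearest
# neighbours, then sign propagation along a minimum spanning tree of the
# Riemannian k-NN graph (Hoppe-style orientation).

#' Estimate point normals by k-NN covariance analysis
#'
#' The normal of each point is the eigenvector of the covariance matrix of
#' its k nearest neighbours belonging to the smallest eigenvalue, normalised
#' to unit length. Signs are arbitrary at this stage; use
#' [orientNormalsMST()] to make them consistent.
#'
#' @param points numeric n x 3 matrix (mm).
#' @param k neighbour count, `3 <= k < n` (default 12, robust for tube-like
#'   sampling density).
#' @return an [OrientedPointCloud-class] with arbitrary normal signs.
#' @export
estimateNormals <- function(points, k = 12) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n - 1L) stop("k must be smaller than the number of points")
  if (k < 3L) stop("k must be at least 3")
  nb <- .knn(points, k)
  N <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    P <- points[c(i, nb[i, ]), , drop = FALSE]
    P <- sweep(P, 2, colMeans(P))
    ev <- eigen(crossprod(P), symmetric = TRUE)
    N[i, ] <- ev$vectors[, 3]
  }
  new("OrientedPointCloud", points = points,
      normals = N / sqrt(rowSums(N^2)))
}

#' Orient normals consistently via a minimum spanning tree
#'
#' Builds the Riemannian graph on k nearest neighbours with edge weight
#' `1 - |n_i . n_j|`, takes its minimum spanning tree, and propagates the
#' normal sign from the point with maximum z (whose normal is first flipped
#' toward +z) so that `n_i . n_j >= 0` along every tree edge. Directions are
#' never changed, only signs. A disconnected neighbour graph is oriented per
#' component with a warning, each component rooted at its own max-z point.
#'
#' @param cloud an [OrientedPointCloud-class] with normals present.
#' @param k neighbour count for the Riemannian graph (default 12).
#' @return an [OrientedPointCloud-class] with consistent signs.
#' @export
orientNormalsMST <- function(cloud, k = 12) {
  P <- cloud@points; N <- cloud@normals
  n <- nrow(P)
  if (n <= 1L) return(cloud)
  k <- min(k, n - 1L)
  nb <- .knn(P, k)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nb))
  keep <- ii < jj
  dup <- cbind(pmin(ii, jj), pmax(ii, jj))
  key <- (dup[, 1] - 1) * n + dup[, 2]
  first <- !duplicated(key)
  ed <- dup[first, , drop = FALSE]
  w <- 1 - abs(rowSums(N[ed[, 1], , drop = FALSE] * N[ed[, 2], , drop = FALSE]))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- pmax(w, 0)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    warning("k-NN graph is disconnected; orienting each component separately")
  mst <- igraph::mst(g)
  adj <- igraph::as_adj_list(mst, mode = "all")
  visited <- rep(FALSE, n)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    root <- members[which.max(P[members, 3])]
    if (N[root, 3] < 0) N[root, ] <- -N[root, ]
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in as.integer(adj[[v]])) {
        if (visited[u]) next
        if (sum(N[u, ] * N[v, ]) < 0) N[u, ] <- -N[u, ]
        visited[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  new("OrientedPointCloud", points = P, normals = N)
}
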