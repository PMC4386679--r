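# Spatial queries used throughout: uniform-grid radius search (cell lists)
# and chunked brute-force k-nearest neighbours. Point counts here are a few
# thousand, so these stay comfortably fast in plain R.

.gridIndex <- function(points, cell) {
  mins <- apply(points, 2, min)
  ijk <- floor(sweep(points, 2, mins) / cell)
  dims <- apply(ijk, 2, max) + 1
  key <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  buckets <- split(seq_len(nrow(points)), key)
  env <- new.env(hash = TRUE, size = length(buckets) * 2L)
  for (nm in names(buckets)) assign(nm, buckets[[nm]], envir = env)
  list(env = env, mins = mins, cell = cell, dims = dims, points = points)
}

.gridQuery <- function(g, p, radius) {
  ijk <- floor((p - g$mins) / g$cell)
  reach <- ceiling(radius / g$cell)
  off <- seq(-reach, reach)
  cand <- integer(0)
  for (dz in off) for (dy in off) for (dx in off) {
    i <- ijk[1] + dx; j <- ijk[2] + dy; k <- ijk[3] + dz
    if (i < 0 || j < 0 || k < 0 || i >= g$dims[1] || j >= g$dims[2] ||
        k >= g$dims[3]) next
    key <- as.character(i + g$dims[1] * (j + g$dims[2] * k))
    b <- get0(key, envir = g$env)
    if (!is.null(b)) cand <- c(cand, b)
  }
  if (!length(cand)) return(integer(0))
  d2 <- rowSums(sweep(g$points[cand, , drop = FALSE], 2, p)^2)
  cand[d2 <= radius^2]
}

# All-pairs radius neighbours, returned as a list of integer vectors
# (self included). Grid-accelerated.
.radiusNeighborhoods <- function(points, radius) {
  n <- nrow(points)
  g <- .gridIndex(points, max(radius, 1e-9))
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- .gridQuery(g, points[i, ], radius)
  out
}

# k nearest neighbours (excluding self) by chunked distance computation.
.knn <- function(points, k, chunk = 512L) {
  n <- nrow(points)
  if (k >= n) stop("k must be smaller than the number of points")
  idx <- matrix(0L, n, k)
  sq <- rowSums(points^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * points[s:e, , drop = FALSE] %*% t(points)
    for (r in seq_len(e - s + 1L)) {
      d <- d2[r, ]
      d[s + r - 1L] <- Inf
      idx[s + r - 1L, ] <- order(d)[seq_len(k)]
    }
  }
  idx
}
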