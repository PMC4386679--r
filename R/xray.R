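# Fluoroscopy simulation: per-pixel linear material thickness through the
# scene (triangle rasterization for meshes, analytic capsule chords for rod
# chains) followed by Beer-Lambert attenuation I = exp(-sigma * u).
# A CPU ray caster computes the same per-pixel thickness a GPU
# multi-render-target pass would; there is no real-time requirement here.

.rayHits <- function(mesh, origin, dir) {
  V <- mesh@vertices; Fm <- mesh@faces
  A <- V[Fm[, 1], , drop = FALSE]
  e1 <- V[Fm[, 2], , drop = FALSE] - A
  e2 <- V[Fm[, 3], , drop = FALSE] - A
  dmat <- matrix(dir, nrow(A), 3, byrow = TRUE)
  pvec <- .rowCross(dmat, e2)
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- sweep(-A, 2, origin, "+")          # origin - A
  u <- rowSums(tvec * pvec) / det
  qvec <- .rowCross(tvec, e1)
  v <- rowSums(dmat * qvec) / det
  t <- rowSums(e2 * qvec) / det
  hit <- ok & u >= -1e-10 & v >= -1e-10 & (u + v) <= 1 + 1e-10
  list(t = t[hit], entering = det[hit] > 0)  # det = -dir . faceNormal
}

#' Is a point inside a closed mesh?
#'
#' Ray-parity test: a point is interior iff a ray from it crosses the
#' surface an odd number of times.
#'
#' @param mesh a closed [TriangleMesh-class].
#' @param points numeric n x 3 matrix.
#' @param dir probe direction (default a fixed irrational-ish direction to
#'   dodge edge-on hits).
#' @return logical vector.
#' @export
meshContains <- function(mesh, points, dir = c(0.2135, 0.5341, 0.8162)) {
  dir <- .unit(dir)
  points <- as.matrix(points)
  vapply(seq_len(nrow(points)), function(i) {
    h <- .rayHits(mesh, points[i, ], dir)
    sum(h$t > 1e-9) %% 2L == 1L
  }, logical(1))
}

#' Linear thickness of a mesh along one ray
#'
#' Intersects the ray with every triangle (Moller-Trumbore), sorts the hits
#' along the ray and sums `t_exit - t_entry` over entry/exit pairs.
#' Unbalanced hit sequences (open meshes, grazing hits) are repaired by
#' dropping the farthest unmatched hits with a warning.
#'
#' @param mesh a closed, consistently wound [TriangleMesh-class].
#' @param origin ray origin (length 3).
#' @param dir ray direction (length 3, need not be unit; thickness is
#'   reported in metric units along the normalised direction).
#' @return thickness in mm.
#' @export
rayThickness <- function(mesh, origin, dir) {
  dir <- .unit(dir)
  hits <- .rayHits(mesh, origin, dir)
  if (!length(hits$t)) return(0)
  th <- hits$t
  entering <- hits$entering
  ord <- order(th)
  th <- th[ord]; entering <- entering[ord]
  nin <- sum(entering); nout <- sum(!entering)
  if (nin != nout) {
    warning("unbalanced ray-mesh intersections; dropping unmatched hits")
    while (sum(entering) > sum(!entering)) {
      k <- max(which(entering)); th <- th[-k]; entering <- entering[-k]
    }
    while (sum(!entering) > sum(entering)) {
      k <- max(which(!entering)); th <- th[-k]; entering <- entering[-k]
    }
  }
  depth <- 0; tIn <- 0; u <- 0
  for (i in seq_along(th)) {
    if (entering[i]) {
      if (depth == 0) tIn <- th[i]
      depth <- depth + 1
    } else {
      depth <- depth - 1
      if (depth == 0) u <- u + th[i] - tIn
    }
  }
  u
}

#' Orthographic camera for a scene
#'
#' @param center view center (mm).
#' @param dir unit view direction (X-ray beam direction).
#' @param up approximate up vector.
#' @param width,height physical extent of the image plane (mm).
#' @return camera list for [XRayScene-class].
#' @export
orthoCamera <- function(center, dir, up = c(0, 0, 1), width = 50,
                        height = 50) {
  list(type = "ortho", center = center, dir = .unit(dir), up = up,
       width = width, height = height)
}

#' Pinhole (C-arm-like perspective) camera
#'
#' @param position camera position (mm).
#' @param lookat point the camera looks at.
#' @param up approximate up vector.
#' @param fov vertical field of view (radians).
#' @return camera list for [XRayScene-class].
#' @export
pinholeCamera <- function(position, lookat, up = c(0, 0, 1), fov = pi / 4) {
  list(type = "pinhole", position = position, lookat = lookat, up = up,
       fov = fov)
}

#' Construct an X-ray scene
#'
#' @param objects list of objects: `list(mesh = , sigma = )` or
#'   `list(chain = , radius = , sigma = )`.
#' @param camera from [orthoCamera()] or [pinholeCamera()].
#' @param size image `c(width, height)` in pixels.
#' @return an [XRayScene-class].
#' @export
XRayScene <- function(objects, camera, size = c(256L, 256L)) {
  new("XRayScene", objects = objects, camera = camera,
      size = as.integer(size))
}

.cameraBasis <- function(cam) {
  if (cam$type == "ortho") {
    d <- .unit(cam$dir)
    r <- .unit(.rowCross(rbind(d), rbind(cam$up))[1, ])
    u <- .rowCross(rbind(r), rbind(d))[1, ]
    list(d = d, r = r, u = u)
  } else {
    d <- .unit(cam$lookat - cam$position)
    r <- .unit(.rowCross(rbind(d), rbind(cam$up))[1, ])
    u <- .rowCross(rbind(r), rbind(d))[1, ]
    list(d = d, r = r, u = u)
  }
}

# Per-pixel thickness of one mesh: triangle rasterization in image space
# with a half-open edge rule so shared edges are never double counted; each
# covered pixel accumulates sign(dir . n) * t, which telescopes to the
# entry/exit thickness for closed meshes.
.rasterMeshThickness <- function(mesh, cam, W, H) {
  bs <- .cameraBasis(cam)
  V <- mesh@vertices; Fm <- mesh@faces
  U <- matrix(0, H, W)
  persp <- cam$type == "pinhole"
  if (persp) {
    rel <- sweep(V, 2, cam$position)
    Z <- rel %*% bs$d
    if (any(Z <= 1e-9)) stop("pinhole camera: mesh vertex behind the camera")
    focal <- (H / 2) / tan(cam$fov / 2)
    px <- (rel %*% bs$r) / Z * focal + (W + 1) / 2
    py <- (H + 1) / 2 - (rel %*% bs$u) / Z * focal
  } else {
    rel <- sweep(V, 2, cam$center)
    px <- (rel %*% bs$r) / cam$width * W + (W + 1) / 2
    py <- (H + 1) / 2 - (rel %*% bs$u) / cam$height * H
  }
  for (f in seq_len(nrow(Fm))) {
    i1 <- Fm[f, 1]; i2 <- Fm[f, 2]; i3 <- Fm[f, 3]
    n <- .rowCross(rbind(V[i2, ] - V[i1, ]), rbind(V[i3, ] - V[i1, ]))[1, ]
    xs <- c(px[i1], px[i2], px[i3])
    ys <- c(py[i1], py[i2], py[i3])
    c0 <- max(1L, ceiling(min(xs) - 1e-9))
    c1 <- min(W, floor(max(xs) + 1e-9))
    r0 <- max(1L, ceiling(min(ys) - 1e-9))
    r1 <- min(H, floor(max(ys) + 1e-9))
    if (c0 > c1 || r0 > r1) next
    area <- (xs[2] - xs[1]) * (ys[3] - ys[1]) - (xs[3] - xs[1]) * (ys[2] - ys[1])
    if (area == 0) next
    ord <- if (area > 0) c(1L, 2L, 3L) else c(1L, 3L, 2L)
    xs2 <- xs[ord]; ys2 <- ys[ord]
    cols <- c0:c1; rows <- r0:r1
    PX <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    PY <- matrix(rows, length(rows), length(cols))
    inside <- NULL
    for (e in 1:3) {
      ax <- xs2[e]; ay <- ys2[e]
      bx <- xs2[e %% 3 + 1]; by <- ys2[e %% 3 + 1]
      E <- (bx - ax) * (PY - ay) - (by - ay) * (PX - ax)
      topleft <- (by > ay) || (by == ay && bx < ax)
      accept <- if (topleft) E >= 0 else E > 0
      inside <- if (is.null(inside)) accept else inside & accept
    }
    if (!any(inside)) next
    # ray parameter t at the covered pixels (plane intersection)
    if (persp) {
      focal <- (H / 2) / tan(cam$fov / 2)
      a <- (PX[inside] - (W + 1) / 2) / focal
      b <- ((H + 1) / 2 - PY[inside]) / focal
      dirs <- outer(a, bs$r) + outer(b, bs$u) +
        matrix(bs$d, sum(inside), 3, byrow = TRUE)
      dn <- .rowNorm(dirs)
      dirs <- dirs / dn
      no <- sum(n * cam$position)
      nd <- dirs %*% n
      tt <- (sum(n * V[i1, ]) - no) / nd
      sgn <- sign(nd)
    } else {
      a <- (PX[inside] - (W + 1) / 2) / W * cam$width
      b <- ((H + 1) / 2 - PY[inside]) / H * cam$height
      no <- sum(n * cam$center) + a * sum(n * bs$r) + b * sum(n * bs$u)
      nd <- sum(n * bs$d)
      if (abs(nd) < 1e-14) next
      tt <- (sum(n * V[i1, ]) - no) / nd
      sgn <- sign(nd)
    }
    idx <- which(inside)
    U[cbind(PY[idx], PX[idx])] <- U[cbind(PY[idx], PX[idx])] + sgn * tt
  }
  pmax(U, 0)
}

# analytic per-pixel chord length through the union of rod capsules
.chainThickness <- function(chain, radius, cam, W, H) {
  bs <- .cameraBasis(cam)
  cols <- seq_len(W); rows <- seq_len(H)
  PX <- matrix(cols, H, W, byrow = TRUE)
  PY <- matrix(rows, H, W)
  if (cam$type == "ortho") {
    a <- (PX - (W + 1) / 2) / W * cam$width
    b <- ((H + 1) / 2 - PY) / H * cam$height
    O <- cbind(as.vector(a), as.vector(b)) %*% rbind(bs$r, bs$u)
    O <- sweep(O, 2, cam$center, "+")
    D <- matrix(bs$d, nrow(O), 3, byrow = TRUE)
  } else {
    focal <- (H / 2) / tan(cam$fov / 2)
    a <- (PX - (W + 1) / 2) / focal
    b <- ((H + 1) / 2 - PY) / focal
    D <- cbind(as.vector(a), as.vector(b)) %*% rbind(bs$r, bs$u)
    D <- D + matrix(bs$d, nrow(D), 3, byrow = TRUE)
    D <- D / .rowNorm(D)
    O <- matrix(cam$position, nrow(D), 3, byrow = TRUE)
  }
  X <- chain@joints
  total <- numeric(nrow(O))
  for (i in seq_len(nrow(X) - 1L)) {
    A <- X[i, ]; B <- X[i + 1L, ]
    u <- .unit(B - A)
    L <- sqrt(sum((B - A)^2))
    w <- sweep(O, 2, A)
    du <- D %*% u
    wu <- w %*% u
    dd <- D - du %*% rbind(u)
    ww <- w - wu %*% rbind(u)
    tIn <- rep(Inf, nrow(O)); tOut <- rep(-Inf, nrow(O))
    # infinite cylinder clipped to the slab 0 <= s <= L
    aq <- rowSums(dd^2)
    bq <- 2 * rowSums(ww * dd)
    cq <- rowSums(ww^2) - radius^2
    disc <- bq^2 - 4 * aq * cq
    okc <- disc > 0 & aq > 1e-14
    if (any(okc)) {
      sq <- sqrt(disc[okc])
      t1 <- (-bq[okc] - sq) / (2 * aq[okc])
      t2 <- (-bq[okc] + sq) / (2 * aq[okc])
      s1 <- wu[okc] + t1 * du[okc]
      s2 <- wu[okc] + t2 * du[okc]
      dus <- du[okc]
      lo <- t1; hi <- t2
      # clip the [t1, t2] interval to the axial slab
      nz <- abs(dus) > 1e-14
      tsA <- ifelse(nz, (0 - wu[okc]) / dus, -Inf)
      tsB <- ifelse(nz, (L - wu[okc]) / dus, Inf)
      slo <- pmin(tsA, tsB); shi <- pmax(tsA, tsB)
      par <- !nz & (wu[okc] < 0 | wu[okc] > L)
      lo2 <- pmax(lo, slo); hi2 <- pmin(hi, shi)
      val <- hi2 > lo2 & !par
      idx <- which(okc)[val]
      tIn[idx] <- pmin(tIn[idx], lo2[val])
      tOut[idx] <- pmax(tOut[idx], hi2[val])
    }
    for (Cc in list(A, B)) {
      wc <- sweep(O, 2, Cc)
      bq <- 2 * rowSums(wc * D)
      cq <- rowSums(wc^2) - radius^2
      disc <- bq^2 - 4 * cq
      oks <- disc > 0
      if (any(oks)) {
        sq <- sqrt(disc[oks])
        t1 <- (-bq[oks] - sq) / 2
        t2 <- (-bq[oks] + sq) / 2
        idx <- which(oks)
        tIn[idx] <- pmin(tIn[idx], t1)
        tOut[idx] <- pmax(tOut[idx], t2)
      }
    }
    hit <- tOut > tIn
    total[hit] <- total[hit] + (tOut[hit] - tIn[hit])
  }
  matrix(total, H, W)
}

#' Render an X-ray image of a scene
#'
#' Computes the per-pixel linear thickness `u_j` of every object and sets
#' `I = exp(-sum_j sigma_j u_j)`: attenuations of overlapping objects
#' multiply (Beer-Lambert composition). Rod chains are rendered as unions
#' of capsules of the instrument radius. Pixels traversed by no object have
#' intensity exactly 1.
#'
#' @param scene an [XRayScene-class].
#' @return an [XRayImage-class].
#' @export
renderXray <- function(scene) {
  W <- scene@size[1]; H <- scene@size[2]
  Aacc <- matrix(0, H, W)
  for (ob in scene@objects) {
    u <- if (!is.null(ob$mesh))
      .rasterMeshThickness(ob$mesh, scene@camera, W, H)
    else
      .chainThickness(ob$chain, ob$radius, scene@camera, W, H)
    Aacc <- Aacc + ob$sigma * u
  }
  new("XRayImage", pixels = exp(-Aacc))
}

#' Write an X-ray image to PNG or PGM
#'
#' Linear mapping of [0,1] to the integer code range with round-half-up
#' quantization (`floor(I * maxcode + 0.5)`); PNG output is 8-bit, PGM
#' supports 8- or 16-bit.
#'
#' @param img an [XRayImage-class].
#' @param path output path.
#' @param format `"png"`, `"pgm"` or `"auto"` (by extension).
#' @param bits 8 or 16 (16 requires PGM).
#' @return invisibly, `path`.
#' @export
writeXrayImage <- function(img, path, format = c("auto", "png", "pgm"),
                           bits = 8) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "pgm") "pgm" else "png"
  }
  maxcode <- 2^bits - 1
  codes <- floor(img@pixels * maxcode + 0.5)
  if (format == "png") {
    if (bits != 8) stop("PNG output is 8-bit; use PGM for 16-bit")
    png::writePNG(codes / maxcode, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(codes), nrow(codes)),
                 sprintf("%d", maxcode)), con)
    writeLines(apply(codes, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read back an image written by [writeXrayImage()]
#'
#' @param path PNG or PGM path.
#' @return an [XRayImage-class].
#' @export
readXrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    stopifnot(toks[1] == "P2")
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    maxc <- as.numeric(toks[4])
    vals <- as.numeric(toks[-(1:4)])
    new("XRayImage", pixels = matrix(vals, h, w, byrow = TRUE) / maxc)
  } else {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    new("XRayImage", pixels = p)
  }
}
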