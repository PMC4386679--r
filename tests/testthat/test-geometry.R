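# Mesh I/O, signed volume, cotangent Laplacian and normal-field
# construction.

test_that("mesh I/O round-trips across the supported formats", {
  tmp <- withr::local_tempdir()
  # smallest valid mesh via OBJ
  obj <- file.path(tmp, "tri.obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), obj)
  m <- readMesh(obj)
  expect_equal(nVertices(m), 3L)
  expect_equal(nFaces(m), 1L)

  cube <- unitCube()
  for (fmt in c("obj", "ply", "stl")) {
    p <- file.path(tmp, paste0("cube.", fmt))
    writeMesh(cube, p)
    back <- readMesh(p)
    expect_equal(meshVolume(back), 1, tolerance = 1e-9)
    if (fmt != "stl") expect_identical(back@vertices, cube@vertices)
  }
  # STL welding: 12 facets, duplicates merged back to 8 vertices
  p <- file.path(tmp, "cube.stl")
  welded <- readMesh(p, weld = TRUE)
  expect_equal(nFaces(welded), 12L)
  expect_equal(nVertices(welded), 8L)
  expect_equal(nVertices(readMesh(p, weld = FALSE)), 36L)

  # binary STL and PLY agree with their ASCII dialects
  pb <- file.path(tmp, "cube-bin.stl")
  writeMesh(cube, pb, binary = TRUE)
  expect_equal(meshVolume(readMesh(pb)), 1, tolerance = 1e-6)
  tube <- smallTube()
  pa <- file.path(tmp, "tube-a.ply"); pbin <- file.path(tmp, "tube-b.ply")
  writeMesh(tube, pa); writeMesh(tube, pbin, binary = TRUE)
  va <- meshVertices(readMesh(pa)); vb <- meshVertices(readMesh(pbin))
  expect_equal(va, vb, tolerance = 1e-6)
  expect_identical(meshFaces(readMesh(pa)), meshFaces(readMesh(pbin)))

  expect_error(writeMesh(new("TriangleMesh"), file.path(tmp, "e.obj")),
               "empty")
  expect_error(readMesh(file.path(tmp, "absent.ply")), "cannot read")
})

test_that("point clouds round-trip through PLY and text", {
  tmp <- withr::local_tempdir()
  set.seed(7)
  P <- matrix(rnorm(60), 20, 3)
  N <- P / sqrt(rowSums(P^2))
  cl <- new("OrientedPointCloud", points = P, normals = N)
  for (p in file.path(tmp, c("c.ply", "c.txt"))) {
    writePointCloud(cl, p)
    back <- readPointCloud(p)
    expect_equal(back@points, P, tolerance = 1e-6)
    expect_equal(back@normals, N, tolerance = 1e-6)
  }
})

test_that("signed mesh volume matches closed forms and scaling", {
  cube <- unitCube()
  expect_equal(meshVolume(cube), 1)
  # icosphere R = 2, 4 subdivision rounds vs (4/3) pi R^3
  sph <- makeIcosphere(2, 4)
  expect_lt(abs(meshVolume(sph) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.01)
  # all-coplanar mesh has no volume
  flat <- TriangleMesh(cbind(matrix(runif(8), 4, 2), 0),
                       rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(meshVolume(flat), 0)
  # scale invariance: volume(s * cube) = s^3 volume(cube)
  for (s in c(0.5, 3)) {
    scaled <- TriangleMesh(cube@vertices * s, cube@faces)
    expect_equal(meshVolume(scaled), s^3 * meshVolume(cube),
                 tolerance = 1e-12)
  }
})

test_that("cotangent Laplacian has zero row sums and hand-checked weights", {
  for (mesh in list(unitCube(), smallTube())) {
    L <- cotanLaplacian(mesh)
    expect_lt(max(abs(Matrix::rowSums(L))) / max(abs(L)), 1e-9)
    expect_true(Matrix::isSymmetric(L))
  }
  # right isoceles triangle: the edge opposite the right angle gets
  # cot(90 deg) / 2 = 0; the others cot(45 deg) / 2 = 1/2
  tri <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  L <- cotanLaplacian(tri)
  expect_equal(L[2, 3], 0, tolerance = 1e-12)
  expect_equal(L[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(L[1, 3], 0.5, tolerance = 1e-12)
  # equilateral triangle: all off-diagonals equal by symmetry
  eq <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                     rbind(c(1, 2, 3)))
  Le <- cotanLaplacian(eq)
  expect_equal(Le[1, 2], Le[1, 3], tolerance = 1e-12)
  expect_equal(Le[1, 2], Le[2, 3], tolerance = 1e-12)
  # non-manifold edge is rejected by name
  bad <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                            c(1, 1, 1)),
                      rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(cotanLaplacian(bad), "non-manifold")
})

test_that("covariance normals recover analytic surface normals", {
  # exact planar case
  set.seed(42)
  P <- cbind(matrix(runif(400, -5, 5), 200, 2), 0)
  cl <- estimateNormals(P, k = 12)
  expect_true(all(abs(abs(cl@normals[, 3]) - 1) < 1e-6))
  # sphere: radial ground truth within 5 degrees for >= 99% of points
  sph <- makeIcosphere(10, 3)
  S <- meshVertices(sph)
  cs <- estimateNormals(S, k = 12)
  rad <- S / sqrt(rowSums(S^2))
  ang <- acos(pmin(1, abs(rowSums(cs@normals * rad))))
  expect_gte(mean(ang < 5 * pi / 180), 0.99)
  # collinear points: normal is orthogonal to the line (any such vector)
  line <- cbind(seq(0, 1, length.out = 4), 0, 0)
  cn <- estimateNormals(line, k = 3)
  expect_true(all(abs(cn@normals[, 1]) < 1e-9))
  expect_error(estimateNormals(line, k = 5), "k must be")
})

test_that("normal estimation is rotation-equivariant up to sign", {
  # generic-position cloud: the icosphere's symmetric neighbour ties would
  # make the k-NN sets themselves orientation dependent
  set.seed(11)
  P <- matrix(rnorm(540), 180, 3)
  P <- 5 * P / sqrt(rowSums(P^2)) + matrix(rnorm(540, 0, 0.05), 180, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(1.1), -sin(1.1)), c(0, sin(1.1), cos(1.1)))
  n1 <- estimateNormals(P, 12)@normals %*% t(R)
  n2 <- estimateNormals(P %*% t(R), 12)@normals
  agree <- abs(rowSums(n1 * n2))
  expect_true(all(agree > 1 - 1e-6))
})

test_that("MST propagation yields a consistent outward orientation", {
  set.seed(3)
  # plane with scrambled signs: one consistent sign after propagation
  P <- cbind(matrix(runif(300, -5, 5), 150, 2), 0)
  N <- matrix(rep(c(0, 0, 1), each = 150), ncol = 3) *
    sample(c(-1, 1), 150, replace = TRUE)
  out <- orientNormalsMST(new("OrientedPointCloud", points = P, normals = N))
  expect_true(all(out@normals[, 3] > 0) || all(out@normals[, 3] < 0))
  # directions untouched, only signs
  expect_true(all(abs(abs(rowSums(out@normals * N)) - 1) < 1e-12))
  # closed sphere: >= 99% outward after propagation from the max-z root
  S <- meshVertices(makeIcosphere(10, 3))
  cs <- estimateNormals(S, 12)
  or <- orientNormalsMST(cs, 12)
  rad <- S / sqrt(rowSums(S^2))
  expect_gte(mean(rowSums(or@normals * rad) > 0), 0.99)
  # single point passes through unchanged
  one <- new("OrientedPointCloud", points = rbind(c(0, 0, 0)),
             normals = rbind(c(0, 0, 1)))
  expect_identical(orientNormalsMST(one)@normals, one@normals)
})
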