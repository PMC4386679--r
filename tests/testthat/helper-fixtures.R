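# Shared fixtures, generated once per test run and cached: phantom meshes at
# the study resolution (32 x 80 for swept tubes) and the extracted skeletons
# the acceptance checks reuse.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

cylinderPhantom <- function() fixture("cylinder", function()
  makePhantom("cylinder", radius = 2, length = 40,
              circumferential = 32, axial = 80))

torusPhantom <- function() fixture("torus", function()
  makePhantom("torus_segment", lumenRadius = 2, bendRadius = 20,
              angle = pi / 2, circumferential = 32, axial = 80))

yPhantom <- function() fixture("y", function()
  makePhantom("y_bifurcation", lumenRadius = 2, trunkLength = 20,
              daughterLength = 15, daughterAngle = pi / 6))

doubleYPhantom <- function() fixture("doubley", function()
  makeDoubleYPhantom())

cylinderSkeleton <- function() fixture("cylinderSkel", function()
  extractCenterline(cylinderPhantom()$mesh))

torusSkeleton <- function() fixture("torusSkel", function()
  extractCenterline(torusPhantom()$mesh))

ySkeleton <- function() fixture("ySkel", function()
  extractCenterline(yPhantom()$mesh))

# distance from each point to the union of analytic centerlines of a phantom
distToTruthCenterline <- function(points, phantom) {
  cls <- do.call(rbind, phantom$truth$centerlines)
  vessim:::.nearestDistance(as.matrix(points), cls)
}

# small low-resolution tube mesh for fast mesh-level tests
smallTube <- function() fixture("smallTube", function()
  makePhantom("cylinder", radius = 2, length = 20,
              circumferential = 12, axial = 20)$mesh)

# axis-aligned box of extent w x h spanning z in [0, d]
slabMesh <- function(w = 10, h = 10, d = 3) {
  V <- as.matrix(expand.grid(c(-w / 2, w / 2), c(-h / 2, h / 2), c(0, d)))
  dimnames(V) <- NULL
  q <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
             c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  Fm <- do.call(rbind, lapply(seq_len(6), function(i)
    rbind(q[i, c(1, 2, 3)], q[i, c(1, 3, 4)])))
  m <- TriangleMesh(V, Fm)
  if (meshVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

# a unit cube surface mesh (12 triangles, 8 vertices)
unitCube <- function() {
  V <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  dimnames(V) <- NULL
  quads <- rbind(
    c(1, 3, 4, 2),   # z = 0 (outward -z)
    c(5, 6, 8, 7),   # z = 1
    c(1, 2, 6, 5),   # y = 0
    c(3, 7, 8, 4),   # y = 1
    c(1, 5, 7, 3),   # x = 0
    c(2, 4, 8, 6))   # x = 1
  Fm <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i)
    rbind(quads[i, c(1, 2, 3)], quads[i, c(1, 3, 4)])))
  TriangleMesh(V, Fm)
}
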