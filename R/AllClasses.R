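#' @import methods
#' @importFrom stats setNames
NULL

.checkMat3 <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x) || (nrow(x) > 0L && ncol(x) != 3L))
    return(sprintf("%s must be a numeric matrix with 3 columns", what))
  if (anyNA(x)) return(sprintf("%s contains NA", what))
  NULL
}

#' Triangulated surface mesh
#'
#' A triangle mesh with vertex positions in millimetres and 1-based face
#' indices. Watertightness (every edge shared by exactly two consistently
#' wound faces) is a checkable predicate, see [isWatertight()], not a class
#' invariant: open meshes are legal and produce documented signed results in
#' [meshVolume()].
#'
#' @slot vertices numeric n x 3 matrix of vertex positions (mm).
#' @slot faces integer m x 3 matrix of vertex indices (1-based).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3)),
  validity = function(object) {
    msg <- .checkMat3(object@vertices, "vertices")
    if (!is.null(msg)) return(msg)
    f <- object@faces
    if (!is.matrix(f) || (nrow(f) > 0L && ncol(f) != 3L))
      return("faces must be a matrix with 3 columns")
    if (nrow(f) > 0L) {
      if (anyNA(f)) return("faces contain NA")
      if (min(f) < 1L || max(f) > nrow(object@vertices))
        return("face index out of vertex range")
      deg <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
      if (any(deg))
        return(sprintf("degenerate face (repeated vertex index) at row %d",
                       which(deg)[1]))
    }
    TRUE
  })

#' Oriented point cloud
#'
#' Points with unit normals, one per point. Normal signs may be arbitrary
#' until [orientNormalsMST()] has been applied.
#'
#' @slot points numeric n x 3 matrix (mm).
#' @slot normals numeric n x 3 matrix of unit vectors.
#' @export
setClass("OrientedPointCloud",
  representation(points = "matrix", normals = "matrix"),
  validity = function(object) {
    msg <- .checkMat3(object@points, "points")
    if (!is.null(msg)) return(msg)
    msg <- .checkMat3(object@normals, "normals")
    if (!is.null(msg)) return(msg)
    if (nrow(object@points) != nrow(object@normals))
      return("points and normals must have equal length")
    if (nrow(object@normals) > 0L) {
      nr <- sqrt(rowSums(object@normals^2))
      if (any(abs(nr - 1) > 1e-9))
        return("normals must be unit length within 1e-9")
    }
    TRUE
  })

#' State of the Laplacian contraction iteration
#'
#' Bookkeeping for the contraction loop: per-vertex attraction weights, the
#' global contraction weight, one-ring areas, and the volume trace. Vertex
#' count and face connectivity are identical across iterations; contraction
#' moves vertices only.
#'
#' @slot WL numeric scalar, current contraction weight.
#' @slot WH numeric vector, current per-vertex attraction weights.
#' @slot WH0 numeric vector, initial per-vertex attraction weights.
#' @slot A0 numeric vector, original one-ring areas.
#' @slot At numeric vector, current one-ring areas.
#' @slot sL numeric scalar, contraction speed-up coefficient.
#' @slot iterations integer, iterations performed.
#' @slot volumes numeric vector, |volume| after each iteration (index 1 is
#'   the input volume).
#' @slot converged logical, TRUE if the volume stop criterion was met.
#' @export
setClass("ContractionState",
  representation(WL = "numeric", WH = "numeric", WH0 = "numeric",
                 A0 = "numeric", At = "numeric", sL = "numeric",
                 iterations = "integer", volumes = "numeric",
                 converged = "logical"),
  validity = function(object) {
    if (any(object@WH <= 0) || any(object@WL <= 0))
      return("contraction weights must stay positive")
    TRUE
  })

#' Points classified as joint or branch by local PCA
#'
#' @slot points numeric n x 3 matrix.
#' @slot f numeric vector, largest-eigenvalue fraction per point, in [1/3, 1].
#' @slot labels character vector, "joint" or "branch".
#' @slot psiF numeric, classification threshold (joint iff f < psiF).
#' @slot radius numeric, PCA neighbourhood radius (mm).
#' @export
setClass("ClassifiedPoints",
  representation(points = "matrix", f = "numeric", labels = "character",
                 psiF = "numeric", radius = "numeric"),
  validity = function(object) {
    n <- nrow(object@points)
    if (length(object@f) != n || length(object@labels) != n)
      return("f and labels must match point count")
    if (n > 0L && (min(object@f) < 0 - 1e-12 || max(object@f) > 1 + 1e-12))
      return("f values must lie in [0, 1]")
    if (!all(object@labels %in% c("joint", "branch")))
      return("labels must be 'joint' or 'branch'")
    bad <- (object@labels == "joint") != (object@f < object@psiF)
    if (any(bad)) return("label must be joint iff f < psiF")
    TRUE
  })

#' A cluster of joint points
#'
#' @slot members integer vector of point indices (into the classified set).
#' @slot center numeric length-3, arithmetic mean of member positions.
#' @export
setClass("JointCluster",
  representation(members = "integer", center = "numeric"),
  validity = function(object) {
    if (length(object@members) < 1L) return("cluster must have members")
    if (length(object@center) != 3L) return("center must be length 3")
    TRUE
  })

#' Curve skeleton of a vessel
#'
#' Branch polylines over a shared node set, junction nodes where three or
#' more branches meet, a fitted cubic B-spline per branch, and an optional
#' per-node lumen radius estimate.
#'
#' @slot nodes numeric n x 3 matrix of skeleton node positions (mm).
#' @slot branches list of integer vectors; each an ordered node-index polyline.
#' @slot junctions integer vector of node indices with branch degree >= 3.
#' @slot splines list of B-spline fits (see [fitBSpline()]), one per branch.
#' @slot radius numeric per-node lumen radius (mm), may be empty.
#' @export
setClass("CurveSkeleton",
  representation(nodes = "matrix", branches = "list", junctions = "integer",
                 splines = "list", radius = "numeric"),
  prototype(junctions = integer(0), splines = list(), radius = numeric(0)),
  validity = function(object) {
    msg <- .checkMat3(object@nodes, "nodes")
    if (!is.null(msg)) return(msg)
    for (b in object@branches) {
      if (length(b) < 2L) return("every branch needs at least 2 nodes")
      if (min(b) < 1L || max(b) > nrow(object@nodes))
        return("branch node index out of range")
      if (any(b[-1] == b[-length(b)]))
        return("consecutive branch nodes must be distinct")
    }
    if (length(object@splines) > 0L &&
        length(object@splines) != length(object@branches))
      return("one spline per branch required when splines are present")
    TRUE
  })

#' Discrete guidewire/catheter state
#'
#' A chain of rigid rods between ordered joints, base (entry side) first.
#' Rods bend at interior joints but do not stretch: every simulation step
#' restores each rod length to its stored rest length within 1e-6 relative.
#'
#' @slot joints numeric (n+1) x 3 matrix of joint positions, base to tip (mm).
#' @slot restLengths numeric vector of n rod rest lengths (mm).
#' @slot phi numeric vector of n-1 intrinsic bias angles at interior joints
#'   (radians, in [0, pi)).
#' @slot stiffness numeric vector of n-1 bending stiffnesses (energy/rad^2).
#' @slot insertedLength numeric, wire length past the entry point (mm).
#' @slot tipRoll numeric, accumulated twist angle (radians).
#' @export
setClass("RodChain",
  representation(joints = "matrix", restLengths = "numeric", phi = "numeric",
                 stiffness = "numeric", insertedLength = "numeric",
                 tipRoll = "numeric"),
  prototype(insertedLength = 0, tipRoll = 0),
  validity = function(object) {
    msg <- .checkMat3(object@joints, "joints")
    if (!is.null(msg)) return(msg)
    n <- nrow(object@joints) - 1L
    if (n < 1L) return("chain needs at least one rod (two joints)")
    if (length(object@restLengths) != n)
      return("restLengths must have one entry per rod")
    if (any(object@restLengths <= 0))
      return("rod lengths must be positive (consecutive joints distinct)")
    ni <- max(0L, n - 1L)
    if (length(object@phi) != ni || length(object@stiffness) != ni)
      return("phi and C must have one entry per interior joint")
    if (ni > 0L && (any(object@phi < 0) || any(object@phi >= pi)))
      return("intrinsic bias angles must lie in [0, pi)")
    TRUE
  })

#' Vessel lumen model for collision queries
#'
#' Analytic lumen: one or more centerline polylines with per-station radii,
#' plus the wall elasticity and rupture threshold. A point is inside the
#' lumen if it is within the local radius of any branch. An optional surface
#' mesh of the same lumen can be attached for rendering and cross-validation.
#'
#' @slot branches list; each element a list with `stations` (k x 3 matrix of
#'   centerline samples), `radii` (length-k), and `arc` (cumulative arc
#'   length).
#' @slot kV numeric, elastic coefficient of the vessel wall (force/mm).
#' @slot FRupture numeric, boundary (rupture) force threshold; may be `Inf`.
#' @slot mesh a [TriangleMesh-class] of the lumen surface, possibly empty.
#' @export
setClass("VesselModel",
  representation(branches = "list", kV = "numeric", FRupture = "numeric",
                 mesh = "TriangleMesh"),
  prototype(kV = 0.5, FRupture = Inf, mesh = new("TriangleMesh")),
  validity = function(object) {
    if (length(object@branches) < 1L) return("vessel needs >= 1 branch")
    for (b in object@branches) {
      if (!all(c("stations", "radii", "arc") %in% names(b)))
        return("each branch needs stations, radii, arc")
      if (nrow(b$stations) != length(b$radii))
        return("radii must match station count")
      if (any(b$radii <= 0)) return("lumen radius must be positive")
    }
    if (object@kV <= 0) return("kV must be positive")
    if (object@FRupture <= 0) return("FRupture must be positive")
    TRUE
  })

#' Per-joint wall-contact records
#'
#' @slot depth numeric, penetration depth per joint (mm, >= 0; 0 strictly
#'   inside or exactly on the wall).
#' @slot normal numeric n x 3 matrix of inward unit normals (wall toward
#'   lumen interior); rows are zero where there is no contact.
#' @slot contact logical per joint, TRUE iff depth > 0.
#' @slot escaped logical per joint, TRUE when the joint lies beyond an open
#'   end of the vessel (no contact generated there).
#' @export
setClass("ContactSet",
  representation(depth = "numeric", normal = "matrix", contact = "logical",
                 escaped = "logical"),
  validity = function(object) {
    n <- length(object@depth)
    if (nrow(object@normal) != n || length(object@contact) != n ||
        length(object@escaped) != n)
      return("contact fields must have equal length")
    if (any(object@depth < 0)) return("depths must be non-negative")
    if (any(object@contact & object@depth <= 0))
      return("contact flag requires positive depth")
    if (any(object@contact)) {
      nr <- sqrt(rowSums(object@normal[object@contact, , drop = FALSE]^2))
      if (any(abs(nr - 1) > 1e-9))
        return("contact normals must be unit length")
    }
    TRUE
  })

#' Per-joint external forces and last displacements
#'
#' @slot forces numeric n x 3 matrix of external (wall) forces; zero rows
#'   where the contact flag is false.
#' @slot alpha numeric n x 3 matrix of joint displacements over the previous
#'   inner iteration (mm).
#' @slot eta numeric feedback coefficient (1/mm) of the force correction.
#' @export
setClass("ForceState",
  representation(forces = "matrix", alpha = "matrix", eta = "numeric"),
  validity = function(object) {
    if (nrow(object@forces) != nrow(object@alpha))
      return("forces and alpha must have equal rows")
    if (object@eta < 0) return("eta must be non-negative")
    TRUE
  })

#' X-ray scene: attenuating objects plus a camera
#'
#' @slot objects list; each element a list with either `mesh`
#'   (a [TriangleMesh-class]) or `chain` (a [RodChain-class]) plus `radius`
#'   (mm, capsule radius for chains), and `sigma` (attenuation per mm, >= 0).
#' @slot camera list describing an orthographic
#'   (`type="ortho"`, `center`, `dir`, `up`, `width`, `height`) or pinhole
#'   (`type="pinhole"`, `position`, `lookat`, `up`, `fov` radians) camera.
#' @slot size integer length-2, image width and height in pixels.
#' @export
setClass("XRayScene",
  representation(objects = "list", camera = "list", size = "integer"),
  validity = function(object) {
    for (ob in object@objects) {
      if (is.null(ob$sigma) || ob$sigma < 0)
        return("every object needs sigma >= 0")
      if (is.null(ob$mesh) && is.null(ob$chain))
        return("object must carry a mesh or a chain")
      if (!is.null(ob$chain) && (is.null(ob$radius) || ob$radius <= 0))
        return("chain objects need a positive capsule radius")
    }
    if (length(object@size) != 2L || any(object@size < 1L))
      return("image dimensions must be positive")
    TRUE
  })

#' Rendered X-ray image
#'
#' Intensities in [0, 1]; row-major with pixel (1,1) at the top-left. Pixels
#' traversed by no object have intensity exactly 1.
#'
#' @slot pixels numeric matrix (rows = image height).
#' @export
setClass("XRayImage",
  representation(pixels = "matrix"),
  validity = function(object) {
    p <- object@pixels
    if (length(p) && (min(p) < 0 || max(p) > 1))
      return("intensities must lie in [0, 1]")
    TRUE
  })
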