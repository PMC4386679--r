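#' Accessors for vessim classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return `meshVertices`/`meshFaces` return the vertex/face matrices of a
#'   [TriangleMesh-class]; `nVertices`/`nFaces` their counts.
#'   `skeletonNodes`, `skeletonBranches`, `skeletonJunctions`,
#'   `skeletonRadius` return the corresponding pieces of a
#'   [CurveSkeleton-class]. `chainJoints` and `rodLengths` return the joint
#'   matrix and rest lengths of a [RodChain-class]; `nRods` the rod count.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))
#' @rdname accessors
#' @export
setGeneric("skeletonBranches", function(x) standardGeneric("skeletonBranches"))
#' @rdname accessors
#' @export
setGeneric("skeletonJunctions", function(x) standardGeneric("skeletonJunctions"))
#' @rdname accessors
#' @export
setGeneric("skeletonRadius", function(x) standardGeneric("skeletonRadius"))
#' @rdname accessors
#' @export
setGeneric("chainJoints", function(x) standardGeneric("chainJoints"))
#' @rdname accessors
#' @export
setGeneric("rodLengths", function(x) standardGeneric("rodLengths"))
#' @rdname accessors
#' @export
setGeneric("nRods", function(x) standardGeneric("nRods"))
#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname accessors
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname accessors
#' @export
setMethod("skeletonNodes", "CurveSkeleton", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("skeletonBranches", "CurveSkeleton", function(x) x@branches)
#' @rdname accessors
#' @export
setMethod("skeletonJunctions", "CurveSkeleton", function(x) x@junctions)
#' @rdname accessors
#' @export
setMethod("skeletonRadius", "CurveSkeleton", function(x) x@radius)
#' @rdname accessors
#' @export
setMethod("chainJoints", "RodChain", function(x) x@joints)
#' @rdname accessors
#' @export
setMethod("rodLengths", "RodChain", function(x) x@restLengths)
#' @rdname accessors
#' @export
setMethod("nRods", "RodChain", function(x) length(x@restLengths))
#' @rdname accessors
#' @export
setMethod("imagePixels", "XRayImage", function(x) x@pixels)

#' Construct a TriangleMesh
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return a [TriangleMesh-class].
#' @export
TriangleMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("TriangleMesh", vertices = as.matrix(vertices), faces = faces)
}

#' Construct a RodChain
#'
#' Rest lengths default to the current joint spacings; bias angles and
#' stiffnesses are recycled across interior joints.
#'
#' @param joints numeric (n+1) x 3 matrix of joint positions, base first.
#' @param phi intrinsic bias angles (radians), recycled to n-1.
#' @param C bending stiffnesses (energy/rad^2), recycled to n-1.
#' @param restLengths rod rest lengths; default current spacings.
#' @param insertedLength wire length past the entry point (mm).
#' @param tipRoll accumulated twist (radians).
#' @return a [RodChain-class].
#' @export
RodChain <- function(joints, phi = 0, C = 1, restLengths = NULL,
                     insertedLength = NULL, tipRoll = 0) {
  joints <- as.matrix(joints)
  n <- nrow(joints) - 1L
  if (is.null(restLengths))
    restLengths <- sqrt(rowSums((joints[-1, , drop = FALSE] -
                                 joints[-(n + 1L), , drop = FALSE])^2))
  ni <- max(0L, n - 1L)
  if (is.null(insertedLength)) insertedLength <- sum(restLengths)
  new("RodChain", joints = joints, restLengths = restLengths,
      phi = rep_len(phi, ni), stiffness = rep_len(C, ni),
      insertedLength = insertedLength, tipRoll = tipRoll)
}

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nVertices(object), nFaces(object)))
  if (nVertices(object)) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(object)
})

setMethod("show", "OrientedPointCloud", function(object) {
  cat(sprintf("OrientedPointCloud: %d points with unit normals\n",
              nrow(object@points)))
  invisible(object)
})

setMethod("show", "CurveSkeleton", function(object) {
  cat(sprintf("CurveSkeleton: %d nodes, %d branches, %d junction(s)\n",
              nrow(object@nodes), length(object@branches),
              length(object@junctions)))
  if (length(object@radius))
    cat(sprintf("  lumen radius %.2f-%.2f mm\n",
                min(object@radius), max(object@radius)))
  invisible(object)
})

setMethod("show", "RodChain", function(object) {
  cat(sprintf(
    "RodChain: %d rods, total length %.2f mm, inserted %.2f mm, roll %.2f rad\n",
    nRods(object), sum(object@restLengths), object@insertedLength,
    object@tipRoll))
  invisible(object)
})

setMethod("show", "VesselModel", function(object) {
  cat(sprintf("VesselModel: %d branch(es), kV = %g, rupture force %g\n",
              length(object@branches), object@kV, object@FRupture))
  invisible(object)
})

setMethod("show", "XRayImage", function(object) {
  cat(sprintf("XRayImage: %d x %d, intensity range [%.3f, %.3f]\n",
              ncol(object@pixels), nrow(object@pixels),
              min(object@pixels), max(object@pixels)))
  invisible(object)
})
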