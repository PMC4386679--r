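# Vessel lumen model and single-pass collision detection for rod chains.

#' Construct a VesselModel from centerline branches
#'
#' @param branches list; each element a list with `stations` (k x 3 matrix
#'   of centerline samples, entry end first for branch 1) and `radii`
#'   (length k or scalar).
#' @param kV wall elastic coefficient (force/mm, default 0.5).
#' @param FRupture boundary (rupture) force; default `Inf` (unbreakable).
#' @param mesh optional lumen surface [TriangleMesh-class].
#' @return a [VesselModel-class].
#' @export
VesselModel <- function(branches, kV = 0.5, FRupture = Inf, mesh = NULL) {
  branches <- lapply(branches, function(b) {
    st <- as.matrix(b$stations)
    arc <- c(0, cumsum(.rowNorm(st[-1, , drop = FALSE] -
                                st[-nrow(st), , drop = FALSE])))
    list(stations = st, radii = rep_len(b$radii, nrow(st)), arc = arc,
         entryArc = if (is.null(b$entryArc)) 0 else b$entryArc)
  })
  if (is.null(mesh)) mesh <- new("TriangleMesh")
  new("VesselModel", branches = branches, kV = kV, FRupture = FRupture,
      mesh = mesh)
}

# For each query point: signed radial distance to the lumen of one branch
# (rho - r at the nearest centerline station), the nearest centerline point,
# and whether the query projects beyond an open end of the branch.
.branchQuery <- function(branch, P) {
  S <- branch$stations; r <- branch$radii
  k <- nrow(S)
  n <- nrow(P)
  best <- rep(Inf, n)
  nearest <- matrix(0, n, 3)
  bestR <- numeric(n)
  beyond <- rep(FALSE, n)
  A <- S[-k, , drop = FALSE]
  B <- S[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  for (i in seq_len(n)) {
    w <- sweep(A, 2, P[i, ], "-")
    t <- -rowSums(w * AB) / pmax(len2, 1e-300)
    tc <- pmin(pmax(t, 0), 1)
    cp <- A + AB * tc
    d2 <- rowSums(sweep(cp, 2, P[i, ])^2)
    j <- which.min(d2)
    best[i] <- sqrt(d2[j])
    nearest[i, ] <- cp[j, ]
    bestR[i] <- r[j] + tc[j] * (r[j + 1L] - r[j])
    beyond[i] <- (j == 1L && t[1] < -1e-9) || (j == k - 1L && t[k - 1L] > 1 + 1e-9)
  }
  list(rho = best, nearest = nearest, r = bestR, beyond = beyond)
}

#' Signed lumen distance for arbitrary points
#'
#' Negative inside the lumen (union over branches), positive outside;
#' magnitude is the radial clearance/penetration at the nearest centerline
#' station.
#'
#' @param vessel a [VesselModel-class].
#' @param points numeric n x 3 matrix.
#' @return list with `signed` (numeric), `nearest` (n x 3 centerline
#'   points), `escaped` (beyond every branch's open ends) and `radius`
#'   (local lumen radius of the governing branch).
#' @export
vesselSignedDistance <- function(vessel, points) {
  P <- as.matrix(points)
  n <- nrow(P)
  signed <- rep(Inf, n)
  nearest <- matrix(0, n, 3)
  radius <- numeric(n)
  beyondAll <- rep(TRUE, n)
  for (b in vessel@branches) {
    q <- .branchQuery(b, P)
    sd <- q$rho - q$r
    upd <- sd < signed
    signed[upd] <- sd[upd]
    nearest[upd, ] <- q$nearest[upd, , drop = FALSE]
    radius[upd] <- q$r[upd]
    beyondAll <- beyondAll & q$beyond
  }
  list(signed = signed, nearest = nearest, escaped = beyondAll,
       radius = radius)
}

#' Detect guidewire-wall collisions (single pass)
#'
#' For every joint, the penetration depth is `d_i = max(0, rho_i - r(s_i))`
#' with rho_i the distance from the joint to the nearest centerline station
#' of the governing branch; the contact normal points inward, from the wall
#' toward the centerline. A joint exactly on the wall (`rho = r`) has zero
#' depth and no contact. Joints beyond an open end of every branch are
#' flagged escaped and generate no contact.
#'
#' @param chain a [RodChain-class].
#' @param vessel a [VesselModel-class].
#' @return a [ContactSet-class].
#' @export
detectCollisions <- function(chain, vessel) {
  q <- vesselSignedDistance(vessel, chain@joints)
  n <- nrow(chain@joints)
  depth <- pmax(0, q$signed)
  depth[q$escaped] <- 0
  normal <- matrix(0, n, 3)
  contact <- depth > 0
  if (any(contact)) {
    dirs <- q$nearest[contact, , drop = FALSE] -
      chain@joints[contact, , drop = FALSE]
    nr <- .rowNorm(dirs)
    nr[nr == 0] <- 1
    normal[contact, ] <- dirs / nr
  }
  new("ContactSet", depth = depth, normal = normal, contact = contact,
      escaped = q$escaped)
}
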