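# Equilibrium of the rod chain by projected gradient descent on the total
# potential energy, with the single-collision-detection force correction,
# plus the push/pull/twist maneuvers and the rupture check.

#' Apply the displacement-feedback force correction
#'
#' `F_i' = F_i (1 - eta (alpha_i . F_i) / |F_i|^2)` per contact joint; zero
#' forces stay zero (no division). The scale factor is clamped below at 0 so
#' that the corrected force never reverses direction: when the joint has
#' moved along the force (`alpha . F >= 0`), the corrected magnitude never
#' exceeds the uncorrected one. Motion against the force (deeper
#' penetration) increases the force.
#'
#' @param state a [ForceState-class].
#' @return a [ForceState-class] with updated forces.
#' @export
correctForce <- function(state) {
  F <- state@forces
  mag2 <- rowSums(F^2)
  act <- mag2 > 0
  if (any(act)) {
    fac <- 1 - state@eta * rowSums(state@alpha[act, , drop = FALSE] *
                                   F[act, , drop = FALSE]) / mag2[act]
    F[act, ] <- F[act, ] * pmax(fac, 0)
  }
  new("ForceState", forces = F, alpha = state@alpha, eta = state@eta)
}

# Enforce rigid rod lengths by symmetric constraint-projection sweeps
# (base joint fixed), until the worst relative length error is < 1e-9.
.projectRods <- function(X, L, maxSweeps = 100L) {
  n <- nrow(X) - 1L
  for (sw in seq_len(maxSweeps)) {
    worst <- 0
    for (i in seq_len(n)) {
      v <- X[i + 1L, ] - X[i, ]
      d <- sqrt(sum(v^2))
      if (d == 0) { v <- c(L[i], 0, 0); d <- L[i] }  # coincident: arbitrary
      err <- (d - L[i]) / L[i]
      if (abs(err) > worst) worst <- abs(err)
      corr <- v * ((d - L[i]) / d)
      if (i == 1L) {
        X[2, ] <- X[2, ] - corr
      } else {
        X[i, ] <- X[i, ] + 0.5 * corr
        X[i + 1L, ] <- X[i + 1L, ] - corr * 0.5
      }
    }
    if (worst < 1e-9) break
  }
  # exact forward pass: snap each rod to its rest length from the base out
  # (a no-op when the sweeps converged; guarantees exact lengths otherwise)
  for (i in seq_len(n)) {
    v <- X[i + 1L, ] - X[i, ]
    d <- sqrt(sum(v^2))
    if (d == 0) { v <- c(L[i], 0, 0); d <- L[i] }
    X[i + 1L, ] <- X[i, ] + v * (L[i] / d)
  }
  X
}

#' One equilibrium step: single collision detection + inner minimization
#'
#' Performs one collision detection, initializes per-contact wall forces
#' `F_i = k_v d_i n_i` (the gradient of the wall energy), then runs an inner
#' projected-gradient loop on the total potential energy under the rigid-rod
#' constraints: joints move along the bending-energy gradient plus the
#' current wall force, rod lengths are re-projected after every trial move,
#' displacements `alpha_i` are recorded, and the forces are updated by
#' [correctForce()]. With `eta = 0` the wall forces stay at their initial
#' single-detection values (the uncorrected scheme this model improves on).
#' Backtracking halves the step whenever the monitored energy would grow, so
#' the returned energy trace is non-increasing; the loop stops when the
#' largest joint displacement drops below `tol` or `maxInner` is reached.
#'
#' The monitored energy is `E_g + E_v` with the wall depths linearized along
#' the frozen contact normals (the geometry of the single detection); with
#' `eta = 0` the wall term is the constant-force potential
#' `-sum F_i . (x_i - x_i^0)` of the uncorrected scheme, offset to agree at
#' the start.
#'
#' @param chain a [RodChain-class].
#' @param vessel a [VesselModel-class], or `NULL` for free space (no wall).
#' @param eta feedback coefficient (1/mm, default 0.5).
#' @param kV wall elastic coefficient; defaults to the vessel's (0.5 in
#'   free space, unused).
#' @param tol inner convergence tolerance on the max joint displacement
#'   (mm, default 1e-4).
#' @param maxInner inner iteration cap (default 200).
#' @return list with `chain`, `contacts` ([ContactSet-class]), `forces`
#'   ([ForceState-class]) and `report` (list: `iterations`, `energyTrace`,
#'   `converged`, `finalStep`).
#' @export
stepEquilibrium <- function(chain, vessel = NULL,
                            eta = 0.5,
                            kV = if (is.null(vessel)) 0.5 else vessel@kV,
                            tol = 1e-4, maxInner = 200) {
  contacts <- if (is.null(vessel)) {
    n0 <- nrow(chain@joints)
    new("ContactSet", depth = numeric(n0), normal = matrix(0, n0, 3),
        contact = logical(n0), escaped = logical(n0))
  } else detectCollisions(chain, vessel)
  X <- chain@joints
  n1 <- nrow(X)
  X0 <- X
  d0 <- contacts@depth
  N0 <- contacts@normal
  act <- contacts@contact
  F <- matrix(0, n1, 3)
  F[act, ] <- kV * d0[act] * N0[act, , drop = FALSE]
  F0 <- F
  linDepth <- function(X) {
    if (!any(act)) return(numeric(0))
    pmax(0, d0[act] - rowSums((X[act, , drop = FALSE] -
                               X0[act, , drop = FALSE]) * N0[act, , drop = FALSE]))
  }
  energy <- function(X) {
    eb <- sum(0.5 * chain@stiffness *
                (.anglesOf(X) - chain@phi)^2)
    if (eta > 0) {
      eb + sum(0.5 * kV * linDepth(X)^2)
    } else {
      eb - sum(F0[act, , drop = FALSE] *
                 (X[act, , drop = FALSE] - X0[act, , drop = FALSE])) +
        sum(0.5 * kV * d0[act]^2)
    }
  }
  lbar <- mean(chain@restLengths)
  gamma0 <- 1 / (kV + max(chain@stiffness, 1e-9) / lbar^2 + 1e-9)
  gamma <- gamma0
  capMove <- 0.5 * min(chain@restLengths)
  Ecur <- energy(X)
  trace <- Ecur
  iters <- 0L
  converged <- FALSE
  alphaLast <- matrix(0, n1, 3)
  Gprev <- NULL
  Xprev <- NULL
  for (k in seq_len(maxInner)) {
    iters <- k
    G <- .bendGradient(X, chain@phi, chain@stiffness) - F
    G[1, ] <- 0                      # base joint clamped at the entry
    # Barzilai-Borwein spectral step (projected), safeguarded by the
    # backtracking below; falls back to the stiffness-scaled step
    if (!is.null(Gprev)) {
      s <- X - Xprev
      y <- G - Gprev
      sy <- sum(s * y)
      yy <- sum(y * y)
      gamma <- if (is.finite(sy) && sy > 0 && yy > 0)
        min(max(sy / yy, 1e-3 * gamma0), 1e4 * gamma0) else gamma0
    }
    Gprev <- G
    Xprev <- X
    D <- -G
    accepted <- FALSE
    for (try in 1:30) {
      step <- gamma
      mv <- sqrt(max(rowSums((step * D)^2)))
      if (mv > capMove) step <- step * capMove / mv
      Xt <- .projectRods(X + step * D, chain@restLengths)
      Et <- energy(Xt)
      if (Et <= Ecur + 1e-12) { accepted <- TRUE; break }
      gamma <- gamma / 2
    }
    if (!accepted) { converged <- TRUE; break }
    alphaLast <- Xt - X
    X <- Xt
    Ecur <- Et
    trace <- c(trace, Ecur)
    if (eta > 0 && any(act)) {
      fs <- correctForce(new("ForceState", forces = F, alpha = alphaLast,
                             eta = eta))
      F <- fs@forces
    }
    if (max(.rowNorm(alphaLast)) < tol) { converged <- TRUE; break }
  }
  chain@joints <- X
  forces <- new("ForceState", forces = F, alpha = alphaLast, eta = eta)
  list(chain = chain, contacts = contacts, forces = forces,
       report = list(iterations = iters, energyTrace = trace,
                     converged = converged, finalStep = gamma))
}

# interior angles from a raw joint matrix
.anglesOf <- function(X) {
  n <- nrow(X) - 1L
  if (n < 2L) return(numeric(0))
  U <- X[2:(n + 1L), , drop = FALSE] - X[1:n, , drop = FALSE]
  u <- U[1:(n - 1L), , drop = FALSE]
  v <- U[2:n, , drop = FALSE]
  atan2(.rowNorm(.rowCross(u, v)), rowSums(u * v))
}

# position at arc distance s along a polyline (rows of P), with linear
# extrapolation beyond the last point
.polylineAt <- function(P, arc, s) {
  k <- nrow(P)
  if (s <= 0) return(P[1, ])
  if (s >= arc[k]) {
    dir <- .unit(P[k, ] - P[k - 1L, ])
    return(P[k, ] + (s - arc[k]) * dir)
  }
  j <- findInterval(s, arc)
  t <- (s - arc[j]) / (arc[j + 1L] - arc[j])
  P[j, ] + t * (P[j + 1L, ] - P[j, ])
}

#' Push or pull the instrument along the vessel
#'
#' The wire is transported along its own polyline (extended straight past
#' the tip for a push): every joint moves `ds` further along the wire's
#' path, new rods are created at the entry so the base stays at the entry
#' point and rod lengths remain near `nominalRod`, and the chain is then
#' re-equilibrated with `outerSteps` calls to [stepEquilibrium()] (each with
#' its own single collision detection). `insertedLength` grows by `ds`.
#'
#' @param chain a [RodChain-class].
#' @param vessel a [VesselModel-class].
#' @param ds signed advance in mm (positive = push, negative = pull).
#' @param nominalRod nominal rod length for entry-side bookkeeping
#'   (default: the chain's mean rest length).
#' @param outerSteps number of equilibrium steps after the transport
#'   (default 4; 0 skips equilibration).
#' @param eta,kV,tol,maxInner passed to [stepEquilibrium()].
#' @return a [RodChain-class]; the last equilibrium result is attached as
#'   attribute `"lastStep"`.
#' @export
pushPull <- function(chain, vessel, ds, nominalRod = NULL, outerSteps = 4,
                     eta = 0.5, kV = vessel@kV, tol = 1e-4, maxInner = 200) {
  if (ds < 0 && chain@insertedLength + ds < -1e-9)
    stop("over-withdrawal: inserted length would become negative")
  if (is.null(nominalRod)) nominalRod <- mean(chain@restLengths)
  X <- chain@joints
  n <- nrow(X) - 1L
  st <- cumsum(c(0, chain@restLengths))
  arc <- c(0, cumsum(.rowNorm(X[-1, , drop = FALSE] -
                              X[-(n + 1L), , drop = FALSE])))
  oldPhi <- chain@phi
  oldC <- chain@stiffness
  baseC <- if (length(oldC)) oldC[1] else 1
  # The wire slides along its own spatial path (extended straight past the
  # tip for a push): the joint at wire-station s sits at path arc s.
  if (ds > 0) {
    k <- max(1L, ceiling(ds / nominalRod))
    baseSt <- seq(0, ds, length.out = k + 1L)[-(k + 1L)]
    newSt <- c(baseSt, st + ds)
    m <- length(newSt) - 1L
    phiNew <- rep(0, m - 1L)
    cNew <- rep(baseC, m - 1L)
    if (n >= 2L) {
      # old interior joint row j (2..n) becomes new row k + j
      rows <- k + 2:n
      phiNew[rows - 1L] <- oldPhi
      cNew[rows - 1L] <- oldC
    }
  } else if (ds < 0) {
    shifted <- st + ds
    keep <- shifted > 1e-9
    newSt <- c(0, shifted[keep])
    m <- length(newSt) - 1L
    if (m < 1L) stop("pull would remove the whole chain")
    nDrop <- (n + 1L) - sum(keep)
    phiNew <- rep(0, max(0L, m - 1L))
    cNew <- rep(baseC, max(0L, m - 1L))
    if (n >= 2L) {
      for (j in 2:n) {
        r <- j - nDrop + 1L          # new row of old joint j
        if (r >= 2L && r <= m) {
          phiNew[r - 1L] <- oldPhi[j - 1L]
          cNew[r - 1L] <- oldC[j - 1L]
        }
      }
    }
  } else {
    newSt <- st; m <- n; phiNew <- oldPhi; cNew <- oldC
  }
  newX <- t(vapply(newSt, function(s) .polylineAt(X, arc, s), numeric(3)))
  newX <- .projectRods(newX, diff(newSt))
  out <- new("RodChain", joints = newX, restLengths = diff(newSt),
             phi = phiNew, stiffness = cNew,
             insertedLength = chain@insertedLength + ds,
             tipRoll = chain@tipRoll)
  last <- NULL
  if (outerSteps > 0) {
    for (o in seq_len(outerSteps)) {
      last <- stepEquilibrium(out, vessel, eta = eta, kV = kV, tol = tol,
                              maxInner = maxInner)
      out <- last$chain
    }
  }
  attr(out, "lastStep") <- last
  out
}

#' Twist the instrument about its own axis
#'
#' The chain carries no torsion energy (the bending energy depends only on
#' inter-rod angles), so twisting is realized kinematically: the tip
#' section, from the first interior joint with a nonzero intrinsic bias
#' angle onward, is rotated about the local tangent there by `droll`, and
#' the accumulated `tipRoll` is updated. A straight-tipped wire (all
#' `phi = 0`) is geometrically unchanged. Rotation about the incoming rod
#' direction preserves all inter-rod angles, so the bending energy is
#' invariant and a subsequent equilibrium step is a no-op in free space.
#'
#' @param chain a [RodChain-class].
#' @param droll twist increment (radians).
#' @param vessel optional [VesselModel-class]; when given, the chain is
#'   re-equilibrated after the rotation.
#' @param ... passed to [stepEquilibrium()] when `vessel` is given.
#' @return a [RodChain-class].
#' @export
twistChain <- function(chain, droll, vessel = NULL, ...) {
  chain@tipRoll <- chain@tipRoll + droll
  j0 <- which(chain@phi > 0)
  if (!length(j0)) return(chain)
  j0 <- j0[1]                      # interior index; joint row j0 + 1
  pivotRow <- j0 + 1L
  X <- chain@joints
  axis <- .unit(X[pivotRow, ] - X[pivotRow - 1L, ])
  rot <- .axisRotation(axis, droll)
  rows <- (pivotRow + 1L):nrow(X)
  rel <- sweep(X[rows, , drop = FALSE], 2, X[pivotRow, ])
  X[rows, ] <- sweep(rel %*% t(rot), 2, X[pivotRow, ], "+")
  chain@joints <- X
  if (!is.null(vessel)) chain <- stepEquilibrium(chain, vessel, ...)$chain
  chain
}

# Rodrigues rotation matrix about unit axis
.axisRotation <- function(u, ang) {
  c0 <- cos(ang); s0 <- sin(ang)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * (u %o% u)
}

#' Check for a vessel-wall rupture event
#'
#' A rupture fires iff the wall-force magnitude at the tip joint is
#' strictly greater than the vessel's boundary force; a tip force exactly
#' at the threshold does not rupture.
#'
#' @param contacts a [ContactSet-class] from the latest equilibrium step.
#' @param forces a [ForceState-class] from the latest equilibrium step.
#' @param vessel a [VesselModel-class] (supplies `FRupture`).
#' @param chain optional [RodChain-class] to report the tip location.
#' @return `NULL`, or a list with `joint`, `force` and `location`.
#' @export
checkRupture <- function(contacts, forces, vessel, chain = NULL) {
  tip <- length(contacts@depth)
  if (!contacts@contact[tip]) return(NULL)
  fmag <- sqrt(sum(forces@forces[tip, ]^2))
  if (fmag > vessel@FRupture) {
    list(joint = tip, force = fmag,
         location = if (!is.null(chain)) chain@joints[tip, ] else NULL)
  } else NULL
}
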