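# Rod-chain mechanics: bending/wall energies, the adaptive split/merge
# exponent, and rediscretization of a chain.

#' Inter-rod angles of a chain
#'
#' The angle at interior joint i between the incoming and outgoing rod
#' vectors, in [0, pi]; 0 for a locally straight chain.
#'
#' @param chain a [RodChain-class].
#' @return numeric vector, one angle per interior joint.
#' @export
interiorAngles <- function(chain) {
  X <- chain@joints
  n <- nrow(X) - 1L
  if (n < 2L) return(numeric(0))
  U <- X[2:(n + 1L), , drop = FALSE] - X[1:n, , drop = FALSE]
  u <- U[1:(n - 1L), , drop = FALSE]
  v <- U[2:n, , drop = FALSE]
  s <- .rowNorm(.rowCross(u, v))
  cc <- rowSums(u * v)
  atan2(s, cc)
}

#' Bending energy of a rod chain
#'
#' `E_g = sum_i 1/2 C_i (theta_i - phi_i)^2` over interior joints, where
#' theta_i is the inter-rod angle and phi_i the intrinsic bias angle. Zero
#' exactly when the chain sits at its intrinsic (stress-free) shape.
#'
#' @param chain a [RodChain-class].
#' @return scalar energy.
#' @export
bendingEnergy <- function(chain) {
  th <- interiorAngles(chain)
  if (!length(th)) return(0)
  sum(0.5 * chain@stiffness * (th - chain@phi)^2)
}

#' Elastic energy stored in the deformed vessel wall
#'
#' `E_v = sum_i 1/2 k_v d_i^2` over contact joints, with d_i the wall
#' penetration depth.
#'
#' @param contacts a [ContactSet-class].
#' @param kV wall elastic coefficient (force/mm).
#' @return scalar energy.
#' @export
wallEnergy <- function(contacts, kV) {
  sum(0.5 * kV * contacts@depth^2)
}

#' Total potential energy of the guidewire-vessel system
#'
#' `E_total = E_g + E_v`.
#'
#' @param chain a [RodChain-class].
#' @param contacts a [ContactSet-class].
#' @param kV wall elastic coefficient.
#' @return scalar energy.
#' @export
totalEnergy <- function(chain, contacts, kV) {
  bendingEnergy(chain) + wallEnergy(contacts, kV)
}

# Analytic gradient of the bending energy w.r.t. joint positions.
# Angle gradients follow the standard three-body (bond-angle) formulas with
# guards at the straight configuration, where the angle direction is
# undefined but the energy gradient stays bounded.
.bendGradient <- function(X, phi, C) {
  n <- nrow(X) - 1L
  G <- matrix(0, n + 1L, 3L)
  if (n < 2L) return(G)
  for (i in seq_len(n - 1L)) {
    p <- X[i, ]; m <- X[i + 1L, ]; q <- X[i + 2L, ]
    u <- m - p; v <- q - m
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    s <- sqrt(sum(w^2))
    cc <- sum(u * v)
    th <- atan2(s, cc)
    dE <- C[i] * (th - phi[i])
    if (abs(dE) < 1e-15) next
    u2 <- sum(u^2); v2 <- sum(v^2)
    if (s < 1e-12 * sqrt(u2 * v2)) {
      if (abs(th - phi[i]) < 1e-9) next
      # straight chain with nonzero bias: pick an arbitrary bend plane
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
             u[1] * ref[2] - u[2] * ref[1])
      s <- sqrt(sum(w^2))
    }
    denom <- u2 * v2
    vxw <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3],
             v[1] * w[2] - v[2] * w[1])
    wxu <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
             w[1] * u[2] - w[2] * u[1])
    dthdu <- (cc * vxw / s - s * v) / denom
    dthdv <- (cc * wxu / s - s * u) / denom
    G[i, ] <- G[i, ] - dE * dthdu
    G[i + 1L, ] <- G[i + 1L, ] + dE * (dthdu - dthdv)
    G[i + 2L, ] <- G[i + 2L, ] + dE * dthdv
  }
  G
}

#' Adaptive discretization exponent
#'
#' Target rod length `L* = sqrt((r_c + 0.5 d_v)^2 * 2 (1 - cos phi_m))`, the
#' chord subtending the maximum bias angle at the outer-lumen curvature
#' radius; the split/merge exponent is `n_d = round(log2(lbar / L*))`. A
#' positive n_d means each rod splits into `2^n_d` smaller ones (tight,
#' high-curvature vessel); a negative n_d merges groups of `2^-n_d` rods.
#'
#' @param lbar mean rod length (mm).
#' @param rc local curvature radius of the vessel centerline (mm).
#' @param dv vessel diameter (mm).
#' @param phim maximum bias angle between adjacent rods (radians, in
#'   (0, pi)).
#' @return integer n_d.
#' @export
computeNd <- function(lbar, rc, dv, phim) {
  if (lbar <= 0 || rc <= 0 || dv <= 0)
    stop("lbar, rc and dv must be positive")
  if (phim <= 0 || phim >= pi) stop("phim must lie in (0, pi)")
  Lstar <- sqrt((rc + 0.5 * dv)^2 * 2 * (1 - cos(phim)))
  as.integer(round(log2(lbar / Lstar)))
}

#' Split or merge the rods of a chain
#'
#' `nd > 0`: each rod is split into `2^nd` equal pieces; inserted joints lie
#' on the original rods (identical polyline geometry), get bias angle 0 and
#' a stiffness interpolated along arc length. `nd < 0`: consecutive groups
#' of `2^-nd` rods merge into single rods between the group endpoints (a
#' trailing short group is kept as-is); the chord-vs-arc length discrepancy
#' is returned as attribute `"lengthDiscrepancy"`. `nd = 0` is the identity.
#'
#' @param chain a [RodChain-class].
#' @param nd integer discretization exponent from [computeNd()].
#' @return a [RodChain-class].
#' @export
rediscretize <- function(chain, nd) {
  nd <- as.integer(nd)
  if (nd == 0L) return(chain)
  X <- chain@joints
  n <- nrow(X) - 1L
  st <- cumsum(c(0, chain@restLengths))
  intSt <- st[2:n]                      # stations of interior joints
  if (nd > 0L) {
    k <- 2L^nd
    newX <- matrix(0, n * k + 1L, 3L)
    newL <- numeric(n * k)
    newX[1, ] <- X[1, ]
    row <- 1L
    for (i in seq_len(n)) {
      for (j in seq_len(k)) {
        row <- row + 1L
        newX[row, ] <- X[i, ] + (j / k) * (X[i + 1L, ] - X[i, ])
        newL[row - 1L] <- chain@restLengths[i] / k
      }
    }
    newSt <- cumsum(c(0, newL))
    inner <- newSt[2:(length(newSt) - 1L)]
    phi <- rep(0, length(inner))
    keepAt <- match(round(intSt, 12), round(inner, 12))
    if (n >= 2L) phi[keepAt] <- chain@phi
    Cnew <- if (n >= 2L)
      stats::approx(intSt, chain@stiffness, xout = inner, rule = 2)$y
    else rep(1, length(inner))
    out <- new("RodChain", joints = newX, restLengths = newL, phi = phi,
               stiffness = Cnew, insertedLength = chain@insertedLength,
               tipRoll = chain@tipRoll)
    attr(out, "lengthDiscrepancy") <- 0
    out
  } else {
    g <- 2L^(-nd)
    keep <- seq(1L, n + 1L, by = g)
    if (keep[length(keep)] != n + 1L) keep <- c(keep, n + 1L)
    newX <- X[keep, , drop = FALSE]
    newL <- .rowNorm(newX[-1, , drop = FALSE] -
                     newX[-nrow(newX), , drop = FALSE])
    innerKeep <- keep[-c(1L, length(keep))]
    phi <- chain@phi[innerKeep - 1L]
    Cn <- chain@stiffness[innerKeep - 1L]
    out <- new("RodChain", joints = newX, restLengths = newL, phi = phi,
               stiffness = Cn, insertedLength = chain@insertedLength,
               tipRoll = chain@tipRoll)
    attr(out, "lengthDiscrepancy") <- sum(chain@restLengths) - sum(newL)
    out
  }
}
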