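# Rod-chain energetics, adaptive discretization, collision queries, the
# force-corrected equilibrium, and the push/pull/twist maneuvers.

freeSpaceTube <- function() fixture("bigTube", function()
  makePhantom("cylinder", radius = 50, length = 400,
              circumferential = 8, axial = 8)$vessel)

bendVessel <- function() fixture("bendVessel", function()
  makePhantom("torus_segment", lumenRadius = 2, bendRadius = 20,
              angle = pi / 2, circumferential = 16, axial = 40)$vessel)

test_that("bending and wall energies evaluate their closed forms", {
  straight <- RodChain(cbind(0:5 * 2, 0, 0), phi = 0, C = 1)
  expect_equal(bendingEnergy(straight), 0)
  # one interior joint at theta = pi/6, phi = 0, C = 2
  ch <- RodChain(rbind(c(0, 0, 0), c(1, 0, 0),
                       c(1 + cos(pi / 6), sin(pi / 6), 0)), phi = 0, C = 2)
  expect_equal(bendingEnergy(ch), (pi / 6)^2, tolerance = 1e-12)
  # intrinsic shape is stress-free
  chb <- RodChain(rbind(c(0, 0, 0), c(1, 0, 0),
                        c(1 + cos(0.7), sin(0.7), 0)), phi = 0.7, C = 3)
  expect_lt(bendingEnergy(chb), 1e-20)
  # wall energy: single contact, quadratic scaling
  mkContacts <- function(d) new("ContactSet", depth = d,
                                normal = matrix(rep(c(1, 0, 0), length(d)),
                                                ncol = 3, byrow = TRUE),
                                contact = d > 0, escaped = rep(FALSE, length(d)))
  expect_equal(wallEnergy(mkContacts(numeric(3)), 4), 0)
  expect_equal(wallEnergy(mkContacts(c(0, 0.5, 0)), 4), 0.5)
  expect_equal(wallEnergy(mkContacts(c(0.2, 0.5, 0.1)), 4),
               4 * wallEnergy(mkContacts(c(0.1, 0.25, 0.05)), 4))
  # total energy decomposes additively
  cs <- mkContacts(c(0, 0.5, 0))
  expect_equal(totalEnergy(ch, cs, 4), bendingEnergy(ch) + 0.5)
  expect_equal(totalEnergy(chb, cs, 4), wallEnergy(cs, 4), tolerance = 1e-15)
})

test_that("adaptive discretization exponent follows the chord-length law", {
  Lstar <- function(rc, dv, phim) sqrt((rc + 0.5 * dv)^2 * 2 * (1 - cos(phim)))
  L0 <- Lstar(10, 4, 0.1)
  expect_equal(computeNd(L0, 10, 4, 0.1), 0L)
  expect_equal(computeNd(4 * L0, 10, 4, 0.1), 2L)
  expect_equal(computeNd(L0 / 2, 10, 4, 0.1), -1L)
  # doubling the mean rod length raises n_d by exactly one
  for (lbar in c(0.7, 1.3, 2.9)) {
    expect_equal(computeNd(2 * lbar, 7, 3, 0.2),
                 computeNd(lbar, 7, 3, 0.2) + 1L)
  }
  # quadrupling (r_c + d_v/2) at small phi_m lowers n_d by 2 (chord ~ linear)
  expect_equal(computeNd(1, 40, 4, 0.05), computeNd(1, 10, 1, 0.05) - 2L)
  expect_error(computeNd(-1, 10, 4, 0.1), "positive")
  expect_error(computeNd(1, 10, 4, pi), "phim")
})

test_that("splitting and merging rods preserve geometry and length", {
  set.seed(3)
  J <- cbind(seq(0, 20, by = 2), cumsum(rnorm(11, 0, 0.2)), 0)
  ch <- RodChain(J, phi = 0.1, C = 2)
  sp <- rediscretize(ch, 1)
  expect_equal(nRods(sp), 2L * nRods(ch))
  expect_equal(sum(rodLengths(sp)), sum(rodLengths(ch)), tolerance = 1e-12)
  # split points lie on the original rods
  expect_equal(chainJoints(sp)[seq(1, 21, by = 2), ], chainJoints(ch),
               tolerance = 1e-12)
  # split-then-merge recovers the original joints
  mg <- rediscretize(sp, -1)
  expect_equal(chainJoints(mg), chainJoints(ch), tolerance = 1e-9)
  expect_equal(mg@phi, ch@phi, tolerance = 1e-12)
  # collinear merge is lossless in length
  st <- RodChain(cbind(seq(0, 20, by = 2), 0, 0))
  mg2 <- rediscretize(st, -1)
  expect_equal(nRods(mg2), 5L)
  expect_equal(sum(rodLengths(mg2)), 20, tolerance = 1e-12)
  expect_equal(attr(mg2, "lengthDiscrepancy"), 0, tolerance = 1e-12)
  expect_identical(rediscretize(ch, 0), ch)
  expect_equal(nRods(rediscretize(ch, 2)), 4L * nRods(ch))
})

test_that("collision detection measures radial penetration with inward normals", {
  ves <- makePhantom("cylinder", radius = 2, length = 40,
                     circumferential = 8, axial = 10)$vessel
  # chain on the centerline: strictly interior, no contacts
  onAxis <- RodChain(cbind(0, 0, seq(5, 35, by = 5)))
  cc <- detectCollisions(onAxis, ves)
  expect_true(all(cc@depth == 0))
  expect_false(any(cc@contact))
  # joint at radial distance 2.5: depth 0.5, normal radially inward
  ch <- RodChain(rbind(c(0, 0, 10), c(2.5, 0, 12)))
  cc2 <- detectCollisions(ch, ves)
  expect_equal(cc2@depth[2], 0.5, tolerance = 1e-9)
  expect_equal(cc2@normal[2, ], c(-1, 0, 0), tolerance = 1e-9)
  # exactly on the wall: zero depth, no contact flag
  chw <- RodChain(rbind(c(0, 0, 10), c(2, 0, 12)))
  cc3 <- detectCollisions(chw, ves)
  expect_equal(cc3@depth[2], 0)
  expect_false(cc3@contact[2])
  # beyond the open end: escaped, no contact
  che <- RodChain(rbind(c(0, 0, 38), c(0, 0, 45)))
  cc4 <- detectCollisions(che, ves)
  expect_true(cc4@escaped[2])
  expect_false(cc4@contact[2])
})

test_that("force correction follows the feedback law", {
  mk <- function(F, a, eta) new("ForceState", forces = rbind(F),
                                alpha = rbind(a), eta = eta)
  # worked value
  out <- correctForce(mk(c(1, 0, 0), c(0.1, 0, 0), 1))
  expect_equal(out@forces[1, ], c(0.9, 0, 0), tolerance = 1e-12)
  # zero displacement and zero feedback leave the force alone
  expect_equal(correctForce(mk(c(1, 2, 0), c(0, 0, 0), 1))@forces[1, ],
               c(1, 2, 0))
  expect_equal(correctForce(mk(c(1, 2, 0), c(0.3, -0.1, 0), 0))@forces[1, ],
               c(1, 2, 0))
  # zero force stays zero (no division)
  expect_equal(correctForce(mk(c(0, 0, 0), c(1, 1, 1), 2))@forces[1, ],
               c(0, 0, 0))
  # magnitude never grows when alpha . F >= 0, even with aggressive eta
  set.seed(9)
  for (r in 1:50) {
    F <- rnorm(3); a <- rnorm(3)
    if (sum(a * F) < 0) a <- -a
    out <- correctForce(mk(F, a, runif(1, 0, 5)))
    expect_lte(sqrt(sum(out@forces^2)), sqrt(sum(F^2)) + 1e-12)
  }
  # motion against the force deepens it
  out2 <- correctForce(mk(c(1, 0, 0), c(-0.2, 0, 0), 1))
  expect_gt(out2@forces[1, 1], 1)
})

test_that("free-space equilibrium restores the intrinsic shape", {
  set.seed(2)
  J <- cbind(seq(0, 20, by = 2), 0, 0)
  J[2:10, 2] <- rnorm(9, 0, 0.15)
  res <- stepEquilibrium(RodChain(J, phi = 0, C = 1), NULL,
                         tol = 1e-6, maxInner = 3000)
  expect_true(res$report$converged)
  expect_lt(bendingEnergy(res$chain), 1e-6)
  expect_lt(max(interiorAngles(res$chain)), 1e-3)
  expect_true(all(diff(res$report$energyTrace) <= 1e-12))
  # nonzero intrinsic bias: equilibrium angle equals phi
  ch2 <- RodChain(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0.3, 0), c(6, 0.3, 0)),
                  phi = c(0.4, 0.2), C = 1)
  res2 <- stepEquilibrium(ch2, NULL, tol = 1e-7, maxInner = 5000)
  expect_equal(interiorAngles(res2$chain), c(0.4, 0.2), tolerance = 1e-3)
})

test_that("equilibrium matches a brute-force grid minimization", {
  # two interior joints in a plane: energy is separable in the two angles,
  # minimised by an exhaustive grid as the independent oracle
  phi <- c(0.3, 0.5); C <- c(1, 2)
  grid <- seq(0, pi, by = 0.002)
  E1 <- 0.5 * C[1] * (grid - phi[1])^2
  E2 <- 0.5 * C[2] * (grid - phi[2])^2
  oracle <- c(grid[which.min(E1)], grid[which.min(E2)])
  ch <- RodChain(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0.6, 0), c(6, 1.4, 0)),
                 phi = phi, C = C)
  res <- stepEquilibrium(ch, NULL, tol = 1e-7, maxInner = 5000)
  expect_equal(interiorAngles(res$chain), oracle, tolerance = 1e-2)
})

test_that("rod lengths survive every public operation to 1e-6 relative", {
  rodErr <- function(ch) {
    seg <- sqrt(rowSums(diff(chainJoints(ch))^2))
    max(abs(seg - rodLengths(ch)) / rodLengths(ch))
  }
  ves <- bendVessel()
  ch <- sampleGuidewireStart(ves, 16, nominalRod = 2, C = 1)
  expect_lt(rodErr(ch), 1e-6)
  ch <- pushPull(ch, ves, 3)
  expect_lt(rodErr(ch), 1e-6)
  ch <- twistChain(ch, pi / 3)
  expect_lt(rodErr(ch), 1e-6)
  res <- stepEquilibrium(ch, ves)
  expect_lt(rodErr(res$chain), 1e-6)
  ch2 <- pushPull(res$chain, ves, -2)
  expect_lt(rodErr(ch2), 1e-6)
})

test_that("push and pull transport the wire with exact length bookkeeping", {
  ves <- makePhantom("cylinder", radius = 2, length = 60,
                     circumferential = 12, axial = 20)$vessel
  ch <- sampleGuidewireStart(ves, 20, nominalRod = 2)
  tip0 <- chainJoints(ch)[nRods(ch) + 1L, ]
  len0 <- sum(rodLengths(ch))
  chp <- pushPull(ch, ves, 10)
  expect_equal(sum(rodLengths(chp)), len0 + 10, tolerance = 1e-6)
  expect_equal(chp@insertedLength, 30)
  tip1 <- chainJoints(chp)[nRods(chp) + 1L, ]
  expect_equal(tip1[3] - tip0[3], 10, tolerance = 0.1)
  # push then pull in a straight tube is reversible
  chb <- pushPull(chp, ves, -10)
  tip2 <- chainJoints(chb)[nRods(chb) + 1L, ]
  expect_equal(tip2, tip0, tolerance = 0.1)
  expect_equal(sum(rodLengths(chb)), len0, tolerance = 1e-6)
  # over-withdrawal is refused
  expect_error(pushPull(ch, ves, -25), "withdrawal")
})

test_that("twist rotates the biased tip about the local tangent", {
  # straight-tipped wire: geometry unchanged by any roll
  st <- RodChain(cbind(0:5 * 2, 0, 0), phi = 0, C = 1)
  tw <- twistChain(st, 1.234)
  expect_equal(chainJoints(tw), chainJoints(st))
  expect_equal(tw@tipRoll, 1.234)
  # curved tip: half-turn reflects the deflection through the tangent axis
  ch <- RodChain(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(6, 0, 0),
                       c(6 + 2 * cos(0.45), 2 * sin(0.45), 0)),
                 phi = c(0, 0, 0.45), C = 1)
  half <- twistChain(ch, pi)
  expect_equal(chainJoints(half)[5, 2], -chainJoints(ch)[5, 2],
               tolerance = 1e-9)
  expect_equal(bendingEnergy(half), bendingEnergy(ch), tolerance = 1e-12)
  # four quarter-turns are the identity
  four <- ch
  for (k in 1:4) four <- twistChain(four, pi / 2)
  expect_equal(chainJoints(four), chainJoints(ch), tolerance = 1e-3)
})

test_that("rupture fires strictly above the boundary force", {
  ves <- bendVessel()
  ves@FRupture <- 0.04
  cs <- new("ContactSet", depth = c(0, 0, 0.1),
            normal = rbind(c(0, 0, 0), c(0, 0, 0), c(-1, 0, 0)),
            contact = c(FALSE, FALSE, TRUE), escaped = rep(FALSE, 3))
  mkF <- function(fx) new("ForceState",
                          forces = rbind(c(0, 0, 0), c(0, 0, 0), c(fx, 0, 0)),
                          alpha = matrix(0, 3, 3), eta = 0.5)
  expect_null(checkRupture(cs, mkF(-0.99 * 0.04), ves))
  expect_null(checkRupture(cs, mkF(-0.04), ves))          # equality: no event
  ev <- checkRupture(cs, mkF(-1.01 * 0.04), ves,
                     chain = RodChain(rbind(c(0, 0, 0), c(1, 0, 0),
                                            c(2, 0, 0))))
  expect_equal(ev$joint, 3L)
  expect_equal(ev$force, 1.01 * 0.04, tolerance = 1e-12)
  expect_equal(length(ev$location), 3L)
})
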