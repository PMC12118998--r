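# Inter-cell and environmental force terms, and the drag (mass) matrix.

test_that("motive force pulls the nearest cell inside the cone", {
  # neighbour behind the cell: empty cone, no force
  st <- makeState(rbind(c(0, 10, 0), c(0, 0, 0)))
  res <- motiveForce(st, 1, kappa = 0.4, psi = 90)
  expect_true(is.na(res$target))
  expect_identical(res$forceSelf, rep(0, 3))
  # single neighbour directly ahead (a-axis is +y)
  st <- makeState(rbind(c(0, 0, 0), c(0, 10, 0)))
  res <- motiveForce(st, 1, kappa = 0.4, psi = 90)
  expect_identical(res$target, 2L)
  expect_equal(res$forceSelf, c(0, 0.4, 0))
  expect_equal(res$forceTarget, -res$forceSelf)
  # nearest of two in-cone candidates wins
  st <- makeState(rbind(c(0, 0, 0), c(0, 9, 0), c(1, 8, 0)))
  expect_identical(motiveForce(st, 1, 0.4, 90)$target, 3L)
  # exact distance tie broken by the lowest index
  st <- makeState(rbind(c(0, 0, 0), c(3, 8, 0), c(-3, 8, 0)))
  expect_identical(motiveForce(st, 1, 0.4, 90)$target, 2L)
  # narrow cone excludes oblique neighbours
  st <- makeState(rbind(c(0, 0, 0), c(8, 8, 0)))
  expect_true(is.na(motiveForce(st, 1, 0.4, 30)$target))
})

test_that("adhesion is piecewise in the enlarged overlap and continuous", {
  recAt <- function(dist) {
    st <- makeState(rbind(c(0, 0, 0), c(0, dist, 0)))
    overlapRecord(st, 1, 2)
  }
  alpha <- 0.1
  # enlarged cells just touching (dist = 1.4 * 10): zero force
  expect_equal(adhesionForce(recAt(14), alpha), rep(0, 3))
  # beyond reach
  expect_equal(adhesionForce(recAt(15), alpha), rep(0, 3))
  # first knot d0E = 0.1 (dEi + dEj): both branches agree (continuity)
  sum14 <- 14
  distKnot1 <- sum14 - 0.1 * sum14
  below <- adhesionForce(recAt(distKnot1 + 1e-7), alpha)
  above <- adhesionForce(recAt(distKnot1 - 1e-7), alpha)
  expect_equal(below, above, tolerance = 1e-4)
  zbar <- intersectionArea(7, 7, 0.9 * sum14)
  expect_equal(below[2], alpha * zbar, tolerance = 1e-4)
  # mid-ramp d0E = 0.2 (dEi + dEj): quadratic factor 1/4
  mid <- adhesionForce(recAt(sum14 - 0.2 * sum14), alpha)
  expect_equal(mid[2], 0.25 * alpha * zbar, tolerance = 1e-10)
  # second knot d0E = 0.3 (dEi + dEj): force reaches zero
  nearEnd <- adhesionForce(recAt(sum14 - 0.3 * sum14 + 1e-7), alpha)
  expect_lt(abs(nearEnd[2]), 1e-5)
  # attraction: force on i points toward j
  expect_gt(adhesionForce(recAt(13), alpha)[2], 0)
})

test_that("boundary force is the printed piecewise form, continuous", {
  expect_equal(boundaryForce(c(17.5, 3, 17.5)), rep(0, 3))       # interior
  expect_equal(boundaryForce(c(2, 0, 17.5))[1], 30)              # 10*(5-2)
  expect_equal(boundaryForce(c(-1, 0, 17.5))[1], 50)             # saturated
  expect_equal(boundaryForce(c(33, 0, 17.5))[1], -30)
  expect_equal(boundaryForce(c(36, 0, 17.5))[1], -50)
  expect_equal(boundaryForce(c(17.5, 0, 2))[3], 30)              # same in z
  expect_equal(boundaryForce(c(17.5, 99, 17.5)), rep(0, 3))      # y free
  # continuity at all four knots
  for (knot in c(0, 5, 30, 35)) {
    lo <- boundaryForce(c(knot - 1e-9, 0, 17.5))[1]
    hi <- boundaryForce(c(knot + 1e-9, 0, 17.5))[1]
    expect_equal(lo, hi, tolerance = 1e-6)
  }
})

test_that("nucleus repulsion matches the printed exponential", {
  recAt <- function(dist) {
    st <- makeState(rbind(c(0, 0, 0), c(0, dist, 0)))
    overlapRecord(st, 1, 2)
  }
  expect_equal(nucleusForce(recAt(4)), rep(0, 3))     # continuous onset
  expect_equal(nucleusForce(recAt(5)), rep(0, 3))     # outside range
  f2 <- nucleusForce(recAt(2))
  expect_equal(f2[2], -10 * (exp(0.75) - 1), tolerance = 1e-12)
  # capped below 0.5 um separation
  expect_equal(nucleusForce(recAt(0.2))[2], nucleusForce(recAt(0.5))[2],
               tolerance = 1e-9)
})

test_that("rheological pair forces cancel and match the projection oracle", {
  # no overlap: zero pair
  st <- makeState(rbind(c(0, 0, 0), c(0, 12, 0)))
  rec <- overlapRecord(st, 1, 2)
  fitRest <- list(semiAxes = c(5, 5, 5))
  pf <- rheologicalPairForces(st, rec, fitRest, fitRest)
  expect_equal(pf$forceI, rep(0, 3))
  # symmetric head-on overlap: equal magnitude, opposite, collinear with v
  st <- makeState(rbind(c(0, 0, 0), c(0, 8, 0)))
  rec <- overlapRecord(st, 1, 2)
  tg <- shapeTargets(st, 1, list(rec))
  fit1 <- fitDeformedRadii(c(5, 5, 5), tg$directions, tg$dTargets)
  tg2 <- shapeTargets(st, 2, list(rec))
  fit2 <- fitDeformedRadii(c(5, 5, 5), tg2$directions, tg2$dTargets)
  pf <- rheologicalPairForces(st, rec, fit1, fit2)
  expect_equal(pf$forceI, -pf$forceJ, tolerance = 1e-12)
  expect_equal(pf$forceI[c(1, 3)], c(0, 0), tolerance = 1e-8)
  expect_lt(pf$forceI[2], 0)      # push away from the neighbour
  # magnitude: both cells compressed by d0/2 = 1 along the y (body b) axis
  expect_equal(pf$forceI[2], -2 * 200 * 1, tolerance = 1e-4)
  # asymmetric overlap still sums to zero
  st3 <- makeState(rbind(c(0, 0, 0), c(0, 8.6, 0)),
                   semiAxes = rbind(c(5, 5, 5), c(4.6, 5.2, 5.2)),
                   restAxes = matrix(5, 2, 3))
  rec3 <- overlapRecord(st3, 1, 2)
  f1 <- fitDeformedRadii(st3@semiAxes[1, ], shapeTargets(st3, 1, list(rec3))$directions,
                         shapeTargets(st3, 1, list(rec3))$dTargets)
  f2b <- fitDeformedRadii(st3@semiAxes[2, ], shapeTargets(st3, 2, list(rec3))$directions,
                          shapeTargets(st3, 2, list(rec3))$dTargets)
  pf3 <- rheologicalPairForces(st3, rec3, f1, f2b)
  expect_equal(pf3$forceI + pf3$forceJ, rep(0, 3), tolerance = 1e-12)
})

test_that("drag matrix has the printed block structure", {
  cfg <- runConfig()
  # isolated cell: chi_ii = 1, diagonal block = muF * I (plus the tiny ridge)
  st1 <- makeState(matrix(c(17.5, 0, 17.5), 1))
  M1 <- dragMatrix(st1, cfg)
  expect_equal(M1, 0.1 * (1 + 1e-9) * diag(3), tolerance = 1e-12)
  # two-cell contact: symmetric, block-row sums chi_ii * muF * I
  st2 <- makeState(rbind(c(10, 0, 17.5), c(10, 9, 17.5)))
  ev <- assembleForces(st2, cfg)
  D <- ev$drag
  expect_equal(D, t(D))
  rec <- overlapRecord(st2, 1, 2)
  chi <- intersectionArea(rec$dI, rec$dJ, rec$dist) / (100 * pi)
  expect_equal(D[1, 2], -chi * 2)                      # muCell = 20 * 0.1
  expect_equal(D[1, 1], (1 - chi) * 0.1 + chi * 2 + 1e-10)
  expect_equal(sum(D[1, ]), (1 - chi) * 0.1 + 1e-10)   # row sum chi_ii muF
  # deeply surrounded cell: the summed contact fractions exceed one and
  # chi_ii clamps at zero
  center <- c(17.5, 20, 17.5)
  offs <- rbind(c(5.5, 0, 0), c(-5.5, 0, 0), c(0, 5.5, 0), c(0, -5.5, 0),
                c(0, 0, 5.5), c(0, 0, -5.5))
  stS <- makeState(rbind(center, sweep(offs, 2, center, "+")))
  DS <- assembleForces(stS, cfg)$drag
  expect_lt(abs(sum(DS[1, ]) - 1e-10), 1e-13)   # chi_ii clamped at zero
})

test_that("drag matrix is positive definite and reduces to muF when free", {
  st <- randomLatticeState(4)
  D <- assembleForces(st, runConfig())$drag
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_gt(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values), 0)
  # no contacts: solving M x = F is x = F / muF
  far <- makeState(rbind(c(17.5, 0, 17.5), c(17.5, 100, 17.5)))
  Df <- assembleForces(far, runConfig())$drag
  expect_equal(Df, 0.1 * (1 + 1e-9) * diag(2), tolerance = 1e-12)
})

test_that("assembled forces match a naive term-by-term recomputation", {
  cfg <- runConfig()
  for (seedCase in c(2, 13)) {
    st <- randomLatticeState(seedCase)
    ev <- assembleForces(st, cfg)
    n <- nCells(st)
    kap <- ifelse(st@type == "prestalk", 0.4, 0.01)
    psi <- ifelse(st@type == "prestalk", 30, 90)
    # naive double loop over all pairs, using the granular R functions
    F <- matrix(0, n, 3)
    fits <- vector("list", n)
    recs <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- overlapRecord(st, i, j)
      recs[[length(recs) + 1]] <- r
    }
    for (i in 1:n) {
      mine <- Filter(function(r) (r$i == i || r$j == i) && r$d0 > 0, recs)
      tg <- shapeTargets(st, i, mine)
      fits[[i]] <- fitDeformedRadii(st@semiAxes[i, ], tg$directions,
                                    tg$dTargets, st@restAxes[i, ])
    }
    for (i in 1:n) {
      mv <- motiveForce(st, i, kap[i], psi[i])
      F[i, ] <- F[i, ] + mv$forceSelf
      if (!is.na(mv$target)) F[mv$target, ] <- F[mv$target, ] + mv$forceTarget
      F[i, ] <- F[i, ] + boundaryForce(st@positions[i, ], cfg@rho,
                                       cfg@boxWidth, cfg@boundaryRadius)
    }
    for (r in recs) {
      fa <- adhesionForce(r, cfg@alpha)
      F[r$i, ] <- F[r$i, ] + fa
      F[r$j, ] <- F[r$j, ] - fa
      if (r$d0 > 0) {       # rheological push only across overlapping pairs
        pf <- rheologicalPairForces(st, r, fits[[r$i]], fits[[r$j]])
        F[r$i, ] <- F[r$i, ] + pf$forceI
        F[r$j, ] <- F[r$j, ] + pf$forceJ
      }
    }
    expect_equal(ev$total, F, tolerance = 1e-6)
    # drag oracle from the same records
    D <- matrix(0, n, n)
    for (r in recs) {
      chi <- intersectionArea(r$dI, r$dJ, r$dist) / (100 * pi)
      D[r$i, r$j] <- D[r$i, r$j] - chi * 2
      D[r$j, r$i] <- D[r$j, r$i] - chi * 2
    }
    for (i in 1:n) {
      chiSum <- -sum(D[i, -i]) / 2
      D[i, i] <- max(0, 1 - chiSum) * 0.1 - sum(D[i, -i]) + 1e-10
    }
    expect_equal(ev$drag, D, tolerance = 1e-9)
  }
})

test_that("internal force terms cancel in Newton pairs", {
  for (seedCase in 1:4) {
    st <- randomLatticeState(seedCase)
    ev <- assembleForces(st, runConfig())
    expect_lt(max(abs(colSums(ev$motive + ev$motiveReaction))), 1e-10)
    expect_lt(max(abs(colSums(ev$overlap + ev$overlapReaction))), 1e-10)
    expect_lt(max(abs(colSums(ev$nucleus))), 1e-10)
    expect_lt(max(abs(colSums(ev$adhesion))), 1e-10)
    # total minus boundary terms sums to zero
    net <- colSums(ev$total - ev$boundaryX - ev$boundaryZ)
    expect_lt(max(abs(net)), 1e-9)
  }
})
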