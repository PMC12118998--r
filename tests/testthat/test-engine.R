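# Initial configuration, the lagged-shape stepper and ensemble orchestration.

test_that("lattice construction places and labels cells as configured", {
  set.seed(1)
  st <- initLattice(runConfig())
  expect_identical(nCells(st), 45L)
  expect_identical(sum(cellTypes(st) == "prestalk"), 1L)
  # the prestalk cell sits at the central site of the posterior layer
  pst <- which(cellTypes(st) == "prestalk")
  expect_lt(st@positions[pst, 2], 1)          # posterior (minimum-y) layer
  expect_equal(st@positions[pst, c(1, 3)], c(17.5, 17.5), tolerance = 0.51)
  # all cells inside the channel cross-section, jitter bounded
  expect_true(all(st@positions[, c(1, 3)] > 5 & st@positions[, c(1, 3)] < 30))
  # nine-posterior: the whole back layer
  set.seed(1)
  st9 <- initLattice(runConfig(nPrestalk = 9L,
                               initialConfiguration = "nine_posterior"))
  expect_identical(sum(cellTypes(st9) == "prestalk"), 9L)
  ys <- sort(unique(round(st9@positions[, 2] / 10) * 10))
  expect_true(all(st9@positions[cellTypes(st9) == "prestalk", 2] < ys[2] - 5))
  # random assignment is seed-reproducible
  set.seed(9); a <- cellTypes(initLattice(runConfig(nPrestalk = 5L,
                                 initialConfiguration = "random")))
  set.seed(9); b <- cellTypes(initLattice(runConfig(nPrestalk = 5L,
                                 initialConfiguration = "random")))
  expect_identical(a, b)
  # a lattice wider than the channel is rejected
  expect_error(initLattice(runConfig(nCells = 245L, nPrestalk = 1L,
                                     latticeDims = c(7L, 5L, 7L))),
               "breaches")
})

test_that("an isolated force-free cell is stationary", {
  cfg <- runConfig(nCells = 1L, nPrestalk = 1L, latticeDims = c(1L, 1L, 1L),
                   jitter = 0,
                   prestalk = cellTypeParams(kappa = 0, psi = 90),
                   prespore = cellTypeParams(kappa = 0, psi = 90))
  set.seed(2)
  st <- initLattice(cfg)
  st2 <- slugStep(st, cfg, nSteps = 50L)
  expect_equal(st2@positions, st@positions, tolerance = 1e-14)
  expect_equal(st2@semiAxes, st@semiAxes, tolerance = 1e-14)
  expect_equal(st2@time, 0.05)
})

test_that("a pulling pair closes its gap with a stationary center of mass", {
  # two distant cells along y, stimulus fixed (gamma = 0), only cell 1 pulls
  cfg <- runConfig(nCells = 2L, nPrestalk = 1L, latticeDims = c(1L, 2L, 1L),
                   latticePitch = 20, jitter = 0, gamma = 0,
                   prestalk = cellTypeParams(kappa = 0.4, psi = 90),
                   prespore = cellTypeParams(kappa = 0, psi = 90))
  set.seed(3)
  st <- initLattice(cfg)
  expect_identical(cellTypes(st), c("prestalk", "prespore"))
  nSteps <- 100L
  st2 <- slugStep(st, cfg, nSteps = nSteps)
  # two-body oracle: v = +/- kappa / muF along y, gap closes at 2 kappa/muF
  vy <- 0.4 / (0.1 * (1 + 1e-9))
  t <- nSteps * cfg@dt
  expect_equal(st2@positions[1, 2], st@positions[1, 2] + vy * t,
               tolerance = 1e-9)
  expect_equal(st2@positions[2, 2], st@positions[2, 2] - vy * t,
               tolerance = 1e-9)
  expect_equal(colMeans(st2@positions), colMeans(st@positions),
               tolerance = 1e-12)
})

test_that("one step displaces no cell farther than the drag bound", {
  cfg <- runConfig()
  set.seed(4)
  st <- initLattice(cfg)
  ev <- assembleForces(st, cfg)
  vmax <- max(abs(solve(ev$drag, ev$total)))
  st2 <- slugStep(st, cfg, nSteps = 1L)
  disp <- max(abs(st2@positions - st@positions))
  expect_lte(disp, 1.5 * vmax * cfg@dt + 1e-12)
  # volumes conserved through the step up to the best-effort multi-fits
  expect_equal(apply(st2@semiAxes, 1, prod), rep(125, 45), tolerance = 0.02)
})

test_that("realizations are reproducible and zero-length runs are trivial", {
  cfg <- runConfig(totalTime = 0)
  tr0 <- runRealization(cfg, seed = 6)
  expect_identical(length(tr0@times), 1L)
  expect_identical(tr0@times, 0)
  cfg <- runConfig(totalTime = 0.2, metricStride = 0.05)
  a <- runRealization(cfg, seed = 8)
  b <- runRealization(cfg, seed = 8)
  expect_identical(a@relPos, b@relPos)
  expect_identical(a@positions, b@positions)
  c2 <- runRealization(cfg, seed = 9)
  expect_false(identical(a@relPos, c2@relPos))
})

test_that("ensembles aggregate realizations with exact statistics", {
  cfg <- runConfig(totalTime = 0.1, metricStride = 0.05, nRealizations = 3L)
  ms <- runEnsemble(cfg, seed = 1)
  expect_identical(dim(ms@values), c(3L, 3L))
  expect_identical(ms@seeds, 1:3)
  # one-pass mean/sd against the obvious two-pass oracle
  for (t in seq_along(ms@times)) {
    expect_equal(ms@mean[t], sum(ms@values[t, ]) / 3, tolerance = 1e-12)
    expect_equal(ms@sd[t],
                 sqrt(sum((ms@values[t, ] - ms@mean[t])^2) / 2),
                 tolerance = 1e-12)
  }
  # each column reproduces the corresponding seeded realization
  tr2 <- runRealization(cfg, seed = 2, recordFrames = FALSE)
  expect_identical(ms@values[, 2], tr2@relPos)
  # single realization: SD identically zero
  ms1 <- runEnsemble(runConfig(totalTime = 0.02, metricStride = 0.01,
                               nRealizations = 1L), seed = 4)
  expect_identical(ms1@sd, rep(0, length(ms1@times)))
})

test_that("short default runs respect containment, volume and spacing", {
  cfg <- runConfig(totalTime = 5, metricStride = 1)
  tr <- runRealization(cfg, seed = 12)
  P <- tr@positions
  expect_true(all(P[, 1, ] > -5 & P[, 1, ] < 40))
  expect_true(all(P[, 3, ] > -5 & P[, 3, ] < 40))
  # no tunneling: centers never closer than 1 um
  for (f in seq_along(tr@times)) {
    dm <- dist(P[, , f])
    expect_gt(min(dm), 1)
  }
  # per-cell volume bounded by the best-effort multi-neighbour fits: the
  # axis stepping conserves the product exactly, so all drift comes from
  # least-squares refits with conflicting boundary targets
  vols <- apply(tr@semiAxes[, , length(tr@times)], 1, prod)
  expect_equal(vols, rep(125, 45), tolerance = 0.02)
})
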