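test_that("support radius matches sphere symmetry and the ray oracle", {
  # sphere: any direction gives the radius
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(-0.2, 0.5, 0.9)))
    expect_equal(supportRadius(c(5, 5, 5), d), 5)
  # elongated rest shape along its long axis
  expect_equal(supportRadius(c(6.25, 4, 4), c(1, 0, 0)), 6.25)
  # oblique direction against an independent root-finding oracle
  expect_equal(supportRadius(c(6.25, 4, 4), c(1, 1, 0)),
               supportOracle(c(6.25, 4, 4), c(1, 1, 0)), tolerance = 1e-9)
  expect_equal(supportRadius(c(6.25, 4, 4), c(1, 1, 0)), 4.7646,
               tolerance = 1e-4)
  set.seed(42)
  for (k in 1:25) {
    s <- runif(3, 3, 7)
    u <- rnorm(3)
    expect_equal(supportRadius(s, u), supportOracle(s, u), tolerance = 1e-9)
  }
  # along each principal axis the support equals that semi-axis exactly
  s <- c(4.4, 5.5, 6.6)
  expect_identical(supportRadius(s, c(1, 0, 0)), 4.4)
  expect_identical(supportRadius(s, c(0, 1, 0)), 5.5)
  expect_identical(supportRadius(s, c(0, 0, 1)), 6.6)
  expect_error(supportRadius(c(5, 5, 5), c(0, 0, 0)), "zero direction")
})

test_that("overlap distance follows d0 = max(0, di + dj - dist)", {
  two <- function(dy) makeState(rbind(c(0, 0, 0), c(0, dy, 0)))
  r8 <- overlapRecord(two(8), 1, 2)
  expect_equal(r8$d0, 2)
  expect_equal(r8$dI, 5)
  expect_equal(r8$dJ, 5)
  expect_equal(overlapRecord(two(12), 1, 2)$d0, 0)
  # deep overlap: boundary of one cell beyond the other's center
  r3 <- overlapRecord(two(3), 1, 2)
  expect_equal(r3$d0, 7)
  expect_gte(r3$d0, r3$dist)
})

test_that("overlap distance is symmetric for random ellipsoid pairs", {
  set.seed(7)
  for (k in 1:20) {
    st <- makeState(rbind(runif(3, 0, 10), runif(3, 0, 10)),
                    axes = array(c(randomFrame(), randomFrame()),
                                 dim = c(3, 3, 2)),
                    semiAxes = matrix(runif(6, 4, 6), 2, 3))
    rij <- overlapRecord(st, 1, 2)
    rji <- overlapRecord(st, 2, 1)
    expect_equal(rij$d0, rji$d0, tolerance = 1e-12)
    expect_equal(rij$vhat, -rji$vhat, tolerance = 1e-12)
    expect_equal(rij$dI, rji$dJ, tolerance = 1e-12)
  }
})

test_that("intersection area matches the lens oracle and known values", {
  expect_equal(intersectionArea(5, 5, 10), 0)          # tangency
  expect_equal(intersectionArea(5, 5, 8), 9 * pi)      # symmetric lens
  expect_equal(intersectionArea(5, 3, 9), 0)           # disjoint
  set.seed(11)
  checked <- 0
  while (checked < 100) {
    r1 <- runif(1, 2, 8); r2 <- runif(1, 2, 8)
    D <- runif(1, abs(r1 - r2) + 0.05, r1 + r2 - 0.05)
    oracle <- lensOracle(r1, r2, D)
    if (oracle <= 0) next
    expect_equal(intersectionArea(r1, r2, D), oracle,
                 tolerance = 5e-3)
    checked <- checked + 1
  }
})

test_that("intersection area is monotone non-increasing in distance", {
  for (d in c(3, 5, 7)) {
    dists <- seq(1e-3, 2 * d, length.out = 200)
    areas <- vapply(dists, function(x) intersectionArea(d, d, x), 0)
    expect_true(all(diff(areas) <= 1e-12))
    expect_equal(areas[200], 0)
  }
})

test_that("single-neighbour fit conserves volume and minimizes axis sum", {
  # axis-aligned: analytic solution (4, sqrt(125/4), sqrt(125/4))
  f <- fitDeformedRadii(c(5, 5, 5), matrix(c(1, 0, 0), 1), 4)
  expect_equal(f$case, "single")
  expect_true(f$converged)
  expect_equal(f$semiAxes, c(4, sqrt(125 / 4), sqrt(125 / 4)),
               tolerance = 1e-7)
  expect_equal(prod(f$semiAxes), 125, tolerance = 1e-8)
  # oblique targets against a penalized-optimization oracle (checked only
  # when the solution is interior to the clamping band rest +/- 1)
  set.seed(3)
  interior <- 0
  for (k in 1:8) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    d <- runif(1, 4.6, 4.95)
    f <- fitDeformedRadii(c(5, 5, 5), matrix(u, 1), d)
    if (any(abs(f$semiAxes - 4) < 1e-8 | abs(f$semiAxes - 6) < 1e-8)) next
    interior <- interior + 1
    expect_equal(supportRadius(f$semiAxes, u), d, tolerance = 1e-6)
    expect_equal(prod(f$semiAxes), 125, tolerance = 1e-5)
    pen <- function(s) {
      if (any(s < 1) || any(s > 9)) return(1e9)
      sum(s) + 1e8 * ((supportRadius(s, u) - d)^2 + (prod(s) / 125 - 1)^2)
    }
    orc <- optim(c(5, 5, 5), pen, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    expect_equal(sum(f$semiAxes), sum(orc$par), tolerance = 1e-3)
  }
  expect_gte(interior, 4)
})

test_that("two-neighbour fit solves both boundary constraints exactly", {
  # orthogonal axis-aligned targets: closed-form check
  f0 <- fitDeformedRadii(c(5, 5, 5), rbind(c(1, 0, 0), c(0, 1, 0)),
                         c(4.5, 4.8))
  expect_equal(f0$case, "double")
  expect_equal(f0$semiAxes, c(4.5, 4.8, 125 / (4.5 * 4.8)),
               tolerance = 1e-7)
  # random mild targets (assert exactly only for interior solutions; the
  # clamped band rest +/- 1 truncates extreme cases by design)
  set.seed(5)
  interior <- 0
  for (k in 1:10) {
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    d <- runif(2, 4.8, 5.0)
    f <- fitDeformedRadii(c(5, 5, 5), rbind(u1, u2), d)
    expect_true(all(f$semiAxes >= 4 - 1e-9 & f$semiAxes <= 6 + 1e-9))
    if (any(abs(f$semiAxes - 4) < 1e-8 | abs(f$semiAxes - 6) < 1e-8)) next
    interior <- interior + 1
    expect_equal(supportRadius(f$semiAxes, u1), d[1], tolerance = 1e-6)
    expect_equal(supportRadius(f$semiAxes, u2), d[2], tolerance = 1e-6)
    expect_equal(prod(f$semiAxes), 125, tolerance = 1e-5)
  }
  expect_gte(interior, 4)
})

test_that("multi-neighbour fit shrinks toward the bound with a residual", {
  f <- fitDeformedRadii(c(5, 5, 5), diag(3), rep(4, 3))
  expect_equal(f$case, "multi")
  expect_true(all(f$semiAxes >= 4 - 1e-12))
  expect_true(all(f$semiAxes < 4.5))
  expect_gt(f$residual, 0)
  # least-squares oracle: box-constrained optim on the same objective
  obj <- function(s) {
    mis <- vapply(1:3, function(j) supportRadius(s, diag(3)[j, ]) - 4, 0)
    sum(mis^2) + (prod(s) / 125 - 1)^2
  }
  orc <- optim(c(5, 5, 5), obj, method = "L-BFGS-B",
               lower = rep(4, 3), upper = rep(6, 3))
  expect_equal(f$semiAxes, orc$par, tolerance = 1e-3)
})

test_that("fit with no overlapping neighbours leaves the shape unchanged", {
  f <- fitDeformedRadii(c(4.7, 5.1, 5.3), matrix(0, 0, 3), numeric(0))
  expect_equal(f$case, "none")
  expect_identical(f$semiAxes, c(4.7, 5.1, 5.3))
  expect_identical(f$residual, 0)
})

test_that("fitted semi-axes are clamped to the admissible band", {
  # an extreme target cannot push the axis below rest - 1
  f <- fitDeformedRadii(c(5, 5, 5), matrix(c(1, 0, 0), 1), 2)
  expect_gte(min(f$semiAxes), 4)
  expect_lte(max(f$semiAxes), 6)
})

test_that("shape targets put the boundary at the overlap midpoint", {
  st <- makeState(rbind(c(0, 0, 0), c(0, 8, 0)))
  rec <- overlapRecord(st, 1, 2)
  tg <- shapeTargets(st, 1, list(rec))
  expect_equal(tg$dTargets, 4)               # d1 - d0/2 = 5 - 1
  expect_equal(drop(tg$directions), drop(crossprod(st@axes[, , 1],
                                                   c(0, 1, 0))))
  # deep overlap switches to the ||v|| - 0.7 dj rule
  st2 <- makeState(rbind(c(0, 0, 0), c(0, 3, 0)))
  tg2 <- shapeTargets(st2, 1, list(overlapRecord(st2, 1, 2)))
  expect_equal(tg2$dTargets, max(0.5, 3 - 0.7 * 5))
})
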