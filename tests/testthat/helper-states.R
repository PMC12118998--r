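# Builders for small synthetic cell configurations used throughout the tests.

frameY <- function() matrix(c(0, 1, 0,  0, 0, 1,  1, 0, 0), 3L, 3L)

# a state from explicit positions; optional per-cell frames and semi-axes
makeState <- function(positions, type = NULL, axes = NULL, semiAxes = NULL,
                      restAxes = NULL) {
  positions <- matrix(positions, ncol = 3L)
  n <- nrow(positions)
  if (is.null(type)) type <- rep("prespore", n)
  if (is.null(axes)) axes <- array(rep(frameY(), n), dim = c(3L, 3L, n))
  if (is.null(restAxes)) restAxes <- matrix(5, n, 3L)
  if (is.null(semiAxes)) semiAxes <- restAxes
  new("SlugState", positions = positions, axes = axes,
      semiAxes = semiAxes, deformation = semiAxes - restAxes,
      restAxes = restAxes, type = type, time = 0)
}

# random orthonormal frame (uniform via QR of a Gaussian matrix)
randomFrame <- function() {
  qr0 <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr0)
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  R
}

# jittered 45-cell lattice with random frames and mildly deformed shapes,
# for force-assembly cross-checks
randomLatticeState <- function(seed = 1, jitterAmp = 1.5) {
  set.seed(seed)
  st <- initLattice(runConfig(jitter = jitterAmp))
  n <- nCells(st)
  axes <- array(0, dim = c(3L, 3L, n))
  for (i in seq_len(n)) axes[, , i] <- randomFrame()
  semi <- matrix(runif(3L * n, 4.2, 5.8), n, 3L)
  initialize(st, axes = axes, semiAxes = semi,
             deformation = semi - st@restAxes)
}

# independent support-distance oracle: root-find the ray-ellipsoid crossing
supportOracle <- function(semiAxes, direction) {
  direction <- direction / sqrt(sum(direction^2))
  implicit <- function(r) sum((r * direction / semiAxes)^2) - 1
  stats::uniroot(implicit, c(1e-3, 100), tol = 1e-12)$root
}

# independent lens-area oracle: locate the circle of intersection of the two
# spheres by root-finding the angle at which sphere-1 surface points are at
# distance r2 from the second center
lensOracle <- function(r1, r2, D) {
  if (D >= r1 + r2 || D <= abs(r1 - r2)) return(0)
  f <- function(th) {
    p <- c(r1 * cos(th), r1 * sin(th))
    sqrt((p[1L] - D)^2 + p[2L]^2) - r2
  }
  th <- stats::uniroot(f, c(1e-9, pi - 1e-9), tol = 1e-13)$root
  pi * (r1 * sin(th))^2
}
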