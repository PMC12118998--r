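# Initial-configuration construction and the lagged-shape time stepper.

.frameAlongY <- function() {
  # right-handed triad with the polarization axis a = +y
  matrix(c(0, 1, 0,
           0, 0, 1,
           1, 0, 0), 3L, 3L)
}

#' Build the initial lattice configuration
#'
#' Places the cells on a rectangular lattice (default 3 x 5 x 3 at 10 um
#' pitch for 45 cells) centered in the confining channel with the long axis
#' along y, applies uniform positional jitter, and assigns cell types:
#' \code{"one_posterior"} puts the single minority prestalk cell at the
#' central site of the posterior (minimum-y) layer, \code{"nine_posterior"}
#' makes the whole posterior layer prestalk, and \code{"random"} draws
#' \code{nPrestalk} sites without replacement.  All cells start as rest
#' ellipsoids polarized along +y.
#'
#' Jitter and random type assignment consume R's RNG stream (jitter first),
#' so the construction is reproducible under \code{\link{set.seed}}.
#'
#' @param config a [RunConfig-class]
#' @return a [SlugState-class] at time 0
#' @examples
#' set.seed(1)
#' st <- initLattice(runConfig())
#' table(cellTypes(st))
#' @export
initLattice <- function(config = runConfig()) {
  validObject(config)
  dims <- config@latticeDims
  pitch <- config@latticePitch
  w <- config@boxWidth
  r <- config@boundaryRadius
  xs <- w / 2 + (seq_len(dims[1L]) - (dims[1L] + 1) / 2) * pitch
  zs <- w / 2 + (seq_len(dims[3L]) - (dims[3L] + 1) / 2) * pitch
  ys <- (seq_len(dims[2L]) - 1) * pitch
  if (min(xs) < -r || max(xs) > w + r || min(zs) < -r || max(zs) > w + r)
    stop(sprintf(paste("lattice cross-section (%.1f to %.1f um) breaches the",
                       "%g um channel by more than one cell radius;",
                       "reduce latticeDims or pitch"),
                 min(xs, zs), max(xs, zs), w))
  grid <- expand.grid(ix = seq_len(dims[1L]), iz = seq_len(dims[3L]),
                      iy = seq_len(dims[2L]))
  n <- nrow(grid)
  stopifnot(n == config@nCells)
  P <- cbind(xs[grid$ix], ys[grid$iy], zs[grid$iz])
  P <- P + matrix(runif(3L * n, -config@jitter, config@jitter), n, 3L)

  type <- rep("prespore", n)
  posterior <- which(grid$iy == 1L)
  if (config@initialConfiguration == "one_posterior") {
    if (config@nPrestalk != 1L)
      stop("'one_posterior' requires nPrestalk = 1")
    center <- posterior[grid$ix[posterior] == ceiling(dims[1L] / 2) &
                        grid$iz[posterior] == ceiling(dims[3L] / 2)]
    type[center[1L]] <- "prestalk"
  } else if (config@initialConfiguration == "nine_posterior") {
    if (config@nPrestalk != length(posterior))
      stop(sprintf("'nine_posterior' requires nPrestalk = %d (posterior layer)",
                   length(posterior)))
    type[posterior] <- "prestalk"
  } else {
    type[sample(n, config@nPrestalk)] <- "prestalk"
  }

  isPst <- type == "prestalk"
  rest <- matrix(rep(config@prespore@restAxes, each = n), n, 3L)
  if (any(isPst))
    rest[isPst, ] <- matrix(config@prestalk@restAxes, sum(isPst), 3L,
                            byrow = TRUE)
  axes <- array(rep(.frameAlongY(), n), dim = c(3L, 3L, n))
  new("SlugState", positions = P, axes = axes, semiAxes = rest,
      deformation = matrix(0, n, 3L), restAxes = rest, type = type,
      time = 0)
}

.runCore <- function(state, config, nSteps, stride, recordFrames) {
  cpp_run(state@positions, as.numeric(state@axes), state@semiAxes,
          state@deformation, state@type == "prestalk",
          .paramList(state, config), as.integer(nSteps), as.integer(stride),
          recordFrames)
}

#' Advance the slug by one or more time steps
#'
#' Each step of the lagged-shape scheme: (1) resample stimulus directions
#' and rotate the polarization frames; (2) with shapes frozen at the step's
#' start, evaluate all forces and solve the drag system \eqn{M p' = F} to
#' advance the positions; (3) at the new positions apply the instantaneous
#' overlap deformations and relax every cell's shape force-free to the
#' current time; (4) advance the clock.
#'
#' @param state a [SlugState-class]
#' @param config a [RunConfig-class]
#' @param nSteps number of time steps of length \code{config@dt}
#' @return the advanced [SlugState-class]
#' @export
slugStep <- function(state, config = runConfig(), nSteps = 1L) {
  stopifnot(is(state, "SlugState"), nSteps >= 1L)
  res <- .runCore(state, config, nSteps, nSteps, FALSE)
  new("SlugState", positions = res$positions,
      axes = array(res$axes, dim = dim(state@axes)),
      semiAxes = res$semiAxes, deformation = res$deformation,
      restAxes = state@restAxes, type = state@type,
      time = state@time + nSteps * config@dt)
}

#' Run one seeded realization
#'
#' Seeds the RNG, builds the initial lattice and integrates to
#' \code{config@totalTime}, recording positions, semi-axes, polarization
#' axes and the relative prestalk position every \code{config@metricStride}
#' seconds.  Identical seeds give identical trajectories.
#'
#' @param config a [RunConfig-class]
#' @param seed integer RNG seed
#' @param recordFrames keep full frames (set \code{FALSE} to store only the
#'   metric series)
#' @return a [Trajectory-class]
#' @examples
#' cfg <- runConfig(totalTime = 0.05, metricStride = 0.01)
#' tr <- runRealization(cfg, seed = 1)
#' relativePosition(tr)
#' @export
runRealization <- function(config = runConfig(), seed = 1L,
                           recordFrames = TRUE) {
  validObject(config)
  set.seed(seed)
  state <- initLattice(config)
  nSteps <- round(config@totalTime / config@dt)
  stride <- max(1L, round(config@metricStride / config@dt))
  res <- .runCore(state, config, nSteps, stride, recordFrames)
  n <- nCells(state)
  empty <- array(numeric(0), dim = c(n, 3L, 0L))
  new("Trajectory", times = res$times, relPos = res$relpos,
      positions = if (recordFrames) res$framePositions else empty,
      semiAxes = if (recordFrames) res$frameSemiAxes else empty,
      aAxis = if (recordFrames) res$frameAAxis else empty,
      type = state@type, config = config, seed = as.integer(seed),
      clampEvents = res$clampEvents, fitFailures = res$fitFailures)
}

#' Run an ensemble of realizations
#'
#' Runs \code{config@nRealizations} realizations with seeds \code{seed},
#' \code{seed + 1}, ... and aggregates the relative-position series into the
#' per-time ensemble mean and standard deviation.
#'
#' @param config a [RunConfig-class]
#' @param seed seed of the first realization
#' @return a [MetricsSeries-class]
#' @examples
#' cfg <- runConfig(totalTime = 0.02, metricStride = 0.01, nRealizations = 2L)
#' ms <- runEnsemble(cfg, seed = 1)
#' ensembleMean(ms)
#' @export
runEnsemble <- function(config = runConfig(), seed = 1L) {
  validObject(config)
  stopifnot(config@nRealizations >= 1L)
  seeds <- as.integer(seed + seq_len(config@nRealizations) - 1L)
  series <- lapply(seeds, function(s)
    runRealization(config, seed = s, recordFrames = FALSE))
  vals <- vapply(series, function(tr) tr@relPos,
                 numeric(length(series[[1L]]@times)))
  vals <- matrix(vals, ncol = length(seeds))
  sdv <- if (ncol(vals) == 1L) rep(0, nrow(vals))
         else apply(vals, 1L, stats::sd)
  new("MetricsSeries", times = series[[1L]]@times, values = vals,
      mean = rowMeans(vals), sd = sdv, seeds = seeds, config = config)
}
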