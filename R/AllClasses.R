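#' Per-type mechanical and behavioural cell parameters
#'
#' Holds the parameters that differ (or may differ) between prestalk and
#' prespore cells: the standard-linear-solid constants of the three ellipsoid
#' axes, the rest semi-axes, the motive-force magnitude \eqn{\kappa} and the
#' motive cone half-angle \eqn{\psi}.
#'
#' @slot kPar spring constants in parallel with the Maxwell arm, one per axis
#'   (g/s^2)
#' @slot kSer spring constants in series with the dashpot, one per axis
#'   (g/s^2)
#' @slot muDash dashpot coefficients, one per axis (g/s)
#' @slot restAxes rest (stress-free) semi-axes (um)
#' @slot kappa motive-force magnitude (g um/s^2)
#' @slot psi motive cone half-angle about the polarization axis (degrees)
#' @export
setClass("CellTypeParams",
  representation(kPar = "numeric", kSer = "numeric", muDash = "numeric",
                 restAxes = "numeric", kappa = "numeric", psi = "numeric"))

setValidity("CellTypeParams", function(object) {
  msg <- character()
  for (sl in c("kPar", "kSer", "muDash", "restAxes"))
    if (length(slot(object, sl)) != 3L || any(slot(object, sl) <= 0))
      msg <- c(msg, sprintf("'%s' must be 3 positive values", sl))
  if (length(object@kappa) != 1L || object@kappa < 0)
    msg <- c(msg, "'kappa' must be a single value >= 0")
  if (length(object@psi) != 1L || object@psi <= 0 || object@psi > 180)
    msg <- c(msg, "'psi' must be in (0, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' Construct per-type cell parameters
#'
#' Defaults are the study's standard mechanical constants: all three axes have
#' parallel and series springs of 100 g/s^2 and dashpots of 160 g/s, and the
#' rest shape is a 5 um sphere.
#'
#' @param kappa motive-force magnitude (g um/s^2)
#' @param psi motive cone half-angle (degrees)
#' @param kPar,kSer spring constants per axis (g/s^2)
#' @param muDash dashpot coefficients per axis (g/s)
#' @param restAxes rest semi-axes (um)
#' @return a [CellTypeParams-class] object
#' @examples
#' prestalk <- cellTypeParams(kappa = 0.4, psi = 30)
#' prespore <- cellTypeParams(kappa = 0.01, psi = 90)
#' @export
cellTypeParams <- function(kappa = 0.4, psi = 30,
                           kPar = rep(100, 3), kSer = rep(100, 3),
                           muDash = rep(160, 3), restAxes = rep(5, 3)) {
  new("CellTypeParams", kPar = as.numeric(kPar), kSer = as.numeric(kSer),
      muDash = as.numeric(muDash), restAxes = as.numeric(restAxes),
      kappa = as.numeric(kappa), psi = as.numeric(psi))
}

#' Run configuration for a slug simulation
#'
#' Bundles the global parameters (population, time step, drag, adhesion,
#' boundary and stimulus settings), the two per-type parameter sets, the
#' initial-configuration choice and the ensemble settings.
#'
#' @slot nCells total number of cells
#' @slot nPrestalk number of prestalk cells
#' @slot dt time step (s)
#' @slot totalTime simulated duration (s)
#' @slot prestalk,prespore per-type parameters ([CellTypeParams-class])
#' @slot muF fluid drag coefficient (g/s)
#' @slot muCellFactor cell-cell drag as a multiple of \code{muF}
#' @slot rho boundary-force stiffness (g/s^2)
#' @slot alpha adhesion strength (g um/s^2)
#' @slot gamma chemoattractant-direction cone half-angle about +y (degrees)
#' @slot rotIncrement rotation increment per time step (degrees)
#' @slot resampleEvery steps between stimulus-direction resamples (default
#'   1000 steps, i.e. 1 s at the default dt: directional noise persists on
#'   the second timescale)
#' @slot boxWidth confining channel width in x and z (um)
#' @slot boundaryRadius cell radius used by the boundary force (um)
#' @slot latticeDims initial lattice extent (cells in x, y, z)
#' @slot latticePitch lattice spacing (um)
#' @slot jitter uniform positional perturbation half-width (um)
#' @slot initialConfiguration one of \code{"one_posterior"},
#'   \code{"nine_posterior"}, \code{"random"}
#' @slot shapeUpdateInterval shape-lag interval (s): shapes are frozen while
#'   positions advance, then deformed and relaxed at this cadence (default:
#'   every time step)
#' @slot metricStride metric recording interval (s)
#' @slot nRealizations ensemble size
#' @slot integrator \code{"adaptive"} (displacement-controlled explicit
#'   Euler), \code{"rk2"} (midpoint) or \code{"euler"} (fixed step)
#' @export
setClass("RunConfig",
  representation(nCells = "integer", nPrestalk = "integer", dt = "numeric",
                 totalTime = "numeric", prestalk = "CellTypeParams",
                 prespore = "CellTypeParams", muF = "numeric",
                 muCellFactor = "numeric", rho = "numeric", alpha = "numeric",
                 gamma = "numeric", rotIncrement = "numeric",
                 resampleEvery = "integer", boxWidth = "numeric",
                 boundaryRadius = "numeric", latticeDims = "integer",
                 latticePitch = "numeric", jitter = "numeric",
                 initialConfiguration = "character",
                 shapeUpdateInterval = "numeric", metricStride = "numeric",
                 nRealizations = "integer", integrator = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "'dt' must be positive")
  if (object@totalTime < 0) msg <- c(msg, "'totalTime' must be >= 0")
  if (object@nPrestalk < 0L || object@nPrestalk > object@nCells)
    msg <- c(msg, "need 0 <= nPrestalk <= nCells")
  if (prod(object@latticeDims) != object@nCells)
    msg <- c(msg, "prod(latticeDims) must equal nCells")
  if (!object@initialConfiguration %in%
        c("one_posterior", "nine_posterior", "random"))
    msg <- c(msg, "unknown 'initialConfiguration'")
  if (!object@integrator %in% c("adaptive", "rk2", "euler"))
    msg <- c(msg, "'integrator' must be \"adaptive\", \"rk2\" or \"euler\"")
  if (object@metricStride < object@dt)
    msg <- c(msg, "'metricStride' must be >= dt")
  if (object@shapeUpdateInterval < object@dt)
    msg <- c(msg, "'shapeUpdateInterval' must be >= dt")
  if (length(msg)) msg else TRUE
})

#' Construct a run configuration
#'
#' Defaults reproduce the study's standard conditions: a 45-cell slug (3 x 5 x
#' 3 lattice at 10 um pitch, jitter +/- 0.5 um) with a single posterior
#' prestalk cell, dt = 0.001 s, fluid drag 0.1 g/s, cell-cell drag 20 muF,
#' boundary stiffness rho = 10 g/s^2, adhesion alpha = 0.1 g um/s^2, and
#' per-type motive parameters kappa = 0.4, psi = 30 (prestalk) versus
#' kappa = 0.01, psi = 90 (prespore).
#'
#' @param nCells,nPrestalk population and prestalk count
#' @param dt time step (s)
#' @param totalTime simulated duration (s)
#' @param prestalk,prespore [CellTypeParams-class] objects
#' @param muF fluid drag (g/s)
#' @param muCellFactor cell-cell drag multiple of \code{muF}
#' @param rho boundary stiffness (g/s^2)
#' @param alpha adhesion strength (g um/s^2)
#' @param gamma stimulus cone half-angle (degrees)
#' @param rotIncrement rotation increment per step (degrees)
#' @param resampleEvery steps between stimulus resampling
#' @param boxWidth channel width (um)
#' @param boundaryRadius boundary-force cell radius (um)
#' @param latticeDims lattice cell counts in x, y, z
#' @param latticePitch lattice spacing (um)
#' @param jitter positional perturbation half-width (um)
#' @param initialConfiguration prestalk placement scheme
#' @param shapeUpdateInterval shape-lag interval (s)
#' @param metricStride metric recording interval (s)
#' @param nRealizations ensemble size
#' @param integrator position integrator
#' @return a validated [RunConfig-class]
#' @examples
#' cfg <- runConfig(totalTime = 10)
#' @export
runConfig <- function(nCells = 45L, nPrestalk = 1L, dt = 0.001,
                      totalTime = 500,
                      prestalk = cellTypeParams(kappa = 0.4, psi = 30),
                      prespore = cellTypeParams(kappa = 0.01, psi = 90),
                      muF = 0.1, muCellFactor = 20, rho = 10, alpha = 0.1,
                      gamma = 15, rotIncrement = 5, resampleEvery = 1000L,
                      boxWidth = 35, boundaryRadius = 5,
                      latticeDims = c(3L, 5L, 3L), latticePitch = 10,
                      jitter = 0.5, initialConfiguration = "one_posterior",
                      shapeUpdateInterval = 0.001, metricStride = 1,
                      nRealizations = 5L, integrator = "adaptive") {
  new("RunConfig", nCells = as.integer(nCells),
      nPrestalk = as.integer(nPrestalk), dt = dt, totalTime = totalTime,
      prestalk = prestalk, prespore = prespore, muF = muF,
      muCellFactor = muCellFactor, rho = rho, alpha = alpha, gamma = gamma,
      rotIncrement = rotIncrement, resampleEvery = as.integer(resampleEvery),
      boxWidth = boxWidth, boundaryRadius = boundaryRadius,
      latticeDims = as.integer(latticeDims), latticePitch = latticePitch,
      jitter = jitter, initialConfiguration = initialConfiguration,
      shapeUpdateInterval = shapeUpdateInterval, metricStride = metricStride,
      nRealizations = as.integer(nRealizations), integrator = integrator)
}

#' Instantaneous state of the simulated slug
#'
#' @slot positions n x 3 cell centers (um)
#' @slot axes 3 x 3 x n orthonormal body frames; column 1 of each slice is
#'   the polarization axis \strong{a}
#' @slot semiAxes n x 3 current semi-axes (um)
#' @slot deformation n x 3 axis deformations from rest (um)
#' @slot restAxes n x 3 rest semi-axes (um)
#' @slot type character, \code{"prestalk"} or \code{"prespore"}
#' @slot time simulation clock (s)
#' @export
setClass("SlugState",
  representation(positions = "matrix", axes = "array", semiAxes = "matrix",
                 deformation = "matrix", restAxes = "matrix",
                 type = "character", time = "numeric"))

setValidity("SlugState", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
  if (!all(dim(object@axes) == c(3L, 3L, n)))
    msg <- c(msg, "axes must be 3 x 3 x n")
  if (!all(dim(object@semiAxes) == c(n, 3L)))
    msg <- c(msg, "semiAxes must be n x 3")
  if (length(object@type) != n)
    msg <- c(msg, "one type label per cell required")
  if (!all(object@type %in% c("prestalk", "prespore")))
    msg <- c(msg, "types must be 'prestalk' or 'prespore'")
  if (!all(is.finite(object@positions)))
    msg <- c(msg, "positions must be finite")
  if (length(msg)) msg else TRUE
})

#' Recorded trajectory of a single realization
#'
#' @slot times recorded times (s)
#' @slot relPos relative prestalk position at each recorded time
#' @slot positions n x 3 x T recorded centers
#' @slot semiAxes n x 3 x T recorded semi-axes
#' @slot aAxis n x 3 x T recorded polarization axes
#' @slot type cell type labels
#' @slot config the [RunConfig-class] used
#' @slot seed RNG seed of this realization
#' @slot clampEvents number of semi-axis clamping events during the run
#' @slot fitFailures number of non-converged shape fits (previous shape kept)
#' @export
setClass("Trajectory",
  representation(times = "numeric", relPos = "numeric", positions = "array",
                 semiAxes = "array", aAxis = "array", type = "character",
                 config = "RunConfig", seed = "integer",
                 clampEvents = "numeric", fitFailures = "numeric"))

#' Ensemble series of the sorting metric
#'
#' @slot times recorded times (s)
#' @slot values T x R matrix of per-realization relative positions
#' @slot mean,sd per-time ensemble mean and standard deviation
#' @slot seeds seeds of the realizations
#' @slot config the [RunConfig-class] used
#' @export
setClass("MetricsSeries",
  representation(times = "numeric", values = "matrix", mean = "numeric",
                 sd = "numeric", seeds = "integer", config = "RunConfig"))

# ---- accessors and show methods -------------------------------------------

#' Number of cells
#' @param x a SlugState or Trajectory
#' @return integer cell count
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "SlugState", function(x) nrow(x@positions))

#' @rdname nCells
#' @export
setMethod("nCells", "Trajectory", function(x) dim(x@positions)[1L])

#' Cell type labels
#' @param x a SlugState or Trajectory
#' @return character vector of types
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "SlugState", function(x) x@type)

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "Trajectory", function(x) x@type)

#' Cell center positions
#' @param x a SlugState
#' @return n x 3 matrix (um)
#' @export
setGeneric("cellPositions", function(x) standardGeneric("cellPositions"))

#' @rdname cellPositions
#' @export
setMethod("cellPositions", "SlugState", function(x) x@positions)

#' Current semi-axes
#' @param x a SlugState
#' @return n x 3 matrix (um)
#' @export
setGeneric("cellSemiAxes", function(x) standardGeneric("cellSemiAxes"))

#' @rdname cellSemiAxes
#' @export
setMethod("cellSemiAxes", "SlugState", function(x) x@semiAxes)

#' Simulation clock
#' @param x a SlugState
#' @return time (s)
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' @rdname simTime
#' @export
setMethod("simTime", "SlugState", function(x) x@time)

#' Recorded metric times
#' @param x a Trajectory or MetricsSeries
#' @return numeric times (s)
#' @export
setGeneric("metricTimes", function(x) standardGeneric("metricTimes"))

#' @rdname metricTimes
#' @export
setMethod("metricTimes", "Trajectory", function(x) x@times)

#' @rdname metricTimes
#' @export
setMethod("metricTimes", "MetricsSeries", function(x) x@times)

#' Ensemble mean of the sorting metric
#' @param x a MetricsSeries
#' @return numeric vector
#' @export
setGeneric("ensembleMean", function(x) standardGeneric("ensembleMean"))

#' @rdname ensembleMean
#' @export
setMethod("ensembleMean", "MetricsSeries", function(x) x@mean)

#' Ensemble standard deviation of the sorting metric
#' @param x a MetricsSeries
#' @return numeric vector
#' @export
setGeneric("ensembleSD", function(x) standardGeneric("ensembleSD"))

#' @rdname ensembleSD
#' @export
setMethod("ensembleSD", "MetricsSeries", function(x) x@sd)

#' Per-realization metric values
#' @param x a MetricsSeries
#' @return T x R matrix
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname metricValues
#' @export
setMethod("metricValues", "MetricsSeries", function(x) x@values)

setMethod("show", "CellTypeParams", function(object) {
  cat("CellTypeParams: kappa =", object@kappa, "g um/s^2, psi =", object@psi,
      "deg\n  rest semi-axes:", paste(object@restAxes, collapse = ", "),
      "um\n  kPar:", paste(object@kPar, collapse = ", "),
      " kSer:", paste(object@kSer, collapse = ", "),
      " muDash:", paste(object@muDash, collapse = ", "), "\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:", object@nCells, "cells (", object@nPrestalk,
      "prestalk ),", object@initialConfiguration, "\n")
  cat("  dt =", object@dt, "s, totalTime =", object@totalTime,
      "s, integrator =", object@integrator, "\n")
  cat("  prestalk: kappa =", object@prestalk@kappa, ", psi =",
      object@prestalk@psi, "; prespore: kappa =", object@prespore@kappa,
      ", psi =", object@prespore@psi, "\n")
  cat("  gamma =", object@gamma, "deg, ensemble of", object@nRealizations,
      "realizations\n")
})

setMethod("show", "SlugState", function(object) {
  cat("SlugState:", nCells(object), "cells at t =", object@time, "s\n")
  cat("  prestalk:", sum(object@type == "prestalk"), " prespore:",
      sum(object@type == "prespore"), "\n")
  yr <- range(object@positions[, 2L])
  cat(sprintf("  y span: [%.2f, %.2f] um; relative prestalk position: %.3f\n",
              yr[1L], yr[2L], relativePosition(object)))
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nCells(object), "cells,", length(object@times),
      "frames over", max(object@times), "s (seed", object@seed, ")\n")
  cat(sprintf("  relative position: %.3f -> %.3f\n",
              object@relPos[1L], object@relPos[length(object@relPos)]))
})

setMethod("show", "MetricsSeries", function(object) {
  cat("MetricsSeries:", ncol(object@values), "realizations,",
      length(object@times), "time points\n")
  cat(sprintf("  mean relative position: %.3f -> %.3f (final SD %.3f)\n",
              object@mean[1L], object@mean[length(object@mean)],
              object@sd[length(object@sd)]))
})
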