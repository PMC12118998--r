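# Inter-cell and environmental force terms.  The granular functions here are
# the documented per-term surface; the engine evaluates the same terms in
# compiled code, and the two are cross-checked in the test suite.

# flatten state + config into the parameter list consumed by the C++ kernels
.paramList <- function(state, config) {
  isPst <- state@type == "prestalk"
  pick <- function(slotName) {
    pst <- slot(config@prestalk, slotName)
    psp <- slot(config@prespore, slotName)
    if (length(pst) == 1L) ifelse(isPst, pst, psp)
    else t(vapply(isPst, function(p) if (p) pst else psp, numeric(3L)))
  }
  list(kappa = pick("kappa"), psi = pick("psi"), kPar = pick("kPar"),
       kSer = pick("kSer"), muDash = pick("muDash"), rest = state@restAxes,
       muF = config@muF, muCell = config@muCellFactor * config@muF,
       rho = config@rho, alpha = config@alpha, boxWidth = config@boxWidth,
       boundaryRadius = config@boundaryRadius, gamma = config@gamma,
       rotIncrement = config@rotIncrement,
       resampleEvery = config@resampleEvery, dt = config@dt,
       shapeUpdateEvery =
         max(1L, as.integer(round(config@shapeUpdateInterval / config@dt))),
       integrator = config@integrator)
}

#' Motive force of one cell
#'
#' The cell pulls on the nearest neighbouring cell center inside the cone of
#' half-angle \eqn{\psi} about its polarization axis \strong{a}.  The moving
#' cell receives the traction reaction \eqn{+\kappa \hat v_{ij}} and the
#' pulled neighbour \eqn{-\kappa \hat v_{ij}}; both are zero when the cone is
#' empty.  Ties in distance are broken by the lowest cell index.  Candidates
#' whose centers lie inside the pulling cell's own surface are skipped: an
#' engulfed center cannot serve as a pseudopod anchor, and the cell reaches
#' for the next center beyond it.
#'
#' @param state a [SlugState-class]
#' @param i index of the moving cell
#' @param kappa motive-force magnitude (g um/s^2)
#' @param psi cone half-angle (degrees)
#' @return list with \code{target} (index or \code{NA}), \code{forceSelf} and
#'   \code{forceTarget}
#' @export
motiveForce <- function(state, i, kappa, psi) {
  stopifnot(psi > 0, psi <= 180, kappa >= 0)
  a <- state@axes[, 1L, i]
  p <- state@positions
  best <- NA_integer_; bestDist <- Inf
  for (j in seq_len(nrow(p))) {
    if (j == i) next
    v <- p[j, ] - p[i, ]
    dist <- sqrt(sum(v^2))
    if (dist < 1e-12) next
    if (sum(a * v) / dist < cos(psi * pi / 180)) next
    # a center inside the cell's own surface is no anchor for a pull
    if (dist <= supportRadius(state@semiAxes[i, ],
                              drop(crossprod(state@axes[, , i], v)))) next
    if (dist < bestDist) { bestDist <- dist; best <- j }
  }
  if (is.na(best))
    return(list(target = NA_integer_, forceSelf = rep(0, 3),
                forceTarget = rep(0, 3)))
  vhat <- (p[best, ] - p[i, ]) / bestDist
  list(target = best, forceSelf = kappa * vhat, forceTarget = -kappa * vhat)
}

#' Normal adhesion force between two cells
#'
#' Adhesion acts through the contact area of the cells enlarged by the factor
#' 1.4 (cells grab onto each other before their surfaces touch).  With
#' enlarged overlap \eqn{d_0} and radii \eqn{d_i, d_j}:
#' \eqn{F_a = \alpha \zeta \hat v_{ij}} while \eqn{0 < d_0 \le 0.1(d_i+d_j)},
#' ramps down quadratically to zero between \eqn{0.1(d_i+d_j)} and
#' \eqn{0.3(d_i+d_j)}, and vanishes beyond.  \eqn{\bar\zeta} in the ramp is
#' the contact area at \eqn{d_0 = 0.1(d_i+d_j)}.
#'
#' @param rec an overlap record from [overlapRecord()] (plain, non-enlarged)
#' @param alpha adhesion strength (g um/s^2)
#' @param enlarge radius enlargement factor
#' @return the attractive force vector on cell \code{i} (cell \code{j}
#'   receives the opposite)
#' @export
adhesionForce <- function(rec, alpha = 0.1, enlarge = 1.4) {
  dI <- enlarge * rec$dI
  dJ <- enlarge * rec$dJ
  sm <- dI + dJ
  d0 <- max(0, sm - rec$dist)
  if (d0 <= 0 || d0 >= 0.3 * sm) return(rep(0, 3))
  if (d0 <= 0.1 * sm) {
    mag <- alpha * intersectionArea(dI, dJ, rec$dist)
  } else {
    zbar <- intersectionArea(dI, dJ, 0.9 * sm)
    mag <- alpha * ((0.3 * sm - d0) / (0.2 * sm))^2 * zbar
  }
  mag * rec$vhat
}

#' Confining boundary force
#'
#' Piecewise-linear inward restoring force of the channel walls at 0 and
#' \code{boxWidth} in x and z; the y direction is unconfined.  The magnitude
#' saturates at \eqn{r\rho} outside the channel.
#'
#' @param position cell center (um)
#' @param rho boundary stiffness (g/s^2)
#' @param boxWidth channel width (um)
#' @param r cell radius used by the force (um)
#' @return force vector (g um/s^2)
#' @examples
#' boundaryForce(c(2, 0, 17.5))   # 30 inward along +x
#' @export
boundaryForce <- function(position, rho = 10, boxWidth = 35, r = 5) {
  cpp_boundary_force(as.numeric(position), rho, boxWidth, r)
}

#' Nucleus repulsion force
#'
#' Cells stiffen steeply as their centers approach: for center distance
#' \eqn{\|v\| < 4} um (the nucleus diameter) the repulsion magnitude is
#' \eqn{10(e^{3(1/\|v\| - 1/4)} - 1)}, applied along \eqn{-\hat v_{ij}} on
#' cell \code{i} and symmetrically on \code{j}.  The magnitude is capped at
#' its value at 0.5 um to avoid overflow.
#'
#' @param rec an overlap record from [overlapRecord()]
#' @return the force vector on cell \code{i}
#' @export
nucleusForce <- function(rec) {
  -cpp_nucleus_magnitude(rec$dist) * rec$vhat
}

#' Rheological force pair from an overlapping cell pair
#'
#' The restoring axis forces of each deformed cell are projected onto the
#' line of centers: the push on cell \code{i} derives from the fitted
#' deformation of cell \code{j} and vice versa, with equal-and-opposite
#' reactions, plus the symmetric nucleus term when the centers are closer
#' than the nucleus diameter.  Rheological forces repel: a pair whose
#' projected axis forces net to a pull (possible when volume-conserving
#' expansions dominate an oblique contact) transmits no overlap force.
#'
#' @param state a [SlugState-class]
#' @param rec overlap record for the pair
#' @param fitI,fitJ results of [fitDeformedRadii()] for the two cells
#' @param kParI,kSerI,kParJ,kSerJ spring constants of the two cells
#' @return list with \code{forceI} and \code{forceJ} (world frame); the two
#'   sum to zero
#' @export
rheologicalPairForces <- function(state, rec, fitI, fitJ,
                                  kParI = rep(100, 3), kSerI = rep(100, 3),
                                  kParJ = rep(100, 3), kSerJ = rep(100, 3)) {
  i <- rec$i; j <- rec$j
  fI <- overlapForce(fitI$semiAxes, state@semiAxes[i, ], kParI, kSerI)
  fJ <- overlapForce(fitJ$semiAxes, state@semiAxes[j, ], kParJ, kSerJ)
  mI <- max(0, sum(fI * abs(drop(crossprod(state@axes[, , i], rec$vhat)))))
  mJ <- max(0, sum(fJ * abs(drop(crossprod(state@axes[, , j], rec$vhat)))))
  nuc <- nucleusForce(rec)
  list(forceI = -(mI + mJ) * rec$vhat + nuc,
       forceJ = (mI + mJ) * rec$vhat - nuc)
}

#' Cell-cell drag (mass) matrix
#'
#' The overdamped force balance is \eqn{M(p) p' = F(p)} with 3x3 blocks
#' \eqn{M_{ii} = (\chi_{ii}\mu_f + \sum_k \chi_{ik}\mu_{cell}) I} and
#' \eqn{M_{ij} = -\chi_{ij}\mu_{cell} I}, where \eqn{\chi_{ij} =
#' \zeta_{ij}/(4\cdot 5^2 \pi)} is the cell-cell contact area normalized by
#' the sphere surface and \eqn{\chi_{ii} = \max(0, 1 - \sum \chi_{ij})} the
#' remaining fluid contact.  A ridge of \eqn{10^{-9}\mu_f} keeps the matrix
#' positive definite.
#'
#' @param state a [SlugState-class]
#' @param config a [RunConfig-class] (provides \code{muF} and the cell-cell
#'   drag factor)
#' @return the dense 3n x 3n drag matrix
#' @export
dragMatrix <- function(state, config = runConfig()) {
  ev <- cpp_assemble_forces(state@positions, as.numeric(state@axes),
                            state@semiAxes, .paramList(state, config))
  kronecker(ev$drag, diag(3))
}

#' Assemble all forces acting on the population
#'
#' Evaluates every force term for the current configuration (with shapes as
#' given) and returns the per-cell breakdown together with the total and the
#' scalar core of the drag matrix.
#'
#' @param state a [SlugState-class]
#' @param config a [RunConfig-class]
#' @return list of n x 3 matrices \code{total}, \code{motive},
#'   \code{motiveReaction}, \code{adhesion}, \code{boundaryX},
#'   \code{boundaryZ}, \code{overlap}, \code{overlapReaction},
#'   \code{nucleus}; the n x n scalar \code{drag} matrix (each 3x3 block of
#'   the full matrix is the scalar times identity); the pairwise
#'   \code{records} table; and the \code{fitted} semi-axes used for the
#'   overlap forces
#' @export
assembleForces <- function(state, config = runConfig()) {
  stopifnot(is(state, "SlugState"))
  out <- cpp_assemble_forces(state@positions, as.numeric(state@axes),
                             state@semiAxes, .paramList(state, config))
  if (any(!is.finite(out$total)))
    stop("non-finite force encountered for cell(s) ",
         paste(which(rowSums(!is.finite(out$total)) > 0), collapse = ", "))
  out
}
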