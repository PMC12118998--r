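#' Preconfigured experiment presets
#'
#' Returns a full [RunConfig-class] for the study's experiment grid, deviating
#' from the defaults only where the condition requires:
#' \describe{
#'   \item{\code{"baseline"}}{no differentiation: both types
#'     \eqn{\kappa = 0.01}, \eqn{\psi = 90}.  No sorting is expected.}
#'   \item{\code{"force-sweep"}}{differential force only: prestalk
#'     \eqn{\kappa} = \code{kappaPrestalk} (default 0.4) with both cones at
#'     90 degrees; prespore \eqn{\kappa = 0.01}.}
#'   \item{\code{"cone-sweep"}}{differential directionality only: both types
#'     share \eqn{\kappa} = \code{kappaBoth} (default 0.4); prestalk cone
#'     \code{psiPrestalk} (default 30) versus 90 for prespore.}
#'   \item{\code{"combined"}}{differential force and cone (the defaults):
#'     prestalk \eqn{\kappa = 0.4, \psi = 30}; prespore
#'     \eqn{\kappa = 0.01, \psi = 90}.}
#'   \item{\code{"stiffness"}}{combined, with all prespore spring and dashpot
#'     constants scaled by \code{factor} (2 = stiffer, 0.5 = softer).}
#'   \item{\code{"axis-stiffness"}}{combined, with anisotropic prestalk
#'     mechanics: \code{which = "a-stiff"} doubles the a-axis constants,
#'     \code{which = "bc-soft"} halves the b and c axes.}
#'   \item{\code{"elongated"}}{combined, with an elongated prestalk rest
#'     shape: a-axis 1.25 times the 5 um sphere and the other axes divided
#'     by 1.25 to keep the volume (semi-axes 6.25, 4, 4 um).}
#' }
#'
#' @param name preset name
#' @param kappaPrestalk prestalk motive force for \code{"force-sweep"}
#' @param kappaBoth shared motive force for \code{"cone-sweep"}
#' @param psiPrestalk prestalk cone angle for \code{"cone-sweep"}
#' @param factor prespore stiffness factor for \code{"stiffness"}
#' @param which axis variant for \code{"axis-stiffness"}
#' @param ... further arguments passed to [runConfig()] (e.g.
#'   \code{totalTime}, \code{nRealizations})
#' @return a [RunConfig-class]
#' @examples
#' experimentPreset("baseline", totalTime = 10)
#' experimentPreset("stiffness", factor = 2)
#' @export
experimentPreset <- function(name = c("baseline", "force-sweep", "cone-sweep",
                                      "combined", "stiffness",
                                      "axis-stiffness", "elongated"),
                             kappaPrestalk = 0.4, kappaBoth = 0.4,
                             psiPrestalk = 30, factor = 2,
                             which = c("a-stiff", "bc-soft"), ...) {
  if (is.character(name) && length(name) == 1L &&
      !name %in% eval(formals(experimentPreset)$name))
    stop("unknown preset '", name, "'; available: ",
         paste(eval(formals(experimentPreset)$name), collapse = ", "))
  name <- match.arg(name)
  scaleMech <- function(p, f, axes = 1:3) {
    p@kPar[axes] <- p@kPar[axes] * f
    p@kSer[axes] <- p@kSer[axes] * f
    p@muDash[axes] <- p@muDash[axes] * f
    p
  }
  switch(name,
    "baseline" = runConfig(
      prestalk = cellTypeParams(kappa = 0.01, psi = 90),
      prespore = cellTypeParams(kappa = 0.01, psi = 90), ...),
    "force-sweep" = runConfig(
      prestalk = cellTypeParams(kappa = kappaPrestalk, psi = 90),
      prespore = cellTypeParams(kappa = 0.01, psi = 90), ...),
    "cone-sweep" = runConfig(
      prestalk = cellTypeParams(kappa = kappaBoth, psi = psiPrestalk),
      prespore = cellTypeParams(kappa = kappaBoth, psi = 90), ...),
    "combined" = runConfig(...),
    "stiffness" = runConfig(
      prespore = scaleMech(cellTypeParams(kappa = 0.01, psi = 90), factor),
      ...),
    "axis-stiffness" = {
      which <- match.arg(which)
      pst <- cellTypeParams(kappa = 0.4, psi = 30)
      pst <- if (which == "a-stiff") scaleMech(pst, 2, 1L)
             else scaleMech(pst, 0.5, 2:3)
      runConfig(prestalk = pst, ...)
    },
    "elongated" = runConfig(
      prestalk = cellTypeParams(kappa = 0.4, psi = psiPrestalk,
                                restAxes = c(6.25, 4, 4)), ...))
}
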