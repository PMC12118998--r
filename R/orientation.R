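#' Sample a chemoattractant direction in the gamma cone
#'
#' Draws a unit vector uniformly over the spherical cap of half-angle
#' \code{gamma} about the +y axis (the fixed chemoattractant bias).  A small
#' \code{gamma} means little random fluctuation in the perceived signal.
#' Uses R's RNG stream, so sequences are reproducible under
#' \code{\link{set.seed}}.
#'
#' @param gamma cone half-angle (degrees), in [0, 90)
#' @return a unit 3-vector
#' @examples
#' set.seed(1)
#' sampleDirection(15)
#' sampleDirection(0)   # exactly (0, 1, 0)
#' @export
sampleDirection <- function(gamma = 15) {
  stopifnot(gamma >= 0, gamma < 90)
  cpp_sample_direction(gamma)
}

#' Rotate a cell's frame towards the stimulus direction
#'
#' Rotates the whole orthonormal triad about the axis \eqn{a \times d} by
#' \code{min(increment, angle(a, d))} so the polarization axis \strong{a}
#' approaches the stimulus \strong{d} without overshooting.  Anti-parallel
#' vectors trigger a front-to-back exchange: \strong{a} is flipped in a
#' single step (handedness preserved).
#'
#' @param axes 3 x 3 orthonormal frame (columns a, b, c)
#' @param d stimulus direction (normalized internally)
#' @param increment rotation increment (degrees), > 0
#' @return the rotated 3 x 3 frame
#' @examples
#' R <- diag(3)                      # a along x
#' rotateToward(R, c(0, 1, 0), 5)    # 5 degrees towards +y
#' @export
rotateToward <- function(axes, d, increment = 5) {
  stopifnot(increment > 0, length(d) == 3L,
            all(dim(axes) == c(3L, 3L)))
  if (sqrt(sum(d^2)) < 1e-12)
    stop("zero stimulus direction")
  cpp_rotate_toward(axes, as.numeric(d), increment)
}
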