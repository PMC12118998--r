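#' Membrane-pressure coupling of the three cell axes
#'
#' Each axis deformation obeys the standard-linear-solid equation
#' \deqn{u_i' = \frac{\bar k_i/\mu_i\,(f_i + \lambda - k_i u_i) + df_i/dt}
#'              {k_i + \bar k_i}}
#' and the pressure-like variable \eqn{\lambda} couples the axes so that the
#' cell volume (equivalently the product of the semi-axes) is conserved.
#' Since each \eqn{u_i'} is affine in \eqn{\lambda}, the volume-rate equation
#' is scalar and linear; this returns its solution.
#'
#' @param u axis deformations from rest (um)
#' @param f applied axis forces (g um/s^2)
#' @param kPar,kSer spring constants (g/s^2)
#' @param muDash dashpot coefficients (g/s)
#' @param restAxes rest semi-axes (um)
#' @return the pressure value \eqn{\lambda} (g um/s^2)
#' @examples
#' solvePressure(rep(0, 3), rep(0, 3))   # rest state: 0
#' @export
solvePressure <- function(u, f, kPar = rep(100, 3), kSer = rep(100, 3),
                          muDash = rep(160, 3), restAxes = rep(5, 3)) {
  stopifnot(length(u) == 3L, length(f) == 3L)
  cpp_solve_lambda(as.numeric(u), as.numeric(f), as.numeric(kPar),
                   as.numeric(kSer), as.numeric(muDash),
                   as.numeric(restAxes))
}

#' Advance the axis deformations over one time step
#'
#' Performs an exact exponential update of the affine axis ODE at fixed
#' applied force.  A force step at the start of the interval (\code{fJump})
#' is realized as the instantaneous elastic jump \eqn{\Delta u = \Delta f /
#' (k + \bar k)} of the standard linear solid.  With
#' \code{lambda = "volume"} the pressure is projected each step so the
#' discrete update conserves the product of the semi-axes exactly;
#' \code{lambda = "zero"} decouples the axes (useful for closed-form
#' comparisons).
#'
#' @inheritParams solvePressure
#' @param dt time step (s)
#' @param fJump instantaneous force step applied at the start (g um/s^2)
#' @param lambda pressure handling, \code{"volume"} or \code{"zero"}
#' @return list with the new \code{u} and the \code{lambda} used
#' @examples
#' # creep towards f/k under constant force with decoupled axes
#' st <- stepAxes(rep(0, 3), c(10, 0, 0), dt = 0.5, lambda = "zero")
#' @export
stepAxes <- function(u, f, dt, kPar = rep(100, 3), kSer = rep(100, 3),
                     muDash = rep(160, 3), restAxes = rep(5, 3),
                     lambda = c("volume", "zero"), fJump = rep(0, 3)) {
  stopifnot(dt > 0)
  lambda <- match.arg(lambda)
  cpp_step_axes(as.numeric(u), as.numeric(f), as.numeric(kPar),
                as.numeric(kSer), as.numeric(muDash), as.numeric(restAxes),
                dt, if (lambda == "volume") 1L else 0L, as.numeric(fJump))
}

#' Overlap restoring force along the cell axes
#'
#' The force exerted by the instantaneous deformation of a standard linear
#' solid: \eqn{f_i = -(k_i + \bar k_i)(s_i^{new} - s_i)} per axis, in the
#' cell's body frame.
#'
#' @param newAxes fitted semi-axes (um)
#' @param currentAxes current semi-axes (um)
#' @param kPar,kSer spring constants (g/s^2)
#' @return three axis forces (g um/s^2)
#' @examples
#' overlapForce(c(4, 5.59, 5.59), c(5, 5, 5))
#' @export
overlapForce <- function(newAxes, currentAxes, kPar = rep(100, 3),
                         kSer = rep(100, 3)) {
  -(kPar + kSer) * (as.numeric(newAxes) - as.numeric(currentAxes))
}

#' Relax the cell shape towards its stress-free state
#'
#' Evolves the axes with zero applied force and the volume-conserving
#' pressure over \code{nSteps} steps of length \code{dt}; the unique stable
#' steady state is the rest shape (up to the conserved volume).
#'
#' @inheritParams stepAxes
#' @param nSteps number of relaxation steps
#' @return the relaxed deformation vector
#' @export
relaxShape <- function(u, dt, nSteps = 1L, kPar = rep(100, 3),
                       kSer = rep(100, 3), muDash = rep(160, 3),
                       restAxes = rep(5, 3), lambda = c("volume", "zero")) {
  lambda <- match.arg(lambda)
  mode <- if (lambda == "volume") 1L else 0L
  u <- as.numeric(u)
  for (s in seq_len(nSteps))
    u <- cpp_step_axes(u, rep(0, 3), as.numeric(kPar), as.numeric(kSer),
                       as.numeric(muDash), as.numeric(restAxes), dt, mode,
                       rep(0, 3))$u
  u
}
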