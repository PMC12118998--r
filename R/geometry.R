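#' Center-to-surface distance of an ellipsoid along a direction
#'
#' For semi-axes \eqn{(s_1,s_2,s_3)} and a unit direction \eqn{u} in the body
#' frame, the point \eqn{r u} lies on the ellipsoid surface at
#' \eqn{r = [\sum_k (u_k/s_k)^2]^{-1/2}}.
#'
#' @param semiAxes three positive semi-axes (um)
#' @param direction direction in the body frame (normalized internally)
#' @return the support distance (um)
#' @examples
#' supportRadius(c(5, 5, 5), c(1, 0, 0))   # sphere: 5
#' supportRadius(c(6.25, 4, 4), c(1, 1, 0))
#' @export
supportRadius <- function(semiAxes, direction) {
  stopifnot(length(semiAxes) == 3L, all(semiAxes > 0),
            length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12)
    stop("zero direction vector")
  cpp_support_radius(as.numeric(semiAxes), as.numeric(direction) / nrm)
}

#' Pairwise overlap measurement between two cells
#'
#' Computes the displacement between the cell centers, the center-to-boundary
#' support distances of both ellipsoids along the line of centers, and the
#' overlap distance \eqn{d_0 = \max(0, d_i + d_j - \|v_{ij}\|)}.
#'
#' Coincident centers (below 1e-9 um) are treated as deep overlap along a
#' random direction and flagged \code{degenerate}.
#'
#' @param state a [SlugState-class]
#' @param i,j distinct cell indices
#' @return a list with \code{i}, \code{j}, \code{vhat} (unit vector from i to
#'   j), \code{dist}, \code{dI}, \code{dJ}, \code{d0} and \code{degenerate}
#' @export
overlapRecord <- function(state, i, j) {
  stopifnot(is(state, "SlugState"), i != j)
  rec <- cpp_overlap_record(state@positions[i, ], state@axes[, , i],
                            state@semiAxes[i, ], state@positions[j, ],
                            state@axes[, , j], state@semiAxes[j, ])
  c(list(i = i, j = j), rec)
}

#' Area of the circle of intersection of two spheres
#'
#' Used as the cell-cell contact area: the cells are treated as spheres with
#' radii equal to their support distances along the line of centers.  Returns
#' zero for disjoint or internally contained spheres and caps near-coincident
#' centers at the smaller great-circle area.
#'
#' @param dI,dJ sphere radii (um)
#' @param dist center distance (um)
#' @return contact area (um^2)
#' @examples
#' intersectionArea(5, 5, 8)    # 9 * pi
#' intersectionArea(5, 5, 10)   # tangent: 0
#' @export
intersectionArea <- function(dI, dJ, dist) {
  stopifnot(dI > 0, dJ > 0, dist > 0)
  cpp_lens_area(dI, dJ, dist)
}

#' Fit deformed semi-axes against boundary target points
#'
#' Given target center-to-boundary distances along body-frame directions
#' (one per overlapping neighbour), finds new semi-axes for the cell:
#' \describe{
#'   \item{single neighbour}{volume-conserving solve minimizing the sum of
#'     the semi-axes (the system is underdetermined);}
#'   \item{two neighbours}{exact solve of the two boundary constraints plus
#'     the volume constraint;}
#'   \item{three or more}{bounded nonlinear least squares through all target
#'     points with a mild volume residual.}
#' }
#' Results are clamped to rest +/- 1 um per axis (the admissible deformation
#' band; [4, 6] um for the default 5 um rest sphere).
#'
#' @param semiAxes current semi-axes (um)
#' @param directions m x 3 matrix of unit directions in the body frame
#' @param dTargets m target boundary distances (um)
#' @param restAxes rest semi-axes defining volume and bounds (um)
#' @return list with \code{semiAxes}, \code{residual} (sum of squared point
#'   misfits, um^2), \code{case} (\code{"none"}, \code{"single"},
#'   \code{"double"}, \code{"multi"}) and \code{converged}
#' @examples
#' # one neighbour compressing the x axis by 1 um
#' fitDeformedRadii(c(5, 5, 5), matrix(c(1, 0, 0), 1), 4)
#' @export
fitDeformedRadii <- function(semiAxes, directions, dTargets,
                             restAxes = c(5, 5, 5)) {
  directions <- matrix(directions, ncol = 3L)
  stopifnot(nrow(directions) == length(dTargets), all(semiAxes > 0))
  if (length(dTargets) == 0L)
    return(list(semiAxes = as.numeric(semiAxes), residual = 0,
                case = "none", converged = TRUE))
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  cpp_fit_radii(as.numeric(semiAxes), directions, as.numeric(dTargets),
                as.numeric(restAxes) - 1, as.numeric(restAxes) + 1,
                prod(restAxes))
}

#' Boundary target distances for a cell's overlap records
#'
#' Converts overlap records into the per-neighbour fitting targets: the new
#' boundary meets the midpoint of the overlap segment,
#' \eqn{d_{new} = d_i - d_0/2}; with a single deeply-overlapping neighbour
#' whose boundary has passed the cell center (\eqn{d_0 \ge \|v\|}) the target
#' is \eqn{\|v\| - 0.7 d_j} instead.
#'
#' @param state a [SlugState-class]
#' @param i cell index
#' @param records list of overlap records involving cell \code{i} (from
#'   [overlapRecord()]); only records with \code{d0 > 0} are used
#' @return list with \code{directions} (m x 3, body frame) and
#'   \code{dTargets}
#' @export
shapeTargets <- function(state, i, records) {
  records <- Filter(function(r) r$d0 > 0, records)
  m <- length(records)
  dirs <- matrix(0, m, 3L)
  d <- numeric(m)
  R <- state@axes[, , i]
  for (q in seq_len(m)) {
    r <- records[[q]]
    if (r$i == i) {
      vh <- r$vhat; dSelf <- r$dI; dOther <- r$dJ
    } else if (r$j == i) {
      vh <- -r$vhat; dSelf <- r$dJ; dOther <- r$dI
    } else stop("record does not involve cell ", i)
    dirs[q, ] <- drop(crossprod(R, vh))
    d[q] <- if (m == 1L && r$d0 >= r$dist) r$dist - 0.7 * dOther
            else dSelf - r$d0 / 2
    d[q] <- max(0.5, d[q])
  }
  list(directions = dirs, dTargets = d)
}
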