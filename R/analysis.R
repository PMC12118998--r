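#' Relative anterior-posterior position of the prestalk cells
#'
#' The sorting metric: with \eqn{y_1} the minimum and \eqn{y_2} the maximum
#' y coordinate over all cells and \eqn{y_0} the mean y coordinate of the
#' prestalk cells, the relative position is \eqn{(y_0 - y_1)/(y_2 - y_1)};
#' 0 means fully posterior, 1 fully anterior.  Invariant under uniform
#' translation and rescaling of y.
#'
#' @param x a [SlugState-class] or [Trajectory-class]
#' @param ... unused
#' @return a scalar (SlugState) or the per-frame series (Trajectory)
#' @export
setGeneric("relativePosition",
           function(x, ...) standardGeneric("relativePosition"))

#' @rdname relativePosition
#' @export
setMethod("relativePosition", "SlugState", function(x, ...) {
  y <- x@positions[, 2L]
  isPst <- x@type == "prestalk"
  if (!any(isPst)) stop("no prestalk cells in the state")
  if (diff(range(y)) < 1e-12)
    stop("degenerate flat slug: all cells share one y coordinate")
  (mean(y[isPst]) - min(y)) / (max(y) - min(y))
})

#' @rdname relativePosition
#' @export
setMethod("relativePosition", "Trajectory", function(x, ...) x@relPos)

#' Coerce a trajectory to a long-format data frame
#'
#' One row per cell per stored frame with time, cell id, type, center
#' coordinates, semi-axes and polarization-axis components.
#'
#' @param x a [Trajectory-class]
#' @param row.names,optional,... passed for S3 compatibility, unused
#' @return a data.frame with \code{nCells * nFrames} rows
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  n <- nCells(x)
  nf <- length(x@times)
  if (nf == 0L || length(dim(x@positions)) != 3L || dim(x@positions)[3L] == 0L)
    stop("trajectory has no stored frames (was it run with recordFrames?)")
  data.frame(
    time = rep(x@times, each = n),
    cell = rep(seq_len(n), nf),
    type = rep(x@type, nf),
    x = as.vector(x@positions[, 1L, ]),
    y = as.vector(x@positions[, 2L, ]),
    z = as.vector(x@positions[, 3L, ]),
    semiA = as.vector(x@semiAxes[, 1L, ]),
    semiB = as.vector(x@semiAxes[, 2L, ]),
    semiC = as.vector(x@semiAxes[, 3L, ]),
    aX = as.vector(x@aAxis[, 1L, ]),
    aY = as.vector(x@aAxis[, 2L, ]),
    aZ = as.vector(x@aAxis[, 3L, ]))
}

#' Write a trajectory to CSV
#'
#' Long-format table (see [as.data.frame.Trajectory()]); round-trips
#' losslessly through [readTrajectory()].
#'
#' @param traj a [Trajectory-class] with stored frames
#' @param path output file path
#' @return the path, invisibly
#' @export
exportTrajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table written by [exportTrajectory()]
#'
#' @param path CSV file path
#' @return the long-format data.frame
#' @export
readTrajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an ensemble metric series to CSV
#'
#' Columns: time, ensemble mean, ensemble SD and one column per seed.
#'
#' @param ms a [MetricsSeries-class]
#' @param path output file path
#' @return the path, invisibly
#' @export
exportMetrics <- function(ms, path) {
  df <- data.frame(time = ms@times, mean = ms@mean, sd = ms@sd)
  vals <- ms@values
  colnames(vals) <- paste0("seed", ms@seeds)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE)
  invisible(path)
}

#' Fit a linear trend to the ensemble-mean sorting curve
#'
#' Ordinary least-squares slope of the ensemble mean against time, with its
#' confidence interval -- the summary used to decide whether a condition
#' sorts (slope CI above zero) or not (CI straddling zero).
#'
#' @param ms a [MetricsSeries-class]
#' @param level confidence level
#' @return list with \code{slope} (per second) and \code{ci} (2-vector)
#' @export
sortingTrend <- function(ms, level = 0.95) {
  fit <- stats::lm(m ~ t, data = data.frame(t = ms@times, m = ms@mean))
  list(slope = unname(stats::coef(fit)[2L]),
       ci = unname(stats::confint(fit, "t", level = level)[1L, ]))
}

#' Time for the ensemble mean to gain a given amount
#'
#' First recorded time at which the ensemble mean exceeds its initial value
#' plus \code{gain}; \code{Inf} when the gain is never reached (no sorting).
#'
#' @param ms a [MetricsSeries-class]
#' @param gain required increase in relative position
#' @return time (s) or \code{Inf}
#' @export
timeToGain <- function(ms, gain = 0.2) {
  idx <- which(ms@mean >= ms@mean[1L] + gain)
  if (length(idx) == 0L) Inf else ms@times[min(idx)]
}

#' Plot an ensemble sorting curve
#'
#' Mean relative position against time with a +/- 1 SD shaded band.
#'
#' @param ms a [MetricsSeries-class]
#' @return a ggplot object
#' @export
plotSorting <- function(ms) {
  df <- data.frame(time = ms@times, mean = ms@mean,
                   lo = pmax(0, ms@mean - ms@sd),
                   hi = pmin(1, ms@mean + ms@sd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "relative position") +
    ggplot2::theme_minimal()
}
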