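#' Guide spiral: the Archimedean template drawn on the app screen
#'
#' The guide is the polar curve r = -theta over 0 <= theta <= 7*pi (three and
#' a half turns). The minus sign places the start direction on the negative
#' x axis: rendered Cartesian points are
#' \deqn{(x, y) = (-s\,\theta\cos\theta,\; -s\,\theta\sin\theta) + c}
#' with screen scale s (cm per radian) and centre c. The scale is solved
#' numerically so that the maximum axis-aligned extent of the dense curve --
#' the on-screen "longitudinal diameter" -- is exactly \code{diameter} cm
#' (4 cm by default, matching the app).
#'
#' @param diameter target maximum axis-aligned extent in cm.
#' @param center numeric length-2, spiral centre in cm.
#' @param theta_end final angle in radians (default \code{7*pi}).
#' @return an object of class \code{guide_spiral} with fields \code{scale}
#'   (cm/rad), \code{theta_end}, \code{center}, \code{diameter}.
#' @export
guide_spiral <- function(diameter = 4, center = c(0, 0), theta_end = 7 * pi) {
  stopifnot(diameter > 0, length(center) == 2, theta_end > 0)
  ext <- spiral_unit_extent(theta_end)
  structure(list(scale = diameter / ext, theta_end = theta_end,
                 center = as.numeric(center), diameter = diameter),
            class = "guide_spiral")
}

# max axis-aligned extent of the unit-scale curve (-t cos t, -t sin t),
# t in [0, theta_end]: locate all derivative sign changes on a fine grid and
# polish each with uniroot, then take the larger of the x and y extents.
spiral_unit_extent <- function(theta_end) {
  axis_extent <- function(f, fp) {
    grid <- seq(0, theta_end, length.out = 20000L)
    v <- fp(grid)
    br <- which(v[-1] * v[-length(v)] < 0)
    roots <- vapply(br, function(i)
      stats::uniroot(fp, c(grid[i], grid[i + 1]), tol = 1e-14)$root, 0)
    cand <- f(c(0, theta_end, roots))
    max(cand) - min(cand)
  }
  ex <- axis_extent(function(t) -t * cos(t),
                    function(t) -cos(t) + t * sin(t))
  ey <- axis_extent(function(t) -t * sin(t),
                    function(t) -sin(t) - t * cos(t))
  max(ex, ey)
}

#' Cartesian point(s) on a guide spiral
#' @param guide a \code{guide_spiral}.
#' @param theta radians in \code{[0, theta_end]}.
#' @return data.frame with columns \code{theta, x, y, r}.
#' @export
spiral_point <- function(guide, theta) {
  data.frame(theta = theta,
             x = -guide$scale * theta * cos(theta) + guide$center[1],
             y = -guide$scale * theta * sin(theta) + guide$center[2],
             r = guide$scale * theta)
}

#' Sample the guide spiral densely
#'
#' @param n_points number of evenly spaced theta values on
#'   \code{[0, theta_end]}; must be at least 2.
#' @inheritParams spiral_point
#' @return data.frame \code{theta, x, y, r} of \code{n_points} rows.
#' @export
generate_guide_spiral <- function(guide = guide_spiral(), n_points = 10000L) {
  if (n_points < 2L) stop("n_points must be at least 2")
  spiral_point(guide, seq(0, guide$theta_end, length.out = n_points))
}

#' @export
print.guide_spiral <- function(x, ...) {
  cat(sprintf("<guide_spiral> r = scale*theta, theta in [0, %.4g] rad, scale %.6f cm/rad, extent %g cm\n",
              x$theta_end, x$scale, x$diameter))
  invisible(x)
}

#' Transform a Cartesian trace to unwrapped polar coordinates
#'
#' Radius is the Euclidean distance to \code{center}. The angle is
#' turn-accumulating: successive angular increments are taken in
#' \code{(-pi, pi]} and summed, so a trace winding three and a half times
#' spans 7*pi rather than folding at 2*pi. The origin of theta is anchored at
#' the guide spiral's start direction (the negative x axis), i.e. theta is
#' the unwrapped position angle minus pi, so the guide itself maps to theta
#' spanning \code{[0, 7*pi]}. Samples at the exact centre (zero radius) adopt
#' the angle of the nearest following off-centre sample; a single-point trace
#' gets theta = 0 by convention.
#'
#' @param trace data.frame or matrix with columns/cols \code{x}, \code{y} (cm).
#' @param center numeric length-2 (cm).
#' @return object of class \code{polar_trace}: list with numeric vectors
#'   \code{theta} (unwrapped radians) and \code{r} (cm).
#' @export
to_polar <- function(trace, center = c(0, 0)) {
  if (is.matrix(trace)) trace <- as.data.frame(trace)
  stopifnot(nrow(trace) >= 1L, all(c("x", "y") %in% colnames(trace)))
  dx <- trace$x - center[1]
  dy <- trace$y - center[2]
  r <- sqrt(dx^2 + dy^2)
  n <- length(r)
  phi <- atan2(dy, dx)              # undefined where r == 0
  ok <- r > 0
  if (!any(ok)) {
    out <- list(theta = numeric(n), r = r)
    class(out) <- "polar_trace"
    return(out)
  }
  # centre samples inherit the angle of the nearest following valid sample
  # (or preceding, for trailing centre samples)
  idx <- seq_len(n)
  nxt <- rev(cummin(rev(ifelse(ok, idx, n + 1L))))
  prv <- cummax(ifelse(ok, idx, 0L))
  use <- ifelse(nxt <= n, nxt, prv)
  phi <- phi[use]
  dphi <- diff(phi)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))   # wrap increments to (-pi, pi]
  theta0 <- phi[1] - pi                            # anchor: guide start = -x axis
  theta0 <- theta0 - 2 * pi * floor((theta0 + pi) / (2 * pi))  # into (-pi, pi]
  theta <- theta0 + c(0, cumsum(dphi))
  structure(list(theta = theta, r = r), class = "polar_trace")
}

#' @export
print.polar_trace <- function(x, ...) {
  cat(sprintf("<polar_trace> %d samples, theta in [%.3f, %.3f] rad\n",
              length(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Spiral tracing error: RMSE between a drawn trace and the guide spiral
#'
#' In unwrapped polar coordinates the guide spiral is the line
#' \code{r = scale * theta}; the tracing error of a drawn sample is its radial
#' residual at its own theta. The RMSE is taken over samples with
#' \code{theta > exclusion} and \code{theta <= theta_end}: the first turn (up
#' to 2*pi by default) is excluded because start-position noise concentrates
#' there, and overshoot beyond the guide's end is clipped.
#'
#' @param polar a \code{polar_trace} (from \code{\link{to_polar}}).
#' @param guide a \code{guide_spiral}.
#' @param exclusion lower theta bound in radians (strict; default \code{2*pi}).
#' @return RMSE in cm.
#' @export
spiral_rmse <- function(polar, guide, exclusion = 2 * pi) {
  stopifnot(inherits(polar, "polar_trace"), inherits(guide, "guide_spiral"))
  keep <- polar$theta > exclusion & polar$theta <= guide$theta_end
  if (!any(keep))
    stop("drawing too short: no samples beyond the excluded first section")
  res <- polar$r[keep] - guide$scale * polar$theta[keep]
  sqrt(mean(res^2))
}

#' Maximum pen pressure of a recording
#'
#' The maximum of the pressure channel, in device units. Lower maximum
#' pressure is characteristic of the CTS group in the spiral-drawing task.
#'
#' @param rec a \code{drawing_recording}.
#' @return scalar in \code{[0, PRESSURE_MAX]}.
#' @export
max_pressure <- function(rec) {
  if (nrow(rec$samples) == 0L) stop("empty recording")
  max(rec$samples$pressure)
}
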