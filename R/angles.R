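# Angles relative to the chain axis, angle-series statistics, count
# percentages as printed in field reports, and the jet Reynolds number.

#' Unsigned acute angle between a vector and the chain axis
#'
#' All zooid, siphon and jet angles are reported as magnitudes, so the angle
#' is folded into \[0, 90\] degrees: `acos(|v . u| / (|v| |u|))`. Accepts 2D
#' vectors (angles digitized in an image plane) or 3D vectors.
#'
#' @param v Numeric 2- or 3-vector.
#' @param axis_direction Numeric vector of the same length (need not be
#'   unit).
#' @return Angle in degrees, in \[0, 90\].
#' @export
angle_to_axis <- function(v, axis_direction) {
  if (length(v) != length(axis_direction) || !length(v) %in% c(2, 3))
    hk_stop("v and axis_direction must both be 2- or 3-vectors",
            "hk_parameter_error")
  nv <- vnorm(v); nu <- vnorm(axis_direction)
  if (nv < .Machine$double.eps || nu < .Machine$double.eps)
    hk_stop("zero vector has no angle to the axis", "hk_degenerate_input")
  cosang <- min(1, abs(sum(v * axis_direction)) / (nv * nu))
  acos(cosang) * 180 / pi
}

#' Summary statistics of an angle series
#'
#' Max, min, mean and sample SD (n-1 denominator) of the angles, plus the
#' percent decrease `100 * (max - min) / max` describing how far the angle
#' drops over the pulsatile cycle. Full precision is retained; the print
#' method displays the percent decrease to one decimal.
#'
#' @param series An [angle_series()] (or data frame with an `angle` column).
#' @return An `angle_stats` object: list with `max`, `min`, `mean`, `sd`,
#'   `n`, `percent_decrease`.
#' @export
series_stats <- function(series) {
  a <- if (inherits(series, "angle_series")) series$samples$angle
       else as.data.frame(series)$angle
  if (!length(a)) hk_stop("empty angle series", "hk_insufficient_data")
  if (any(a < 0)) hk_stop("angles must be >= 0", "hk_range_error")
  mx <- max(a); mn <- min(a)
  structure(list(max = mx, min = mn, mean = mean(a),
                 sd = if (length(a) > 1) sd(a) else NA_real_, n = length(a),
                 percent_decrease = if (mx > 0) 100 * (mx - mn) / mx else 0),
            class = "angle_stats")
}

#' @export
print.angle_stats <- function(x, ...) {
  cat(sprintf("<angle_stats> n = %d: mean %.1f deg (sd %.1f), range %.1f-%.1f deg, decrease %.1f%%\n",
              x$n, x$mean, x$sd, x$min, x$max,
              round(x$percent_decrease, 1)))
  invisible(x)
}

#' Truncated count percentage
#'
#' `floor(100 * k / n_total)`: percentages of counts are truncated toward
#' zero, not rounded, matching the field convention in which 10 of 15 is
#' printed as 66%.
#'
#' @param k Count of successes (0 <= k <= n_total).
#' @param n_total Total count (> 0).
#' @return Integer percent.
#' @export
percent_of_counts <- function(k, n_total) {
  if (n_total <= 0) hk_stop("n_total must be > 0", "hk_division_error")
  if (k < 0 || k > n_total)
    hk_stop("k must lie in [0, n_total]", "hk_parameter_error")
  as.integer(floor(100 * k / n_total))
}

#' Jet Reynolds number
#'
#' `Re = U * d / nu`, the ratio of inertial to viscous forces for a jet of
#' speed `U` and diameter `d` in water of kinematic viscosity `nu`
#' (seawater: 1.05e-6 m^2/s).
#'
#' @param U Jet speed, m/s (>= 0).
#' @param d Siphon/jet diameter, m (> 0).
#' @param nu Kinematic viscosity, m^2/s (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(U, d, nu = 1.05e-6) {
  if (d <= 0 || nu <= 0) hk_stop("d and nu must be > 0", "hk_parameter_error")
  if (U < 0) hk_stop("U must be >= 0", "hk_parameter_error")
  U * d / nu
}

#' Jet angle from a digitized wake trace
#'
#' Fits the total-least-squares direction through the trace points (a
#' digitized dye/wake centreline) and returns its unsigned acute angle to
#' the chain axis.
#'
#' @param trace A [landmark_track()] with role `jet_trace` (or any object
#'   with samples `x,y,z`).
#' @param axis A `chain_axis`.
#' @return Angle in degrees, in \[0, 90\].
#' @export
jet_angle_from_trace <- function(trace, axis) {
  s <- if (inherits(trace, "landmark_track")) trace$samples else as.data.frame(trace)
  m <- as.matrix(s[, c("x", "y", "z")])
  if (nrow(m) < 2) hk_stop("need >= 2 trace points", "hk_insufficient_data")
  if (max(dist(m)) < 1e-12)
    hk_stop("trace points are coincident", "hk_degenerate_geometry")
  dir <- tls_line(m)$direction
  angle_to_axis(dir, axis$direction)
}
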