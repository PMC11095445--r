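# Spin kinematics: chain axis, rotation phase of an off-axis landmark about
# that axis, angular velocity, handedness, and translational swim speed.

#' Fit the linear chain axis
#'
#' With exactly two zooid-gut positions the axis is the line through them
#' (the field definition: the shortest line between the frontal zooid gut
#' and the adjacent zooid gut); with three or more, the total-least-squares
#' line (first principal direction of the centered points). The direction is
#' oriented toward the colony's net displacement when the tracks span more
#' than one frame; otherwise it points from the rear of the chain toward the
#' frontal zooid. An explicit `orient` vector overrides both.
#'
#' @param zooid_tracks List of >= 2 zooid-gut [landmark_track()] or
#'   `adjusted_trajectory` objects.
#' @param frame Frame number at which to fit the axis.
#' @param orient Optional 3-vector fixing the sign of the direction.
#' @return A `chain_axis`: list with `point` (mm), unit `direction`, and
#'   `rms_residual` (mm).
#' @export
fit_chain_axis <- function(zooid_tracks, frame, orient = NULL) {
  pos_at <- function(tr, fr) {
    s <- if (inherits(tr, "landmark_track")) tr$samples else tr
    i <- match(fr, s$frame)
    if (is.na(i)) return(NULL)
    c(s$x[i], s$y[i], s$z[i])
  }
  pts <- Filter(Negate(is.null), lapply(zooid_tracks, pos_at, fr = frame))
  if (length(pts) < 2)
    hk_stop("need >= 2 zooid positions at the frame", "hk_insufficient_landmarks")
  m <- do.call(rbind, pts)
  if (max(dist(m)) < 1e-9)
    hk_stop("zooid positions are coincident", "hk_degenerate_geometry")
  fit <- tls_line(m)
  dir <- fit$direction
  if (is.null(orient)) {
    # net displacement of the track centroids over their shared span
    disp <- net_displacement(zooid_tracks)
    orient <- if (!is.null(disp) && vnorm(disp) > 1e-9) disp else m[1, ] - m[nrow(m), ]
  }
  if (sum(dir * orient) < 0) dir <- -dir
  structure(list(point = fit$point, direction = dir, rms_residual = fit$rms),
            class = "chain_axis")
}

# net displacement of the centroid of a set of tracks from their first to
# last shared frame; NULL for single-frame data
net_displacement <- function(tracks) {
  mats <- lapply(tracks, function(tr) {
    s <- if (inherits(tr, "landmark_track")) tr$samples else tr
    s
  })
  frames <- Reduce(intersect, lapply(mats, function(s) s$frame))
  if (length(frames) < 2) return(NULL)
  f0 <- min(frames); f1 <- max(frames)
  at <- function(fr) rowMeans(vapply(mats, function(s) {
    i <- match(fr, s$frame); c(s$x[i], s$y[i], s$z[i])
  }, numeric(3)))
  at(f1) - at(f0)
}

#' @export
print.chain_axis <- function(x, ...) {
  cat(sprintf("<chain_axis> point (%.2f, %.2f, %.2f) mm, direction (%.3f, %.3f, %.3f), rms %.3g mm\n",
              x$point[1], x$point[2], x$point[3], x$direction[1],
              x$direction[2], x$direction[3], x$rms_residual))
  invisible(x)
}

#' Rotation phase of an off-axis marker about the chain axis
#'
#' Projects the marker onto the plane normal to the chain axis at each
#' shared frame and returns the unwrapped polar angle over time. The
#' in-plane basis is parallel-transported between frames by the minimal
#' (zero-twist) rotation taking each axis direction to the next, so that
#' wobble of the instantaneous axis does not masquerade as spin. The basis is right-handed about the axis
#' direction (oriented with net displacement), so a positive phase rate is
#' counterclockwise viewed along the swim direction from behind.
#'
#' @param marker `adjusted_trajectory` of the off-axis marker.
#' @param axis Either a fixed `chain_axis`, or a list of >= 2 zooid
#'   `adjusted_trajectory` objects from which the instantaneous axis is
#'   fitted per frame.
#' @param tol Minimum in-plane distance (mm) below which the phase is
#'   undefined.
#' @return A `spin_phase`: data frame with columns `t`, `theta` (rad,
#'   unwrapped) and `r` (in-plane distance, mm); attribute `convention`.
#' @export
phase_angle_series <- function(marker, axis, tol = 1e-6) {
  mm <- traj_matrix(marker)
  if (inherits(axis, "chain_axis")) {
    frames <- marker$frame
    pts <- matrix(axis$point, length(frames), 3, byrow = TRUE)
    dirs <- matrix(axis$direction, length(frames), 3, byrow = TRUE)
    keep <- seq_along(frames)
  } else {
    axis_frames <- Reduce(intersect, lapply(axis, function(a) a$frame))
    frames <- intersect(marker$frame, axis_frames)
    if (length(frames) < 3)
      hk_stop("marker and axis tracks overlap on < 3 frames",
              "hk_alignment_error")
    keep <- match(frames, marker$frame)
    disp <- net_displacement(axis)
    fits <- lapply(frames, function(fr)
      fit_chain_axis(axis, fr, orient = disp))
    pts <- do.call(rbind, lapply(fits, `[[`, "point"))
    dirs <- do.call(rbind, lapply(fits, `[[`, "direction"))
    # continuity of the axis orientation across frames
    for (i in seq_len(nrow(dirs))[-1])
      if (sum(dirs[i, ] * dirs[i - 1, ]) < 0) dirs[i, ] <- -dirs[i, ]
  }
  n <- length(frames)
  t <- marker$t[keep]
  theta <- numeric(n); r <- numeric(n)
  b <- plane_basis(dirs[1, ])
  e1 <- b$e1
  for (i in seq_len(n)) {
    u <- dirs[i, ]
    if (i > 1) {
      # minimal-rotation (zero-twist) transport of e1: rotate by the unique
      # rotation about u_prev x u taking the previous axis direction to the
      # current one
      uprev <- dirs[i - 1, ]
      w <- cross3(uprev, u)
      s2 <- sum(w^2)
      if (s2 > 1e-24) {
        cth <- sum(uprev * u)
        # Rodrigues formula with sin = |w|, cos = cth
        e1 <- e1 * cth + cross3(w, e1) +
          w * (sum(w * e1) * (1 - cth) / s2)
      }
      e1 <- unitv(e1 - sum(e1 * u) * u)
    }
    e2 <- cross3(u, e1)
    d <- mm[keep[i], ] - pts[i, ]
    d <- d - sum(d * u) * u
    r[i] <- vnorm(d)
    if (r[i] < tol)
      hk_stop(sprintf("marker lies on the axis at frame %d (in-plane distance %.2g mm)",
                      frames[i], r[i]), "hk_undefined_phase")
    theta[i] <- atan2(sum(d * e2), sum(d * e1))
  }
  theta <- unwrap_phase(theta)
  structure(data.frame(t = t, theta = theta, r = r),
            class = c("spin_phase", "data.frame"),
            convention = hk_convention())
}

#' Angular velocity and handedness from a phase series
#'
#' Finite differences of the unwrapped phase: `omega_i = (theta_{i+1} -
#' theta_i) / (t_{i+1} - t_i)`. Handedness is CCW when the median angular
#' velocity is positive under the package convention. Sampling must resolve
#' the rotation (|omega| * dt < pi); near-Nyquist phase steps raise an
#' error.
#'
#' @param phase A `spin_phase` (or data frame with `t`, `theta`).
#' @return A `spin_measurement`: list with `phase`, `omega` (data frame of
#'   midpoint `t`, `omega` rad/s), `mean_abs_omega`, `median_omega`,
#'   `handedness` (`"CW"`/`"CCW"`), `convention`.
#' @export
angular_velocity <- function(phase) {
  if (nrow(phase) < 2)
    hk_stop("need >= 2 phase samples", "hk_insufficient_data")
  dth <- diff(phase$theta); dt <- diff(phase$t)
  if (any(dt <= 0)) hk_stop("times must be strictly increasing",
                            "hk_ordering_error")
  if (any(abs(dth) >= pi * 0.98))
    hk_stop("phase step near pi between samples: rotation under-sampled (|omega|*dt must be < pi)",
            "hk_aliasing_error")
  omega <- dth / dt
  med <- median(omega)
  structure(list(phase = phase,
                 omega = data.frame(t = phase$t[-1] - dt / 2, omega = omega),
                 mean_abs_omega = mean(abs(omega)), median_omega = med,
                 handedness = if (med > 0) "CCW" else "CW",
                 convention = attr(phase, "convention") %||% hk_convention()),
            class = "spin_measurement")
}

#' @export
print.spin_measurement <- function(x, ...) {
  cat(sprintf("<spin_measurement> mean |omega| = %.4g rad/s (%.4g deg/s), handedness %s\n",
              x$mean_abs_omega, x$mean_abs_omega * 180 / pi, x$handedness))
  cat("  convention:", x$convention, "\n")
  invisible(x)
}

#' Spin direction of a measured rotation
#'
#' Returns `"CW"` or `"CCW"` under the package convention, or
#' `"indeterminate"` when the median angular velocity is below the
#' significance floor (a result, not an error).
#'
#' @param meas A `spin_measurement` from [angular_velocity()].
#' @param floor Minimum |median omega| (rad/s) to call a direction.
#' @return Character scalar.
#' @export
spin_direction <- function(meas, floor = 0) {
  if (abs(meas$median_omega) <= floor) return("indeterminate")
  meas$handedness
}

#' Translational swim speed
#'
#' `swim_speed` is the mean path speed, total path length over total elapsed
#' time across consecutive samples; `net_speed` is the straight-line
#' net-displacement magnitude over elapsed time.
#'
#' @param traj An `adjusted_trajectory` (or data frame with `t,x,y,z`).
#' @return Speed in mm/s.
#' @export
swim_speed <- function(traj) {
  if (nrow(traj) < 2) hk_stop("need >= 2 samples", "hk_insufficient_data")
  m <- traj_matrix(traj)
  elapsed <- traj$t[nrow(traj)] - traj$t[1]
  if (elapsed <= 0) hk_stop("zero elapsed time", "hk_degenerate_input")
  sum(sqrt(rowSums(diff(m)^2))) / elapsed
}

#' @rdname swim_speed
#' @export
net_speed <- function(traj) {
  if (nrow(traj) < 2) hk_stop("need >= 2 samples", "hk_insufficient_data")
  m <- traj_matrix(traj)
  elapsed <- traj$t[nrow(traj)] - traj$t[1]
  if (elapsed <= 0) hk_stop("zero elapsed time", "hk_degenerate_input")
  vnorm(m[nrow(m), ] - m[1, ]) / elapsed
}
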