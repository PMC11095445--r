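# Background-motion removal by reference-particle subtraction. A passive
# particle (marine snow, radiolarian, foraminiferan) co-tracked near the
# chain carries the same additive water/diver/camera motion as the animal;
# per-frame subtraction yields motion-corrected coordinates.

#' Motion-correct a landmark track
#'
#' Subtracts the reference particle's coordinates from the track's, frame by
#' frame, on the intersection of their frame sets. Frames present in only
#' one of the two are dropped and counted. No temporal smoothing is applied
#' by default; an optional centered moving average of the reference
#' (`smooth_window`, in frames) and optional linear interpolation of the
#' reference onto the track's frames are available and reported when used.
#'
#' @param track A [landmark_track()] (any non-reference role).
#' @param reference A [landmark_track()] with role `reference_particle`, or
#'   an object accepted by `as_reference` (e.g. the all-zero reference used
#'   to express "no correction").
#' @param smooth_window Odd moving-average width in frames; 0 disables.
#' @param interpolate If `TRUE`, linearly interpolate the reference in `t`
#'   onto track frames missing from the reference (default off).
#' @return An `adjusted_trajectory`: a data frame with columns
#'   `frame, t, x, y, z` (mm, motion-corrected) and attributes
#'   `landmark_id`, `reference_id`, `n_dropped`.
#' @export
correct_motion <- function(track, reference, smooth_window = 0,
                           interpolate = FALSE) {
  if (!inherits(track, "landmark_track") ||
      !inherits(reference, "landmark_track"))
    hk_stop("track and reference must be landmark_track objects",
            "hk_parameter_error")
  if (reference$role != "reference_particle")
    hk_stop(sprintf("reference track '%s' has role '%s', not reference_particle",
                    reference$landmark_id, reference$role), "hk_role_error")
  rs <- reference$samples
  if (smooth_window > 0) {
    if (smooth_window %% 2 == 0)
      hk_stop("smooth_window must be odd", "hk_parameter_error")
    k <- rep(1 / smooth_window, smooth_window)
    for (col in c("x", "y", "z")) {
      sm <- stats::filter(rs[[col]], k, sides = 2)
      rs[[col]] <- ifelse(is.na(sm), rs[[col]], as.numeric(sm))
    }
    message(sprintf("reference '%s' smoothed with a %d-frame moving average",
                    reference$landmark_id, smooth_window))
  }
  ts <- track$samples
  if (interpolate) {
    rx <- approx(rs$t, rs$x, xout = ts$t)$y
    ry <- approx(rs$t, rs$y, xout = ts$t)$y
    rz <- approx(rs$t, rs$z, xout = ts$t)$y
    keep <- !is.na(rx)
    out <- data.frame(frame = ts$frame[keep], t = ts$t[keep],
                      x = ts$x[keep] - rx[keep], y = ts$y[keep] - ry[keep],
                      z = ts$z[keep] - rz[keep])
    n_dropped <- sum(!keep)
    message(sprintf("reference '%s' linearly interpolated onto track frames",
                    reference$landmark_id))
  } else {
    shared <- intersect(ts$frame, rs$frame)
    if (!length(shared))
      hk_stop("track and reference share no frames", "hk_alignment_error")
    it <- match(shared, ts$frame); ir <- match(shared, rs$frame)
    out <- data.frame(frame = shared, t = ts$t[it],
                      x = ts$x[it] - rs$x[ir], y = ts$y[it] - rs$y[ir],
                      z = ts$z[it] - rs$z[ir])
    n_dropped <- (nrow(ts) - length(shared)) + (nrow(rs) - length(shared))
  }
  structure(out, class = c("adjusted_trajectory", "data.frame"),
            landmark_id = track$landmark_id,
            reference_id = reference$landmark_id, n_dropped = n_dropped)
}

#' Motion-correct every animal track in a recording
#'
#' @param rec A [colony_recording()] containing one reference-particle track.
#' @param ... Passed to [correct_motion()].
#' @return Named list of `adjusted_trajectory` objects (all non-reference
#'   tracks).
#' @export
correct_recording <- function(rec, ...) {
  ref <- reference_track(rec)
  if (is.null(ref))
    hk_stop("recording has no reference_particle track", "hk_role_error")
  animal <- Filter(function(tr) tr$role != "reference_particle", rec$tracks)
  lapply(animal, correct_motion, reference = ref, ...)
}

#' A zero reference track
#'
#' Convenience constructor for a reference particle fixed at the origin over
#' the given frames; correcting against it leaves coordinates unchanged.
#'
#' @param frames Integer frame numbers.
#' @param frame_rate Frames per second.
#' @return A [landmark_track()] with role `reference_particle`.
#' @export
zero_reference <- function(frames, frame_rate) {
  landmark_track("zero-ref", "reference_particle",
                 data.frame(frame = frames, t = frames / frame_rate,
                            x = 0, y = 0, z = 0))
}

# internal: adjusted_trajectory coordinates as an n x 3 matrix
traj_matrix <- function(traj) as.matrix(traj[, c("x", "y", "z")])

# internal: turn an adjusted trajectory back into a landmark_track (used by
# tests and by re-application of correction)
as_landmark_track <- function(traj, role = "zooid_gut", id = NULL) {
  landmark_track(id %||% attr(traj, "landmark_id") %||% "traj", role,
                 data.frame(frame = traj$frame, t = traj$t, x = traj$x,
                            y = traj$y, z = traj$z))
}
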