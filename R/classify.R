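# Swimming-mode classification: spinning around a linear axis (orbit radius
# ~ 0), swimming in a full helix (orbit radius > 0), or transitioning. The
# field coding rule is radius 0 vs > 0; with measurement noise the package
# uses a threshold tau = max(0.25 * zooid_length, 3 * estimated noise floor)
# per window, and an 80%-of-duration rule at the recording level.

#' Estimate the rotation period of a trajectory
#'
#' Robust period estimate used to size classification windows: the median
#' |d theta / d t| of the unwrapped polar angle about the trajectory's
#' displacement axis, over steps whose radial distance is in the upper part
#' of its range (points well off axis rotate cleanly even when part of the
#' record is straight). Returns `NA` when no rotation is detectable.
#'
#' @param traj An `adjusted_trajectory` or data frame with `t,x,y,z`.
#' @return Period in seconds, or `NA`.
#' @export
estimate_rotation_period <- function(traj) {
  traj <- as.data.frame(traj)
  if (nrow(traj) < 10) return(NA_real_)
  cyl <- cylindrical(traj)
  # no rotation to time when the radial excursion is within scatter of a
  # straight line
  if (mean(cyl$r) <= max(3 * sd(cyl$r), 1e-9)) return(NA_real_)
  theta <- unwrap_phase(cyl$theta_raw)
  big <- cyl$r > quantile(cyl$r, 0.6)
  step <- big[-1] & big[-length(big)]
  if (sum(step) < 5) return(NA_real_)
  rate <- abs(diff(theta) / diff(traj$t))[step]
  w <- median(rate)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  span <- sum(abs(diff(theta))[step])
  if (span < pi) return(NA_real_)
  2 * pi / w
}

#' Fit helices over sliding windows
#'
#' Splits the trajectory into fixed-duration windows (default: two estimated
#' rotation periods, capped at the record length; when no rotation is
#' detectable, a quarter of the record) with 50% overlap, and fits each
#' window with [fit_helix()]. Windows with too few samples are skipped.
#'
#' @param traj An `adjusted_trajectory`.
#' @param window Window duration in s; `NULL` for the default above.
#' @param overlap Fractional overlap between consecutive windows.
#' @param refine Passed to [fit_helix()].
#' @return List of `helix_fit` objects, each with attribute `window`
#'   (`c(t_start, t_end)`).
#' @export
fit_helix_windows <- function(traj, window = NULL, overlap = 0.5,
                              refine = TRUE) {
  traj <- as.data.frame(traj)
  dur <- diff(range(traj$t))
  if (is.null(window)) {
    period <- estimate_rotation_period(traj)
    window <- if (is.finite(period)) min(2 * period, dur) else dur / 4
    # a usable window must hold enough samples for a fit
    if (sum(traj$t <= min(traj$t) + window) < 20) window <- dur / 4
  }
  window <- min(window, dur)
  starts <- seq(min(traj$t), max(traj$t) - window + 1e-12,
                by = max(window * (1 - overlap), 1e-9))
  fits <- list()
  for (s in starts) {
    sel <- traj$t >= s - 1e-12 & traj$t <= s + window + 1e-12
    if (sum(sel) < 10) next
    f <- tryCatch(fit_helix(traj[sel, ], refine = refine),
                  error = function(e) NULL)
    if (is.null(f)) next
    attr(f, "window") <- c(t_start = s, t_end = s + window)
    fits[[length(fits) + 1]] <- f
  }
  if (!length(fits))
    hk_stop("no window produced a valid fit", "hk_classification_error")
  attr(fits, "window_duration") <- window
  fits
}

#' Classify swimming mode from per-window helix fits
#'
#' Each window is labelled `spinning` if its orbit radius is below the
#' threshold `tau`, else `helical`. The recording is `spinning` if at least
#' `frac` (default 80%) of the windowed duration is spinning, `helical` if
#' at least `frac` is helical, and `transition` otherwise.
#'
#' `tau` defaults to `max(0.25 * zooid_length, 3 * noise_floor)`, where the
#' noise floor is the median RMS residual of the window fits unless given.
#'
#' @param fits List of `helix_fit` objects (see [fit_helix_windows()]).
#' @param zooid_length Zooid length in mm (sets the size scale of `tau`).
#' @param tau Orbit-radius threshold in mm; `NULL` for the default.
#' @param frac Duration fraction required for a pure mode.
#' @param noise_floor Measurement-noise scale in mm; `NULL` to estimate.
#' @return A `swim_mode` object: list with `mode`, `window_labels` (data
#'   frame `t_start, t_end, label, orbit_radius`), `fractions` (named,
#'   summing to 1), `tau`, `frac`, `noise_floor`.
#' @export
classify_mode <- function(fits, zooid_length, tau = NULL, frac = 0.8,
                          noise_floor = NULL) {
  if (!length(fits)) hk_stop("no window fits", "hk_classification_error")
  radii <- vapply(fits, function(f) f$orbit_radius, numeric(1))
  rms <- vapply(fits, function(f) f$rms_residual, numeric(1))
  if (is.null(noise_floor)) noise_floor <- median(rms)
  if (is.null(tau)) tau <- max(0.25 * zooid_length, 3 * noise_floor)
  win <- t(vapply(fits, function(f) {
    w <- attr(f, "window")
    if (is.null(w)) c(min(f$t), max(f$t)) else unname(w)
  }, numeric(2)))
  labels <- ifelse(radii < tau, "spinning", "helical")
  durs <- win[, 2] - win[, 1]
  fractions <- c(spinning = sum(durs[labels == "spinning"]),
                 transition = 0,
                 helical = sum(durs[labels == "helical"])) / sum(durs)
  mode <- if (fractions["spinning"] >= frac) "spinning"
          else if (fractions["helical"] >= frac) "helical"
          else "transition"
  structure(list(mode = mode,
                 window_labels = data.frame(t_start = win[, 1],
                                            t_end = win[, 2], label = labels,
                                            orbit_radius = radii),
                 fractions = fractions, tau = tau, frac = frac,
                 noise_floor = noise_floor),
            class = "swim_mode")
}

#' @export
print.swim_mode <- function(x, ...) {
  cat(sprintf("<swim_mode> %s (tau = %.3g mm, %d windows)\n", x$mode, x$tau,
              nrow(x$window_labels)))
  cat(sprintf("  fractions: spinning %.2f, helical %.2f\n",
              x$fractions["spinning"], x$fractions["helical"]))
  invisible(x)
}

#' Classify a trajectory end to end
#'
#' Convenience wrapper: [fit_helix_windows()] then [classify_mode()].
#'
#' @param traj An `adjusted_trajectory`.
#' @param zooid_length Zooid length in mm.
#' @param window,overlap,refine Passed to [fit_helix_windows()].
#' @param ... Passed to [classify_mode()].
#' @return A `swim_mode` object with the window fits attached as
#'   `attr(, "fits")`.
#' @export
classify_trajectory <- function(traj, zooid_length, window = NULL,
                                overlap = 0.5, refine = TRUE, ...) {
  fits <- fit_helix_windows(traj, window = window, overlap = overlap,
                            refine = refine)
  out <- classify_mode(fits, zooid_length, ...)
  attr(out, "fits") <- fits
  out
}
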