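# Ground-truth-labelled synthetic recordings emulating the statistical
# structure of in situ stereo-video salp tracks: a chain translating along a
# straight axis while spinning about it, or tracing circular helices; a
# passive reference particle sharing the additive background drift; and
# isotropic Gaussian digitization noise.

#' Specify ground truth for a synthetic recording
#'
#' Defaults are the package's standard study conditions: 100 fps digitization,
#' 3 s duration, mean axial speed 178.8 mm/s along +z, |angular velocity|
#' 2.83 rad/s, orbit radius 10 mm for helical motion, zooid spacing 4 mm,
#' digitization noise sigma 0.5 mm, and a background drift of constant
#' velocity plus a slow sinusoid. The sign of `angular_velocity` encodes
#' handedness: positive = counterclockwise viewed along the swim direction
#' from behind (right-handed helix).
#'
#' @param mode `"spinning"`, `"helical"` or `"transition"`.
#' @param axial_velocity Mean translation velocity, mm/s 3-vector.
#' @param orbit_radius Orbit radius in mm (off-axis marker radius for
#'   spinning; zooid orbit radius for helical motion).
#' @param angular_velocity Signed rad/s.
#' @param drift `NULL`, an n x 3 matrix (mm per frame), or a list with
#'   `velocity` (mm/s 3-vector), `amplitude` (mm 3-vector), `period` (s).
#' @param noise_sigma Isotropic Gaussian noise sd, mm.
#' @param seed Integer RNG seed.
#' @param duration Recording length, s.
#' @param frame_rate Frames per second.
#' @param n_zooids Number of zooid-gut landmarks generated.
#' @param zooid_spacing Spacing between gut landmarks along the chain, mm.
#' @param zooid_angle_dv,zooid_angle_lat Dorsoventral / lateral zooid tilt
#'   (degrees), carried as truth for the jet model.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(mode = c("spinning", "helical", "transition"),
                            axial_velocity = c(0, 0, 178.8),
                            orbit_radius = if (mode == "spinning") 5 else 10,
                            angular_velocity = 2.83,
                            drift = list(velocity = c(5, -3, 2),
                                         amplitude = c(3, 3, 3), period = 5),
                            noise_sigma = 0.5, seed = 1L, duration = 3,
                            frame_rate = 100, n_zooids = 4,
                            zooid_spacing = 4, zooid_angle_dv = 22.3,
                            zooid_angle_lat = 22.2) {
  mode <- match.arg(mode)
  if (frame_rate <= 0) hk_stop("frame_rate must be > 0", "hk_parameter_error")
  if (noise_sigma < 0) hk_stop("noise_sigma must be >= 0", "hk_parameter_error")
  if (orbit_radius < 0) hk_stop("orbit_radius must be >= 0", "hk_parameter_error")
  pitch <- if (abs(angular_velocity) > 0)
    2 * pi * vnorm(axial_velocity) / abs(angular_velocity) else NA_real_
  structure(list(mode = mode, axial_velocity = axial_velocity,
                 orbit_radius = orbit_radius, pitch = pitch,
                 angular_velocity = angular_velocity, drift = drift,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 duration = duration, frame_rate = frame_rate,
                 n_zooids = as.integer(n_zooids),
                 zooid_spacing = zooid_spacing,
                 zooid_angle_dv = zooid_angle_dv,
                 zooid_angle_lat = zooid_angle_lat),
            class = "synthetic_truth")
}

# Shared scaffolding: time grid, swim frame, drift and noise injection.
synth_frame <- function(truth) {
  n <- floor(truth$duration * truth$frame_rate) + 1L
  frame <- seq_len(n) - 1L
  t <- frame / truth$frame_rate
  u <- if (vnorm(truth$axial_velocity) > 0) unitv(truth$axial_velocity)
       else c(0, 0, 1)
  b <- plane_basis(u)
  list(frame = frame, t = t, u = u, e1 = b$e1, e2 = b$e2,
       drift = drift_at(truth$drift, t))
}

synth_tracks <- function(paths, roles, zooid_index, sf, truth) {
  noisy <- function(m) {
    if (truth$noise_sigma > 0)
      m <- m + matrix(rnorm(length(m), 0, truth$noise_sigma), nrow(m))
    m
  }
  tracks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    # identical additive drift on animal tracks and the reference particle
    # (whose drift-free path is constant), so subtraction removes it exactly
    m <- noisy(paths[[i]] + sf$drift)
    tracks[[i]] <- landmark_track(names(paths)[i], roles[i],
                                  data.frame(frame = sf$frame, t = sf$t,
                                             x = m[, 1], y = m[, 2], z = m[, 3]),
                                  zooid_index = zooid_index[i])
  }
  tracks
}

#' Generate a synthetic spinning-chain recording
#'
#' Zooid-gut landmarks lie on a straight line translating at the mean axial
#' velocity; one off-axis marker rotates about that line at the signed
#' angular velocity and orbit radius; a passive reference particle follows
#' the background drift only. Drift is added identically to all animal
#' tracks and the reference; isotropic Gaussian noise is added to every
#' coordinate. Deterministic given `truth$seed`.
#'
#' @param truth A [synthetic_truth()] with `mode = "spinning"`.
#' @return A list with elements `recording` ([colony_recording()]) and
#'   `truth`.
#' @export
generate_spinning_chain <- function(truth = synthetic_truth("spinning")) {
  if (truth$mode != "spinning")
    hk_stop("truth$mode must be 'spinning'", "hk_parameter_error")
  sf <- synth_frame(truth)
  with_seed(truth$seed, {
    base <- outer(sf$t, truth$axial_velocity)  # frontal gut at origin at t=0
    paths <- list()
    roles <- character(0); zidx <- integer(0)
    for (i in seq_len(truth$n_zooids)) {
      off <- -(i - 1) * truth$zooid_spacing * sf$u  # chain trails the front
      paths[[sprintf("gut%02d", i)]] <- sweep(base, 2, off, `+`)
      roles <- c(roles, "zooid_gut"); zidx <- c(zidx, i)
    }
    ph <- truth$angular_velocity * sf$t
    orbit <- truth$orbit_radius *
      (outer(cos(ph), sf$e1) + outer(sin(ph), sf$e2))
    paths[["marker"]] <- base + orbit
    roles <- c(roles, "off_axis_marker"); zidx <- c(zidx, NA_integer_)
    ref0 <- c(30, 30, 0)  # particle near, not on, the chain
    paths[["ref"]] <- matrix(ref0, length(sf$t), 3, byrow = TRUE)
    roles <- c(roles, "reference_particle"); zidx <- c(zidx, NA_integer_)
    tracks <- synth_tracks(paths, roles, zidx, sf, truth)
    rec <- colony_recording(
      sprintf("synthetic-spin-seed%d", truth$seed), tracks,
      frame_rate = truth$frame_rate, zooid_count = truth$n_zooids,
      chain_length = truth$n_zooids * truth$zooid_spacing, zooid_length = 10,
      metadata = list(synthetic = TRUE, mode = truth$mode))
    list(recording = rec, truth = truth)
  })
}

# Helical path about an axis through `centre` with direction u: point i has
# phase offset phi_i.
helix_path <- function(t, centre, u, e1, e2, v_ax, R, omega, phi) {
  ph <- omega * t + phi
  sweep(outer(t, v_ax * u) + R * (outer(cos(ph), e1) + outer(sin(ph), e2)),
        2, centre, `+`)
}

#' Generate a synthetic helical-swimming recording
#'
#' Each zooid-gut landmark traces a circular helix of common radius, pitch
#' and signed angular frequency about a straight displacement axis, with
#' phases staggered by the axial zooid spacing (pitch = 2*pi*|v|/|omega|
#' mm/turn). Reference particle, drift and noise as in
#' [generate_spinning_chain()].
#'
#' @param truth A [synthetic_truth()] with `mode = "helical"` and
#'   `orbit_radius > 0`.
#' @return A list with elements `recording` and `truth`.
#' @export
generate_helical_chain <- function(truth = synthetic_truth("helical")) {
  if (truth$mode != "helical")
    hk_stop("truth$mode must be 'helical'", "hk_parameter_error")
  if (truth$orbit_radius <= 0)
    hk_stop("orbit_radius must be > 0 for helical mode", "hk_parameter_error")
  sf <- synth_frame(truth)
  v_ax <- vnorm(truth$axial_velocity)
  with_seed(truth$seed, {
    paths <- list(); roles <- character(0); zidx <- integer(0)
    for (i in seq_len(truth$n_zooids)) {
      # zooid i sits (i-1)*spacing behind the front along the axis; on a
      # helix that axial lag maps to a phase lag of 2*pi*lag/pitch
      lag <- (i - 1) * truth$zooid_spacing
      phi <- if (is.na(truth$pitch) || truth$pitch == 0) 0 else
        -sign(truth$angular_velocity) * 2 * pi * lag / truth$pitch
      paths[[sprintf("gut%02d", i)]] <- helix_path(
        sf$t, centre = -lag * sf$u, u = sf$u, e1 = sf$e1, e2 = sf$e2,
        v_ax = v_ax, R = truth$orbit_radius,
        omega = truth$angular_velocity, phi = phi)
      roles <- c(roles, "zooid_gut"); zidx <- c(zidx, i)
    }
    paths[["ref"]] <- matrix(c(30, 30, 0), length(sf$t), 3, byrow = TRUE)
    roles <- c(roles, "reference_particle"); zidx <- c(zidx, NA_integer_)
    tracks <- synth_tracks(paths, roles, zidx, sf, truth)
    rec <- colony_recording(
      sprintf("synthetic-helix-seed%d", truth$seed), tracks,
      frame_rate = truth$frame_rate, zooid_count = truth$n_zooids,
      chain_length = truth$n_zooids * truth$zooid_spacing, zooid_length = 10,
      metadata = list(synthetic = TRUE, mode = truth$mode))
    list(recording = rec, truth = truth)
  })
}

#' Generate a synthetic transition recording
#'
#' Concatenates a spinning segment and a helical segment with positions
#' continuous at the switch: the helical axis is placed parallel to the swim
#' axis at perpendicular offset `truth_b$orbit_radius` from the gut line, and
#' every landmark starts its helix from its own position at the switch time.
#'
#' @param truth_a A spinning [synthetic_truth()] (used for `t < switch_t`).
#' @param truth_b A helical [synthetic_truth()] (used for `t >= switch_t`).
#' @param switch_t Switch time in seconds (0 gives a purely helical record).
#' @return A list with `recording`, `truths` (list of the two), and
#'   `window_labels`, a data frame of (t_start, t_end, label) ground truth.
#' @export
generate_transition_recording <- function(truth_a, truth_b,
                                          switch_t = truth_a$duration / 2) {
  if (truth_a$mode != "spinning" || truth_b$mode != "helical")
    hk_stop("need truth_a spinning and truth_b helical", "hk_parameter_error")
  same <- isTRUE(all.equal(truth_a$frame_rate, truth_b$frame_rate)) &&
    truth_a$n_zooids == truth_b$n_zooids &&
    isTRUE(all.equal(truth_a$zooid_spacing, truth_b$zooid_spacing))
  if (!same)
    hk_stop(paste("truth_a and truth_b disagree on frame_rate, n_zooids or",
                  "zooid_spacing: the switch cannot be continuous"),
            "hk_parameter_error")
  if (switch_t < 0 || switch_t > truth_a$duration + truth_b$duration)
    hk_stop("switch_t outside the recording", "hk_parameter_error")
  sf <- synth_frame(synthetic_truth(
    "spinning", axial_velocity = truth_a$axial_velocity,
    duration = truth_a$duration + truth_b$duration,
    frame_rate = truth_a$frame_rate, n_zooids = truth_a$n_zooids,
    zooid_spacing = truth_a$zooid_spacing, drift = truth_a$drift,
    noise_sigma = truth_a$noise_sigma, seed = truth_a$seed))
  t <- sf$t
  pre <- t < switch_t
  v_a <- truth_a$axial_velocity
  v_b <- vnorm(truth_b$axial_velocity)
  R <- truth_b$orbit_radius
  with_seed(truth_a$seed, {
    paths <- list(); roles <- character(0); zidx <- integer(0)
    # helix axis: parallel to u, offset R along e1 from the gut line at switch
    axis_at_switch <- switch_t * v_a + R * sf$e1
    # helical continuation: from a landmark's exact position at switch_t,
    # orbit the offset axis (keeping its own radius and phase) while the
    # axis translates at truth_b's axial speed
    continue_helical <- function(at_sw) {
      d <- at_sw - axis_at_switch
      ax <- sum(d * sf$u); dperp <- d - ax * sf$u
      r_i <- vnorm(dperp)
      phi_i <- atan2(sum(dperp * sf$e2), sum(dperp * sf$e1))
      th <- truth_b$angular_velocity * (t - switch_t) + phi_i
      sweep(outer(t - switch_t, v_b * sf$u) +
              r_i * (outer(cos(th), sf$e1) + outer(sin(th), sf$e2)),
            2, axis_at_switch + ax * sf$u, `+`)
    }
    splice <- function(straight, at_sw) {
      rbind(straight[pre, , drop = FALSE],
            continue_helical(at_sw)[!pre, , drop = FALSE])
    }
    for (i in seq_len(truth_a$n_zooids)) {
      p0 <- -(i - 1) * truth_a$zooid_spacing * sf$u
      straight <- sweep(outer(t, v_a), 2, p0, `+`)
      paths[[sprintf("gut%02d", i)]] <- splice(straight, p0 + switch_t * v_a)
      roles <- c(roles, "zooid_gut"); zidx <- c(zidx, i)
    }
    # off-axis marker spins about the gut line pre-switch, then continues
    # helically through the switch like any landmark
    ph <- truth_a$angular_velocity * t
    marker_straight <- outer(t, v_a) + truth_a$orbit_radius *
      (outer(cos(ph), sf$e1) + outer(sin(ph), sf$e2))
    ph_sw <- truth_a$angular_velocity * switch_t
    marker_at_sw <- switch_t * v_a + truth_a$orbit_radius *
      (cos(ph_sw) * sf$e1 + sin(ph_sw) * sf$e2)
    paths[["marker"]] <- splice(marker_straight, marker_at_sw)
    roles <- c(roles, "off_axis_marker"); zidx <- c(zidx, NA_integer_)
    paths[["ref"]] <- matrix(c(30, 30, 0), length(t), 3, byrow = TRUE)
    roles <- c(roles, "reference_particle"); zidx <- c(zidx, NA_integer_)
    truth_cat <- truth_a
    truth_cat$noise_sigma <- truth_a$noise_sigma
    tracks <- synth_tracks(paths, roles, zidx, sf, truth_cat)
    rec <- colony_recording(
      sprintf("synthetic-transition-seed%d", truth_a$seed), tracks,
      frame_rate = truth_a$frame_rate, zooid_count = truth_a$n_zooids,
      chain_length = truth_a$n_zooids * truth_a$zooid_spacing,
      zooid_length = 10,
      metadata = list(synthetic = TRUE, mode = "transition",
                      switch_t = switch_t))
    labels <- data.frame(
      t_start = c(0, switch_t), t_end = c(switch_t, max(t)),
      label = c("spinning", "helical"))
    labels <- labels[labels$t_end > labels$t_start, ]
    list(recording = rec, truths = list(spinning = truth_a, helical = truth_b),
         window_labels = labels)
  })
}

#' Generate a pulsatile siphon-angle series
#'
#' Emulates the time-varying lateral siphon angle over the zooid's pulsatile
#' jetting cycle: `angle(t) = mean + amplitude * cos(2*pi*t/period) + noise`,
#' clamped into \[0, 90\] degrees. With the package defaults
#' (mean 21.9 deg, amplitude 2.6 deg) the noiseless series swings between
#' 24.5 and 19.3 degrees.
#'
#' @param mean,amplitude Degrees; `mean - amplitude` must be >= 0.
#' @param period Pulse period, s.
#' @param duration Series length, s.
#' @param rate Samples per second.
#' @param noise_sigma Gaussian noise sd, degrees.
#' @param seed Integer RNG seed.
#' @return An [angle_series()].
#' @export
generate_siphon_series <- function(mean = 21.9, amplitude = 2.6, period = 1,
                                   duration = 4, rate = 50, noise_sigma = 0,
                                   seed = 1L) {
  if (mean - amplitude < 0)
    hk_stop("mean - amplitude must be >= 0", "hk_parameter_error")
  t <- seq(0, duration, by = 1 / rate)
  with_seed(seed, {
    a <- mean + amplitude * cos(2 * pi * t / period)
    if (noise_sigma > 0) a <- a + rnorm(length(t), 0, noise_sigma)
    a <- pmin(90, pmax(0, a))
    angle_series("synthetic-siphon", data.frame(t = t, angle = a),
                 plane = "lateral")
  })
}

#' Mirror-reflect a colony recording
#'
#' Reflects every coordinate through the x = 0 plane (`x -> -x`), flipping
#' the chirality of the motion; useful for handedness tests.
#'
#' @param rec A [colony_recording()].
#' @return The reflected recording.
#' @export
reflect_recording <- function(rec) {
  rec$tracks <- lapply(rec$tracks, function(tr) {
    tr$samples$x <- -tr$samples$x
    tr
  })
  rec
}

#' Rigidly transform a colony recording
#'
#' Applies `p -> Q p + b` to every sample of every track.
#'
#' @param rec A [colony_recording()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 offset (mm).
#' @return The transformed recording.
#' @export
transform_recording <- function(rec, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  rec$tracks <- lapply(rec$tracks, function(tr) {
    m <- as.matrix(tr$samples[, c("x", "y", "z")]) %*% t(rotation)
    m <- sweep(m, 2, translation, `+`)
    tr$samples[, c("x", "y", "z")] <- m
    tr
  })
  rec
}
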