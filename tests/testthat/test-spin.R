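test_that("chain axis fit: exact cases and degenerate input", {
  mk <- function(id, p, zi) landmark_track(id, "zooid_gut",
    data.frame(frame = 0L, t = 0, x = p[1], y = p[2], z = p[3]), zi)
  pts <- lapply(1:4, function(i) c(0, 0, 10 - 2 * i))
  tracks <- Map(mk, paste0("g", 1:4), pts, 1:4)
  ax <- fit_chain_axis(tracks, frame = 0)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-12)
  expect_equal(ax$rms_residual, 0, tolerance = 1e-12)
  # frontal zooid is at larger z here, so the default orientation points +z
  expect_gt(ax$direction[3], 0)

  two <- Map(mk, c("a", "b"), list(c(0, 0, 0), c(1, 2, 2)), 1:2)
  ax2 <- fit_chain_axis(two, 0)
  expect_equal(abs(sum(ax2$direction * c(1, 2, 2) / 3)), 1, tolerance = 1e-12)
  expect_equal(ax2$rms_residual, 0, tolerance = 1e-12)

  expect_error(fit_chain_axis(tracks[1], 0),
               class = "hk_insufficient_landmarks")
  same <- Map(mk, c("a", "b"), list(c(1, 1, 1), c(1, 1, 1)), 1:2)
  expect_error(fit_chain_axis(same, 0), class = "hk_degenerate_geometry")
})

test_that("noisy axis direction stays within 1 degree (Monte Carlo)", {
  true_pts <- cbind(0, 0, c(0, 4, 8, 12))
  angs <- replicate(1000, {
    m <- true_pts + matrix(rnorm(12, sd = 0.1), 4)
    tracks <- lapply(1:4, function(i) data.frame(
      frame = 0L, t = 0, x = m[i, 1], y = m[i, 2], z = m[i, 3]))
    ax <- fit_chain_axis(tracks, 0, orient = c(0, 0, 1))
    acos(min(1, abs(sum(ax$direction * c(0, 0, 1))))) * 180 / pi
  })
  expect_lt(median(angs), 1)
  expect_lt(quantile(angs, 0.95), 2)
})

test_that("phase series reproduces constructed rotations", {
  t <- seq(0, 2, by = 0.01)
  axis <- chain_axis_z()
  mk_traj <- function(theta, r = 5) {
    structure(data.frame(frame = seq_along(t) - 1, t = t,
                         x = r * cos(theta), y = r * sin(theta), z = 30 * t),
              class = c("adjusted_trajectory", "data.frame"))
  }
  ph <- phase_angle_series(mk_traj(2 * pi * t + 0.3), axis)
  expect_equal(ph$theta, 2 * pi * t + 0.3, tolerance = 1e-9)
  # stationary off-axis marker: constant phase
  ph0 <- phase_angle_series(mk_traj(rep(0.7, length(t))), axis)
  expect_equal(diff(range(ph0$theta)), 0, tolerance = 1e-12)
  # marker on the axis: undefined phase
  expect_error(phase_angle_series(mk_traj(0 * t, r = 0), axis),
               class = "hk_undefined_phase")
})

test_that("phase slope from a noisy spinning recording is within 2%", {
  tr <- synthetic_truth("spinning", axial_velocity = c(0, 0, 20),
                        orbit_radius = 5, angular_velocity = 10,
                        noise_sigma = 0.2, drift = NULL, duration = 2,
                        frame_rate = 100, seed = 3)
  g <- generate_spinning_chain(tr)
  adj <- correct_recording(g$recording)
  ph <- phase_angle_series(adj$marker, adj[grep("gut", names(adj))])
  slope <- unname(coef(lm(theta ~ t, data = ph))[2])
  expect_equal(slope, 10, tolerance = 0.02)
})

test_that("angular velocity and handedness follow the phase sign", {
  t <- seq(0, 1, by = 0.01)
  ph <- structure(data.frame(t = t, theta = 2 * pi * t),
                  class = c("spin_phase", "data.frame"))
  m <- angular_velocity(ph)
  expect_equal(m$omega$omega, rep(2 * pi, 100), tolerance = 1e-9)
  expect_equal(m$mean_abs_omega, 2 * pi, tolerance = 1e-9)
  expect_identical(m$handedness, "CCW")
  ph$theta <- -ph$theta
  expect_identical(angular_velocity(ph)$handedness, "CW")
  expect_error(angular_velocity(ph[1, , drop = FALSE]),
               class = "hk_insufficient_data")
  # under-sampled rotation is refused, not silently aliased
  bad <- data.frame(t = c(0, 0.01, 0.02), theta = c(0, 3.1, 6.2))
  expect_error(angular_velocity(bad), class = "hk_aliasing_error")
})

test_that("full-revolution spin recovers omega to 1e-9", {
  tr <- noiseless_spin_truth(omega = 2 * pi, duration = 1)
  g <- generate_spinning_chain(tr)
  adj <- correct_recording(g$recording)
  m <- angular_velocity(phase_angle_series(adj$marker,
                                           adj[grep("gut", names(adj))]))
  expect_equal(m$mean_abs_omega, 2 * pi, tolerance = 1e-9)
  expect_identical(spin_direction(m), "CCW")
})

test_that("spin direction flips under reflection, is rotation-invariant, and can be indeterminate", {
  g <- generate_spinning_chain(noiseless_spin_truth())
  direction_of <- function(rec) {
    adj <- correct_recording(rec)
    spin_direction(angular_velocity(
      phase_angle_series(adj$marker, adj[grep("gut", names(adj))])))
  }
  expect_identical(direction_of(g$recording), "CCW")
  expect_identical(direction_of(reflect_recording(g$recording)), "CW")
  set.seed(11)
  for (i in 1:20) {
    rot <- transform_recording(g$recording, random_rotation(),
                               rnorm(3, sd = 50))
    expect_identical(direction_of(rot), "CCW")
  }
  # significance floor turns a sub-threshold rotation into "indeterminate"
  adj <- correct_recording(g$recording)
  m <- angular_velocity(phase_angle_series(adj$marker,
                                           adj[grep("gut", names(adj))]))
  expect_identical(spin_direction(m, floor = 100), "indeterminate")
})

test_that("swim speed: path and net conventions", {
  still <- data.frame(frame = 0:10, t = (0:10) / 100, x = 1, y = 2, z = 3)
  expect_equal(swim_speed(still), 0)
  line <- data.frame(frame = 0:9, t = (0:9) / 100, x = 0, y = 0,
                     z = seq(0, 90, by = 10))
  expect_equal(swim_speed(line), 1000)
  expect_equal(net_speed(line), 1000)
  # helix: path speed sqrt(v^2 + (omega R)^2), net speed ~ v
  g <- generate_helical_chain(noiseless_helix_truth(R = 5, omega = 2 * pi,
                                                    v = 20))
  adj <- frontal_adjusted(g)
  expect_equal(swim_speed(adj), sqrt(20^2 + (2 * pi * 5)^2), tolerance = 1e-3)
  expect_equal(net_speed(adj), 20, tolerance = 1e-2)
  expect_error(swim_speed(still[1, , drop = FALSE]),
               class = "hk_insufficient_data")
})
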