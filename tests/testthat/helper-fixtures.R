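# Fixtures built in code: random rigid motions and small random recordings.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a small recording with randomized tracks and gaps, for round-trip tests
random_recording <- function(seed) {
  set.seed(seed)
  fps <- sample(c(50, 100, 160), 1)
  n <- sample(5:20, 1)
  mk <- function(id, role, zi = NA_integer_) {
    frames <- sort(sample(0:(2 * n), n))
    landmark_track(id, role,
                   data.frame(frame = frames, t = frames / fps,
                              x = rnorm(n, sd = 50), y = rnorm(n, sd = 50),
                              z = rnorm(n, sd = 50)),
                   zooid_index = zi)
  }
  # distinct gapped frame sets, but force a shared frame so validation passes
  tracks <- list(mk("g1", "zooid_gut", 1L), mk("g2", "zooid_gut", 2L),
                 mk("ref", "reference_particle"))
  shared <- 0L
  tracks <- lapply(tracks, function(tr) {
    if (!shared %in% tr$samples$frame) {
      s <- rbind(data.frame(frame = shared, t = shared / fps,
                            x = rnorm(1), y = rnorm(1), z = rnorm(1)),
                 tr$samples)
      tr <- landmark_track(tr$landmark_id, tr$role, s, tr$zooid_index)
    }
    tr
  })
  colony_recording(paste0("rand", seed), tracks, frame_rate = fps,
                   zooid_count = 2L, chain_length = 20, zooid_length = 10,
                   metadata = list(site = "test"))
}

# standard noiseless, drift-free truths used across kinematics tests
noiseless_helix_truth <- function(seed = 1L, R = 5, omega = 2 * pi,
                                  v = 20, duration = 3, n_zooids = 4) {
  synthetic_truth("helical", axial_velocity = c(0, 0, v), orbit_radius = R,
                  angular_velocity = omega, noise_sigma = 0, drift = NULL,
                  duration = duration, frame_rate = 100, n_zooids = n_zooids,
                  seed = seed)
}

noiseless_spin_truth <- function(seed = 1L, R = 5, omega = 2 * pi, v = 20,
                                 duration = 2) {
  synthetic_truth("spinning", axial_velocity = c(0, 0, v), orbit_radius = R,
                  angular_velocity = omega, noise_sigma = 0, drift = NULL,
                  duration = duration, frame_rate = 100, n_zooids = 4,
                  seed = seed)
}

# brute-force wrench oracle: explicit sum of r x F terms, written against
# the coordinate formula rather than any package helper
brute_wrench <- function(jets, axis) {
  u <- axis$direction / sqrt(sum(axis$direction^2))
  f_tot <- c(0, 0, 0); tq <- c(0, 0, 0)
  for (j in jets) {
    f <- -j$magnitude * j$direction
    r <- j$attach_point - axis$point
    f_tot <- f_tot + f
    tq <- tq + c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
                 r[1] * f[2] - r[2] * f[1])
  }
  list(net_force = f_tot, axial_thrust = sum(u * f_tot),
       axial_torque = sum(u * tq))
}

frontal_adjusted <- function(gen) {
  correct_motion(get_track(gen$recording, "gut01"),
                 reference_track(gen$recording))
}
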