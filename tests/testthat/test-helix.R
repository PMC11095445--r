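test_that("noiseless helix parameters are recovered to 1e-6 relative error", {
  g <- generate_helical_chain(noiseless_helix_truth(R = 5, omega = 2 * pi,
                                                    v = 20))
  f <- fit_helix(frontal_adjusted(g))
  expect_equal(f$orbit_radius, 5, tolerance = 1e-6)
  expect_equal(f$pitch, 20, tolerance = 1e-6)
  expect_equal(f$angular_frequency, 2 * pi, tolerance = 1e-6)
  expect_equal(f$axial_speed, 20, tolerance = 1e-6)
  expect_identical(f$handedness, "CCW")
  expect_lt(f$rms_residual, 1e-6)
  # negative omega: left-handed helix
  gl <- generate_helical_chain(noiseless_helix_truth(omega = -2 * pi))
  expect_identical(fit_helix(frontal_adjusted(gl))$handedness, "CW")
})

test_that("straight trajectories give non-rotating fits with pitch NA", {
  line <- data.frame(frame = 0:99, t = (0:99) / 100, x = 0, y = 0,
                     z = seq(0, 99, by = 1))
  f <- fit_helix(line)
  expect_false(f$rotating)
  expect_lt(f$orbit_radius, 1e-9)
  expect_true(is.na(f$pitch))
  set.seed(4)
  noisy <- line
  noisy$x <- rnorm(100, sd = 0.5); noisy$y <- rnorm(100, sd = 0.5)
  fn <- fit_helix(noisy)
  expect_false(fn$rotating)
  expect_lt(fn$orbit_radius, 3 * 0.5)
  expect_error(fit_helix(line[1:5, ]), class = "hk_insufficient_data")
})

test_that("a static offset from the chain axis is not mistaken for an orbit", {
  # a landmark riding at a fixed offset is a straight trajectory about its
  # own displacement axis: no rotation, no helix
  t <- (0:99) / 100
  off <- data.frame(frame = 0:99, t = t, x = 5, y = 0, z = 100 * t)
  f <- fit_helix(off)
  expect_false(f$rotating)
  expect_true(is.na(f$angular_frequency))
  expect_lt(f$orbit_radius, 1e-9)
})

test_that("orbit radius: translation, circle, noisy helix", {
  line <- data.frame(frame = 0:99, t = (0:99) / 100, x = 0, y = 0, z = 0:99)
  expect_lt(orbit_radius(line), 1e-9)
  th <- (0:199) / 200 * 4 * pi  # uniform over whole turns
  circ <- data.frame(frame = seq_along(th) - 1, t = th / (2 * pi),
                     x = 7 * cos(th), y = 7 * sin(th), z = 0)
  expect_equal(orbit_radius(circ), 7, tolerance = 1e-9)
  errs <- vapply(1:50, function(s) {
    tr <- noiseless_helix_truth(seed = s)
    tr$noise_sigma <- 0.5
    g <- generate_helical_chain(tr)
    abs(orbit_radius(frontal_adjusted(g)) - 5) / 5
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("near-planar circular orbits are fit as helical and flagged", {
  th <- (0:299) / 300 * 6 * pi  # uniform over whole turns
  circ <- data.frame(frame = seq_along(th) - 1, t = th / (2 * pi),
                     x = 7 * cos(th), y = 7 * sin(th), z = 0)
  f <- fit_helix(circ)
  expect_true(f$rotating)
  expect_true(f$planar)
  expect_equal(f$orbit_radius, 7, tolerance = 1e-6)
  expect_equal(f$pitch, 0, tolerance = 1e-6)
})

test_that("noisy helices recover radius and pitch within 5% (Monte Carlo)", {
  res <- vapply(1:60, function(s) {
    tr <- noiseless_helix_truth(seed = s)
    tr$noise_sigma <- 0.2
    g <- generate_helical_chain(tr)
    f <- fit_helix(frontal_adjusted(g))
    c(abs(f$orbit_radius - 5) / 5, abs(f$pitch - 20) / 20,
      f$handedness == "CCW")
  }, numeric(3))
  expect_lt(median(res[1, ]), 0.05)
  expect_lt(median(res[2, ]), 0.05)
  expect_equal(mean(res[3, ]), 1)
})

test_that("refinement never degrades the two-stage initializer", {
  for (s in 1:10) {
    tr <- noiseless_helix_truth(seed = s)
    tr$noise_sigma <- 0.4
    g <- generate_helical_chain(tr)
    adj <- frontal_adjusted(g)
    expect_lte(fit_helix(adj, refine = TRUE)$rms_residual,
               fit_helix(adj, refine = FALSE)$rms_residual + 1e-12)
  }
})

test_that("fit is invariant under rigid motions; handedness flips under reflection", {
  g <- generate_helical_chain(noiseless_helix_truth())
  f0 <- fit_helix(frontal_adjusted(g))
  set.seed(21)
  for (i in 1:10) {
    rec <- transform_recording(g$recording, random_rotation(),
                               rnorm(3, sd = 100))
    f <- fit_helix(frontal_adjusted(list(recording = rec)))
    expect_equal(f$orbit_radius, f0$orbit_radius, tolerance = 1e-6)
    expect_equal(f$pitch, f0$pitch, tolerance = 1e-6)
    expect_equal(abs(f$angular_frequency), abs(f0$angular_frequency),
                 tolerance = 1e-6)
    expect_identical(f$handedness, f0$handedness)
  }
  fm <- fit_helix(frontal_adjusted(list(
    recording = reflect_recording(g$recording))))
  expect_identical(fm$handedness, "CW")
  expect_equal(fm$orbit_radius, f0$orbit_radius, tolerance = 1e-6)
})

test_that("helix and spin handedness agree on the same recording", {
  for (s in 1:5) {
    for (om in c(2 * pi, -2 * pi)) {
      tr <- synthetic_truth("helical", axial_velocity = c(0, 0, 20),
                            orbit_radius = 5, angular_velocity = om,
                            noise_sigma = 0.2, drift = NULL, duration = 3,
                            frame_rate = 100, seed = s)
      g <- generate_helical_chain(tr)
      adj <- frontal_adjusted(g)
      f <- fit_helix(adj)
      ph <- phase_angle_series(adj, f$axis)
      m <- angular_velocity(ph)
      expect_identical(f$handedness, m$handedness)
      expect_identical(f$handedness, if (om > 0) "CCW" else "CW")
    }
  }
})

test_that("helix_fit methods are coherent", {
  g <- generate_helical_chain(noiseless_helix_truth())
  f <- fit_helix(frontal_adjusted(g))
  expect_named(coef(f), c("orbit_radius", "pitch", "angular_frequency",
                          "axial_speed"))
  pred <- predict(f)
  expect_equal(dim(pred), c(f$n, 3))
  expect_lt(max(abs(residuals(f))), 1e-6)
  sims <- simulate(f, nsim = 2, seed = 5, sigma = 0.1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]], sims[[2]]))
  f2 <- fit_helix(sims[[1]])
  expect_equal(f2$orbit_radius, 5, tolerance = 0.05)
  expect_output(print(f), "orbit radius")
  expect_output(summary(f), "convention")
})

test_that("windowed classification recovers ground-truth modes", {
  # all-spinning and all-helical window sets classify directly
  mk_fit <- function(radius, t0, t1) {
    f <- list(orbit_radius = radius, rms_residual = 0.1, rotating = radius > 1,
              t = c(t0, t1))
    class(f) <- "helix_fit"
    attr(f, "window") <- c(t_start = t0, t_end = t1)
    f
  }
  zl <- 10
  spin <- classify_mode(lapply(0:3, function(i) mk_fit(0, i, i + 1)), zl)
  expect_identical(spin$mode, "spinning")
  hel <- classify_mode(lapply(0:3, function(i) mk_fit(10 * spin$tau, i, i + 1)), zl)
  expect_identical(hel$mode, "helical")
  expect_equal(sum(hel$fractions), 1)

  # end-to-end on noiseless synthetic recordings under defaults
  ta <- noiseless_spin_truth(duration = 3, v = 30)
  tb <- noiseless_helix_truth(duration = 3, v = 30, R = 10)
  gs <- generate_spinning_chain(ta)
  expect_identical(classify_trajectory(frontal_adjusted(gs), 10)$mode,
                   "spinning")
  gh <- generate_helical_chain(tb)
  expect_identical(classify_trajectory(frontal_adjusted(gh), 10)$mode,
                   "helical")
  gt <- generate_transition_recording(ta, tb, switch_t = 3)
  expect_identical(classify_trajectory(frontal_adjusted(gt), 10)$mode,
                   "transition")
})

test_that("more zooids with larger orbits classify helical, fewer spin", {
  # the qualitative size effect: long chains in wide helices vs short
  # straight spinners
  long <- synthetic_truth("helical", n_zooids = 10, orbit_radius = 12,
                          axial_velocity = c(0, 0, 30), noise_sigma = 0.3,
                          drift = NULL, angular_velocity = 2 * pi,
                          duration = 3, seed = 2)
  short <- synthetic_truth("spinning", n_zooids = 4, orbit_radius = 5,
                           axial_velocity = c(0, 0, 30), noise_sigma = 0.3,
                           drift = NULL, angular_velocity = 2 * pi,
                           duration = 3, seed = 2)
  gl <- generate_helical_chain(long)
  gsh <- generate_spinning_chain(short)
  expect_identical(classify_trajectory(frontal_adjusted(gl), 10)$mode,
                   "helical")
  expect_identical(classify_trajectory(frontal_adjusted(gsh), 10)$mode,
                   "spinning")
})
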