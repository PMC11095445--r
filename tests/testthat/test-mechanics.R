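test_that("axis-aligned on-axis jets give thrust and zero torque", {
  axis <- chain_axis_z()
  jets <- lapply(0:3, function(i)
    jet_spec(c(0, 0, 4 * i), c(0, 0, -1), magnitude = 2))
  w <- net_wrench(jets, axis)
  expect_equal(w$axial_thrust, 8)
  expect_equal(w$axial_torque, 0)
  expect_identical(w$predicted_handedness, "none")
  expect_error(net_wrench(list(), axis), class = "hk_insufficient_input")
})

test_that("tilted-jet example: torque 4 r sin(theta), thrust 4 cos(theta)", {
  axis <- chain_axis_z()
  th <- 22 * pi / 180
  jets <- lapply(0:3, function(i) {
    rhat <- c(cos(i * pi / 3), sin(i * pi / 3), 0)  # arbitrary azimuths
    that <- c(-rhat[2], rhat[1], 0)                 # common tangential sense
    jet_spec(5 * rhat + c(0, 0, 4 * i),
             -cos(th) * c(0, 0, 1) + sin(th) * that)
  })
  w <- net_wrench(jets, axis)
  expect_equal(abs(w$axial_torque), 4 * 5 * sin(th), tolerance = 1e-12)
  expect_equal(w$axial_thrust, 4 * cos(th), tolerance = 1e-12)
  # mirror reflection flips the torque sign, not the thrust
  mirror <- lapply(jets, function(j) {
    j$attach_point[1] <- -j$attach_point[1]
    j$direction[1] <- -j$direction[1]
    j
  })
  wm <- net_wrench(mirror, axis)
  expect_equal(wm$axial_torque, -w$axial_torque, tolerance = 1e-12)
  expect_equal(wm$axial_thrust, w$axial_thrust, tolerance = 1e-12)
  expect_identical(sort(c(w$predicted_handedness, wm$predicted_handedness)),
                   c("CCW", "CW"))
})

test_that("net_wrench agrees with the brute-force oracle on random jet sets", {
  set.seed(31)
  for (i in 1:200) {
    axis <- list(point = rnorm(3, sd = 10),
                 direction = random_rotation()[, 1])
    n <- sample(1:10, 1)
    jets <- lapply(seq_len(n), function(k)
      jet_spec(rnorm(3, sd = 20), rnorm(3), magnitude = runif(1, 0, 5)))
    w <- net_wrench(jets, axis)
    o <- brute_wrench(jets, axis)
    expect_equal(w$net_force, o$net_force, tolerance = 1e-9)
    expect_equal(w$axial_thrust, o$axial_thrust, tolerance = 1e-9)
    expect_equal(w$axial_torque, o$axial_torque, tolerance = 1e-9)
    expect_lte(abs(w$axial_thrust),
               sqrt(sum(w$net_force^2)) + 1e-12)
  }
})

test_that("wrench is linear in magnitudes and equivariant under rigid motions", {
  set.seed(5)
  axis <- chain_axis_z()
  jets <- build_chain_jets(6, spacing = 4, dv_angle = 20, lat_angle = 15,
                           radius = 5)
  w1 <- net_wrench(jets, axis)
  jets3 <- lapply(jets, function(j) { j$magnitude <- 3 * j$magnitude; j })
  w3 <- net_wrench(jets3, axis)
  expect_equal(w3$axial_thrust, 3 * w1$axial_thrust)
  expect_equal(w3$axial_torque, 3 * w1$axial_torque)
  for (i in 1:10) {
    Q <- random_rotation(); b <- rnorm(3, sd = 30)
    jets_r <- lapply(jets, function(j) {
      j$attach_point <- as.numeric(Q %*% j$attach_point + b)
      j$direction <- as.numeric(Q %*% j$direction)
      j
    })
    axis_r <- list(point = as.numeric(Q %*% axis$point + b),
                   direction = as.numeric(Q %*% axis$direction))
    wr <- net_wrench(jets_r, axis_r)
    expect_equal(wr$axial_thrust, w1$axial_thrust, tolerance = 1e-9)
    expect_equal(wr$axial_torque, w1$axial_torque, tolerance = 1e-9)
  }
})

test_that("chain jet sets: zero tilt gives zero torque, lateral tilt does not", {
  axis <- chain_axis_z()
  w0 <- net_wrench(build_chain_jets(8, dv_angle = 0, lat_angle = 0), axis)
  expect_equal(w0$axial_torque, 0, tolerance = 1e-12)
  # purely dorsoventral tilt: force lines stay in radial planes, no torque
  wdv <- net_wrench(build_chain_jets(8, dv_angle = 25, lat_angle = 0), axis)
  expect_equal(wdv$axial_torque, 0, tolerance = 1e-12)
  wlat <- net_wrench(build_chain_jets(8, dv_angle = 0, lat_angle = 10), axis)
  expect_gt(abs(wlat$axial_torque), 0.1)
  # doubling the chain doubles thrust and torque
  w8 <- net_wrench(build_chain_jets(8, dv_angle = 22.3, lat_angle = 22.2), axis)
  w16 <- net_wrench(build_chain_jets(16, dv_angle = 22.3, lat_angle = 22.2), axis)
  expect_equal(w16$axial_thrust, 2 * w8$axial_thrust, tolerance = 1e-12)
  expect_equal(w16$axial_torque, 2 * w8$axial_torque, tolerance = 1e-12)
  expect_error(build_chain_jets(4, spacing = -1), class = "hk_parameter_error")
})

test_that("thrust-to-torque ratio decreases monotonically with tilt", {
  expect_equal(thrust_torque_ratio(90, 2), 0)
  expect_equal(thrust_torque_ratio(45, 1), 1)
  expect_identical(thrust_torque_ratio(0, 1), Inf)
  for (r in c(0.5, 1, 5)) {
    grid <- seq(1, 89, by = 1)
    vals <- vapply(grid, thrust_torque_ratio, numeric(1), lever_radius = r)
    expect_true(all(diff(vals) < 0))
    expect_gt(thrust_torque_ratio(20, r), thrust_torque_ratio(40, r))
  }
  expect_error(thrust_torque_ratio(91, 1), class = "hk_parameter_error")
  expect_error(thrust_torque_ratio(10, 0), class = "hk_parameter_error")
})

test_that("per-jet thrust falls and torque rises with tilt at fixed lever", {
  axis <- chain_axis_z()
  tilts <- seq(1, 89, by = 1)
  th <- vapply(tilts, function(a)
    net_wrench(build_chain_jets(1, dv_angle = 0, lat_angle = a), axis)$axial_thrust,
    numeric(1))
  tq <- vapply(tilts, function(a)
    abs(net_wrench(build_chain_jets(1, dv_angle = 0, lat_angle = a), axis)$axial_torque),
    numeric(1))
  expect_true(all(diff(th) < 0))
  expect_true(all(diff(tq) > 0))
})
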