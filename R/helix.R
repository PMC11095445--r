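# Circular-helix model of a motion-corrected trajectory.
#
# Model: x(t) = c + (a0 + v t) u + R [cos(w t + phi) e1 + sin(w t + phi) e2]
# with (e1, e2, u) a right-handed orthonormal frame. The orbit radius R,
# pitch 2*pi*|v|/|w|, signed angular frequency w and axial speed v are the
# quantities of interest; sign(w) encodes handedness under the package
# convention (positive = CCW viewed along the swim direction from behind,
# i.e. a right-handed helix).

# internal: cylindrical decomposition of a trajectory about an axis through
# the centroid. Among the three principal directions of the centered cloud,
# the axis is the one minimizing the spread of radial distances: the first
# principal direction for straight lines and long helices, the plane normal
# for near-planar (low-pitch) orbits.
cylindrical <- function(traj) {
  m <- traj_matrix(traj)
  centroid <- colMeans(m)
  x <- sweep(m, 2, centroid)
  sv <- svd(x, nu = 0)
  spread <- apply(sv$v, 2, function(u) {
    a <- as.numeric(x %*% u)
    d <- x - outer(a, u)
    sd(sqrt(rowSums(d^2)))
  })
  u <- sv$v[, which.min(spread)]
  fit <- list(point = centroid, direction = u)
  if (sum(u * (m[nrow(m), ] - m[1, ])) < 0) u <- -u  # orient with net displacement
  b <- plane_basis(u)
  x <- sweep(m, 2, fit$point)
  a <- as.numeric(x %*% u)
  d <- x - outer(a, u)
  r <- sqrt(rowSums(d^2))
  theta_raw <- atan2(d %*% b$e2, d %*% b$e1)
  list(point = fit$point, u = u, e1 = b$e1, e2 = b$e2, a = a, r = r,
       theta_raw = as.numeric(theta_raw), m = m)
}

helix_model <- function(t, c0, u, e1, e2, a0, v, R, omega, phi) {
  ph <- omega * t + phi
  sweep(outer(a0 + v * t, u) + R * (outer(cos(ph), e1) + outer(sin(ph), e2)),
        2, c0, `+`)
}

#' Fit a circular helix to a motion-corrected trajectory
#'
#' Two-stage estimator. Stage 1 fits the straight displacement axis as the
#' total-least-squares line through the points (first principal direction of
#' the centered cloud), oriented with the net displacement. Stage 2 works in
#' cylindrical coordinates about that axis: the orbit radius is the mean
#' radial distance, the signed angular frequency is the slope of the
#' unwrapped polar angle versus time, the axial speed is the slope of the
#' axial coordinate versus time, and pitch = 2*pi*|axial speed|/|omega|
#' mm/turn. By default a joint Levenberg-Marquardt refinement of all nine
#' model parameters follows; the refined fit is kept only if it does not
#' increase the RMS residual.
#'
#' Trajectories whose radial excursion is indistinguishable from scatter
#' about a straight line (orbit radius below `3 * sd(radial distance)`) are
#' returned as non-rotating fits: orbit radius as measured, pitch, angular
#' frequency and handedness `NA`. A trajectory with a clearly nonzero orbit
#' radius but less than a quarter turn of phase progression is an error
#' (`hk_non_rotating_orbit`): the orbit cannot be distinguished from a
#' static offset.
#'
#' @param traj An `adjusted_trajectory` (or data frame with `t,x,y,z` in mm
#'   and s); >= 10 samples.
#' @param refine Run the joint Levenberg-Marquardt refinement (default
#'   `TRUE`).
#' @return A `helix_fit` object: list with `axis` (a `chain_axis`),
#'   `orbit_radius` (mm), `pitch` (mm/turn, `NA` for non-rotating fits),
#'   `angular_frequency` (signed rad/s), `axial_speed` (mm/s),
#'   `rms_residual` (mm), `handedness` (`"CW"`/`"CCW"`/`NA`), `rotating`
#'   (logical), `convention`, plus fitting internals.
#' @export
fit_helix <- function(traj, refine = TRUE) {
  traj <- as.data.frame(traj)
  if (nrow(traj) < 10)
    hk_stop("need >= 10 samples to fit a helix", "hk_insufficient_data")
  if (!all(is.finite(as.matrix(traj[, c("x", "y", "z")]))))
    hk_stop("non-finite coordinates", "hk_format_error")
  cyl <- cylindrical(traj)
  t <- traj$t
  R0 <- mean(cyl$r)
  s_r <- sd(cyl$r)
  rotating <- R0 > max(3 * s_r, 1e-9)
  theta <- unwrap_phase(cyl$theta_raw)
  axfit <- lm(cyl$a ~ t)
  v0 <- unname(coef(axfit)[2]); a00 <- unname(coef(axfit)[1])
  if (!rotating) {
    axis <- structure(list(point = cyl$point, direction = cyl$u,
                           rms_residual = sqrt(mean(cyl$r^2))),
                      class = "chain_axis")
    return(structure(list(axis = axis, orbit_radius = R0, pitch = NA_real_,
                          angular_frequency = NA_real_, axial_speed = v0,
                          rms_residual = sqrt(mean(cyl$r^2)),
                          handedness = NA_character_, rotating = FALSE,
                          convention = hk_convention(), t = t,
                          n = nrow(traj), data = cyl$m),
                     class = "helix_fit"))
  }
  if (abs(diff(range(theta))) < pi / 2)
    hk_stop("orbit radius well above scatter but phase progresses < pi/2: cannot distinguish an orbit from a static offset",
            "hk_non_rotating_orbit")
  phfit <- lm(theta ~ t)
  omega0 <- unname(coef(phfit)[2]); phi0 <- unname(coef(phfit)[1])
  par <- list(c0 = cyl$point, u = cyl$u, e1 = cyl$e1, e2 = cyl$e2, a0 = a00,
              v = v0, R = R0, omega = omega0, phi = phi0)
  rms_of <- function(p) {
    pred <- helix_model(t, p$c0, p$u, p$e1, p$e2, p$a0, p$v, p$R, p$omega, p$phi)
    sqrt(mean(rowSums((cyl$m - pred)^2)))
  }
  rms0 <- rms_of(par)
  if (refine) {
    ref <- refine_helix(cyl$m, t, par)
    if (!is.null(ref) && rms_of(ref) <= rms0 + 1e-12) {
      par <- ref
      rms0 <- rms_of(ref)
    }
  }
  # re-orient so u points along net displacement (sign of v)
  if (par$v < 0) {
    par$u <- -par$u; par$v <- -par$v; par$a0 <- -par$a0
    par$e2 <- -par$e2; par$omega <- -par$omega; par$phi <- -par$phi
  }
  axis <- structure(list(point = par$c0, direction = par$u,
                         rms_residual = rms0), class = "chain_axis")
  pitch <- 2 * pi * abs(par$v) / abs(par$omega)
  structure(list(axis = axis, orbit_radius = par$R, pitch = pitch,
                 angular_frequency = par$omega, axial_speed = par$v,
                 rms_residual = rms0,
                 handedness = if (par$omega > 0) "CCW" else "CW",
                 rotating = TRUE,
                 # near-planar circular orbit: negligible axial progress per
                 # turn, handedness sign not meaningful without displacement
                 planar = pitch < 0.01 * par$R,
                 convention = hk_convention(),
                 par = par, t = t, n = nrow(traj), data = cyl$m),
            class = "helix_fit")
}

# Joint Levenberg-Marquardt refinement. The axis point is constrained to
# the plane through the stage-1 centroid perpendicular to the stage-1
# direction (its axial position is absorbed by a0), and the direction is
# parameterized as u0 + s1 w1 + s2 w2, normalized, with (w1, w2) a fixed
# basis perpendicular to u0 — smooth everywhere and free of gimbal issues.
refine_helix <- function(m, t, init) {
  u0 <- init$u
  b <- plane_basis(u0)
  w1 <- b$e1; w2 <- b$e2
  unpack <- function(p) {
    u <- unitv(u0 + p[3] * w1 + p[4] * w2)
    bb <- plane_basis(u)
    list(c0 = init$c0 + p[1] * w1 + p[2] * w2, u = u, e1 = bb$e1, e2 = bb$e2,
         a0 = p[5], v = p[6], R = p[7], omega = p[8], phi = p[9])
  }
  # re-express the stage-1 phase in the canonical basis of u0 so the
  # starting residuals match the initializer
  resid_fn <- function(p) {
    q <- unpack(p)
    pred <- helix_model(t, q$c0, q$u, q$e1, q$e2, q$a0, q$v, q$R, q$omega, q$phi)
    as.numeric(m - pred)
  }
  start <- c(0, 0, 0, 0, init$a0, init$v, init$R, init$omega, init$phi)
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  q <- unpack(out$par)
  if (q$R < 0) {  # fold a negative radius into a phase shift
    q$R <- -q$R; q$phi <- q$phi + pi
  }
  q
}

#' @export
print.helix_fit <- function(x, digits = 4, ...) {
  if (x$rotating) {
    cat(sprintf("<helix_fit> n = %d samples\n", x$n))
    cat(sprintf("  orbit radius  %s mm\n", signif(x$orbit_radius, digits)))
    cat(sprintf("  pitch         %s mm/turn\n", signif(x$pitch, digits)))
    cat(sprintf("  omega         %s rad/s (%s)\n",
                signif(x$angular_frequency, digits), x$handedness))
    cat(sprintf("  axial speed   %s mm/s\n", signif(x$axial_speed, digits)))
    cat(sprintf("  rms residual  %s mm\n", signif(x$rms_residual, digits)))
  } else {
    cat(sprintf("<helix_fit> n = %d samples: non-rotating (straight) trajectory\n", x$n))
    cat(sprintf("  orbit radius  %s mm (at/below scatter); pitch not applicable\n",
                signif(x$orbit_radius, digits)))
    cat(sprintf("  axial speed   %s mm/s\n", signif(x$axial_speed, digits)))
  }
  invisible(x)
}

#' @export
summary.helix_fit <- function(object, ...) {
  cat("Circular-helix fit\n")
  print(object)
  cat("  convention:", object$convention, "\n")
  invisible(object)
}

#' @export
coef.helix_fit <- function(object, ...) {
  c(orbit_radius = object$orbit_radius, pitch = object$pitch,
    angular_frequency = object$angular_frequency,
    axial_speed = object$axial_speed)
}

#' @export
predict.helix_fit <- function(object, t = object$t, ...) {
  if (!object$rotating) {
    ax <- object$axis
    a <- object$axial_speed * (t - object$t[1])
    base <- sweep(outer(a, ax$direction), 2, ax$point, `+`)
    colnames(base) <- c("x", "y", "z")
    return(base)
  }
  p <- object$par
  out <- helix_model(t, p$c0, p$u, p$e1, p$e2, p$a0, p$v, p$R, p$omega, p$phi)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
residuals.helix_fit <- function(object, ...) {
  object$data - predict(object)
}

#' @export
fitted.helix_fit <- function(object, ...) predict(object)

#' @export
plot.helix_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  m <- x$data
  plot(m[, 1], m[, 2], type = "l", xlab = "x (mm)", ylab = "y (mm)",
       main = "trajectory (x-y projection)", asp = 1, ...)
  pred <- predict(x)
  lines(pred[, 1], pred[, 2], col = 2, lty = 2)
  res <- sqrt(rowSums((m - pred)^2))
  plot(x$t, res, type = "l", xlab = "t (s)", ylab = "|residual| (mm)",
       main = "fit residual", ...)
  invisible(x)
}

#' Simulate replicate trajectories from a fitted helix
#'
#' Draws `nsim` noisy realizations of the fitted helix, with isotropic
#' Gaussian noise of sd equal to the fit's RMS residual per axis (or
#' `sigma`).
#'
#' @param object A `helix_fit`.
#' @param nsim Number of replicates.
#' @param seed RNG seed.
#' @param sigma Noise sd in mm; defaults to `rms_residual / sqrt(3)`.
#' @param ... Unused.
#' @return List of data frames with `t, x, y, z`.
#' @export
simulate.helix_fit <- function(object, nsim = 1, seed = NULL,
                               sigma = object$rms_residual / sqrt(3), ...) {
  base <- predict(object)
  gen <- function() {
    m <- base + matrix(rnorm(length(base), 0, sigma), nrow(base))
    data.frame(t = object$t, x = m[, 1], y = m[, 2], z = m[, 3])
  }
  if (is.null(seed)) replicate(nsim, gen(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
}

#' Orbit radius of a trajectory
#'
#' Mean radial distance of the trajectory from its total-least-squares
#' displacement axis (stage 1 of [fit_helix()]).
#'
#' @param traj An `adjusted_trajectory` or data frame with `t,x,y,z`.
#' @return Radius in mm.
#' @export
orbit_radius <- function(traj) {
  traj <- as.data.frame(traj)
  if (nrow(traj) < 2) hk_stop("need >= 2 samples", "hk_insufficient_data")
  mean(cylindrical(traj)$r)
}
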