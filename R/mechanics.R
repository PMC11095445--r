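# Minimal rigid-chain multi-jet statics. Each zooid expels a jet from its
# excurrent siphon; the reaction force on the chain is minus the efflux
# direction times the jet magnitude. Obliquely oriented jets with a common
# chiral (tangential) sense produce axial thrust plus a net torque about
# the chain axis whose sign sets the spin handedness. Statics only: no
# drag, added mass, or rotational dynamics.

#' Specify a single jet
#'
#' @param attach_point Excurrent-siphon position in the chain frame, mm
#'   3-vector.
#' @param direction Jet efflux direction (normalized internally); the
#'   thrust on the body is along `-direction`.
#' @param magnitude Jet force in consistent (dimensionless) model units.
#' @param zooid_index Optional zooid number.
#' @return A `jet_spec` object.
#' @export
jet_spec <- function(attach_point, direction, magnitude = 1,
                     zooid_index = NA_integer_) {
  if (magnitude < 0) hk_stop("magnitude must be >= 0", "hk_parameter_error")
  structure(list(attach_point = as.numeric(attach_point),
                 direction = unitv(as.numeric(direction)),
                 magnitude = magnitude,
                 zooid_index = as.integer(zooid_index)),
            class = "jet_spec")
}

#' Net force and torque of a jet set about the chain axis
#'
#' The wrench of the jet reaction forces: `net_force = sum(m_i * (-d_i))`,
#' `axial_thrust = u . net_force`, and `axial_torque = u . sum((p_i - c) x
#' F_i)` about the axis point. Positive axial torque (right-hand rule about
#' the axis, which is oriented along the swim direction) predicts
#' counterclockwise spin viewed from behind — the same convention as the
#' kinematic handedness, so model and measurement are directly comparable.
#'
#' @param jets List of [jet_spec()] objects (>= 1).
#' @param axis A `chain_axis` (or list with `point` and unit `direction`).
#' @param tol |axial torque| below which no handedness is predicted.
#' @return A `jet_wrench`: list with `net_force`, `axial_thrust`,
#'   `axial_torque`, `torque` (full 3-vector), `predicted_handedness`
#'   (`"CW"`, `"CCW"` or `"none"`), `convention`.
#' @export
net_wrench <- function(jets, axis, tol = 1e-9) {
  if (!length(jets)) hk_stop("empty jet list", "hk_insufficient_input")
  u <- unitv(axis$direction)
  net_force <- c(0, 0, 0); torque <- c(0, 0, 0)
  for (j in jets) {
    f <- -j$magnitude * j$direction
    net_force <- net_force + f
    torque <- torque + cross3(j$attach_point - axis$point, f)
  }
  axial_torque <- sum(u * torque)
  structure(list(net_force = net_force,
                 axial_thrust = sum(u * net_force),
                 axial_torque = axial_torque, torque = torque,
                 predicted_handedness = if (abs(axial_torque) < tol) "none"
                                        else if (axial_torque > 0) "CCW"
                                        else "CW",
                 convention = hk_convention()),
            class = "jet_wrench")
}

#' @export
print.jet_wrench <- function(x, ...) {
  cat(sprintf("<jet_wrench> axial thrust %.4g, axial torque %.4g (force units, force units * mm)\n",
              x$axial_thrust, x$axial_torque))
  cat(sprintf("  predicted handedness: %s\n", x$predicted_handedness))
  invisible(x)
}

#' Thrust-to-torque ratio of a tilted jet
#'
#' For a unit jet tilted by `tilt_angle` from the chain axis with tangential
#' lever arm `lever_radius`: `cos(theta) / (lever_radius * sin(theta))`.
#' Strictly decreasing in the tilt on (0, 90) degrees — low-angle jets
#' maximize forward thrust and minimize torque. At 0 degrees the ratio is
#' infinite (all thrust, no torque) and is returned as `Inf`.
#'
#' @param tilt_angle Degrees, in \[0, 90\].
#' @param lever_radius mm (> 0).
#' @return Dimensionless ratio per unit force (1/mm).
#' @export
thrust_torque_ratio <- function(tilt_angle, lever_radius) {
  if (tilt_angle < 0 || tilt_angle > 90)
    hk_stop("tilt_angle must lie in [0, 90] degrees", "hk_parameter_error")
  if (lever_radius <= 0)
    hk_stop("lever_radius must be > 0", "hk_parameter_error")
  th <- tilt_angle * pi / 180
  if (tilt_angle == 0) return(Inf)
  cos(th) / (lever_radius * sin(th))
}

#' Build an idealized chain jet set
#'
#' Constructs one jet per zooid on a straight chain along +z: attach points
#' uniformly spaced along the axis at the given lever radius, alternating
#' dorsal/ventral sides (chiral, not rotational, symmetry between serial
#' neighbors). Each efflux direction starts anti-parallel to the axis, is
#' tilted by the dorsoventral angle in the radial plane and by the lateral
#' angle in the tangential plane; all tangential components share the same
#' sign (the common chiral sense), so any nonzero lateral angle yields a net
#' axial torque while a purely dorsoventral tilt does not.
#'
#' @param n_zooids Number of jets (>= 1).
#' @param spacing Axial spacing between siphons, mm (>= 0).
#' @param dv_angle Dorsoventral tilt, degrees in \[0, 90).
#' @param lat_angle Lateral tilt, degrees in \[0, 90).
#' @param radius Lever radius (siphon offset from the chain axis), mm.
#' @return List of [jet_spec()] objects; the matching axis is
#'   `chain_axis_z()`.
#' @export
build_chain_jets <- function(n_zooids, spacing = 4, dv_angle = 22.3,
                             lat_angle = 22.2, radius = 5) {
  if (n_zooids < 1) hk_stop("n_zooids must be >= 1", "hk_parameter_error")
  if (spacing < 0) hk_stop("spacing must be >= 0", "hk_parameter_error")
  if (dv_angle < 0 || dv_angle >= 90 || lat_angle < 0 || lat_angle >= 90)
    hk_stop("angles must lie in [0, 90) degrees", "hk_parameter_error")
  u <- c(0, 0, 1)
  dv <- dv_angle * pi / 180; lat <- lat_angle * pi / 180
  jets <- vector("list", n_zooids)
  for (i in seq_len(n_zooids)) {
    side <- if (i %% 2 == 1) 1 else -1  # alternate dorsal/ventral
    rhat <- c(side, 0, 0)
    that <- cross3(u, rhat)  # tangential sense: common chirality
    d <- -cos(dv) * cos(lat) * u + sin(dv) * rhat + cos(dv) * sin(lat) * that
    jets[[i]] <- jet_spec(attach_point = radius * rhat + (i - 1) * spacing * u,
                          direction = d, magnitude = 1, zooid_index = i)
  }
  jets
}

#' Canonical chain axis along +z
#'
#' @param point Axis point, mm 3-vector.
#' @return A `chain_axis` with direction `(0, 0, 1)`.
#' @export
chain_axis_z <- function(point = c(0, 0, 0)) {
  structure(list(point = point, direction = c(0, 0, 1), rms_residual = 0),
            class = "chain_axis")
}
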