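#' Field conditions for spin-lock preparation
#'
#' Bundles the off-resonance and B1-scale state of a voxel (or simulation
#' cell) together with the derived tilted-frame quantities: the angular
#' off-resonance \eqn{\Delta\omega_0 = 2\pi\Delta f_0}, the effective
#' spin-lock amplitude, the tilt angle
#' \eqn{\theta = \arctan(\Delta\omega_0/\omega_{SL})} of the effective field
#' away from the nominal lock axis, and the effective precession rate
#' \eqn{\omega_e = \sqrt{\omega_{SL}^2 + \Delta\omega_0^2}}.
#'
#' Two B1-error models are supported. In `"coupled"` mode a single
#' multiplicative scale acts on the hard-pulse flip angles *and* on the
#' spin-lock amplitude (so it also enters \eqn{\theta} and \eqn{\omega_e}).
#' In `"pulses_only"` mode the scale perturbs only the nominal 90\eqn{^\circ}
#' and 180\eqn{^\circ} flip angles while the spin-lock amplitude stays
#' nominal; this is the perturbation model used by the published simulation
#' protocols, where flip-angle errors are dialled in directly.
#'
#' @param delta_f0 off-resonance in Hz.
#' @param b1_scale dimensionless multiplicative B1 factor
#'   (`0.75` means a -25\% B1 deviation).
#' @param f_sl nominal spin-lock frequency in Hz; must be positive.
#' @param b1_mode `"coupled"` or `"pulses_only"`; see Details.
#' @return An object of class `"field_conditions"`: a list with the inputs
#'   plus `delta_omega0`, `omega_sl_eff`, `theta`, `omega_e`, and the scaled
#'   pulse angles `alpha` (90 deg) and `beta` (180 deg), all angles in
#'   radians and angular frequencies in rad/s.
#' @examples
#' f <- field_conditions(delta_f0 = 350, b1_scale = 0.75, f_sl = 500)
#' f$theta                       # atan(350/375)
#' effective_frequency(f)        # Hz
#' @export
field_conditions <- function(delta_f0 = 0, b1_scale = 1, f_sl = 500,
                             b1_mode = c("coupled", "pulses_only")) {
  b1_mode <- match.arg(b1_mode)
  stopifnot(is.finite(delta_f0), is.finite(b1_scale), is.finite(f_sl),
            f_sl > 0)
  omega_sl_nominal <- 2 * pi * f_sl
  omega_sl_eff <- if (b1_mode == "coupled") omega_sl_nominal * b1_scale
                  else omega_sl_nominal
  if (omega_sl_eff <= 0)
    stop("effective spin-lock amplitude must be positive; tilt angle undefined")
  delta_omega0 <- 2 * pi * delta_f0
  structure(list(
    delta_f0 = delta_f0,
    b1_scale = b1_scale,
    f_sl = f_sl,
    b1_mode = b1_mode,
    delta_omega0 = delta_omega0,
    omega_sl_eff = omega_sl_eff,
    theta = atan2(delta_omega0, omega_sl_eff),
    omega_e = sqrt(omega_sl_eff^2 + delta_omega0^2),
    alpha = (pi / 2) * b1_scale,
    beta = pi * b1_scale
  ), class = "field_conditions")
}

#' @export
print.field_conditions <- function(x, ...) {
  cat(sprintf(
    "field conditions: df0 = %g Hz, B1 scale = %g (%s), fSL = %g Hz\n",
    x$delta_f0, x$b1_scale, x$b1_mode, x$f_sl))
  cat(sprintf("  theta = %.4f rad, fe = %.2f Hz\n",
              x$theta, x$omega_e / (2 * pi)))
  invisible(x)
}

#' Tilt angle of the effective spin-lock field
#'
#' @param fields a [field_conditions()] object.
#' @return Tilt angle \eqn{\theta} in radians, in \eqn{(-\pi/2, \pi/2)}.
#' @export
tilt_angle <- function(fields) {
  stopifnot(inherits(fields, "field_conditions"))
  fields$theta
}

#' Effective spin-lock frequency
#'
#' Magnitude of the effective field in frequency units,
#' \eqn{f_e = \sqrt{f_{SL,eff}^2 + \Delta f_0^2}}.
#'
#' @inheritParams tilt_angle
#' @return Effective frequency in Hz.
#' @export
effective_frequency <- function(fields) {
  stopifnot(inherits(fields, "field_conditions"))
  fields$omega_e / (2 * pi)
}

#' Rotating-frame relaxation parameters
#'
#' @param t1rho decay constant parallel to the spin-lock axis, seconds.
#' @param t2rho decay constant perpendicular to the spin-lock axis, seconds.
#' @param enabled set `FALSE` to disable relaxation (identity decay matrix),
#'   which turns every propagator into a pure rotation.
#' @return An object of class `"relaxation_params"`.
#' @examples
#' relaxation_params(0.05, 0.05)
#' relaxation_params(0.05, 0.01)   # T1rho:T2rho = 5:1
#' @export
relaxation_params <- function(t1rho, t2rho = t1rho, enabled = TRUE) {
  stopifnot(is.finite(t1rho), is.finite(t2rho), t1rho > 0, t2rho > 0,
            is.logical(enabled), length(enabled) == 1L)
  structure(list(t1rho = t1rho, t2rho = t2rho, enabled = enabled),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("relaxation: T1rho = %g s, T2rho = %g s%s\n",
              x$t1rho, x$t2rho, if (x$enabled) "" else " (disabled)"))
  invisible(x)
}
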