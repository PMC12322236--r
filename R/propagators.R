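#' Elementary rotation matrix
#'
#' 3x3 rotation of the magnetization vector about a principal axis of the
#' rotating frame. The convention is the left-handed, clockwise one used
#' throughout the spin-lock literature this package follows:
#' \deqn{R_x(\psi) = \begin{pmatrix} 1 & 0 & 0 \\ 0 & \cos\psi & \sin\psi \\
#'   0 & -\sin\psi & \cos\psi \end{pmatrix}}
#' and analogously for y and z. All downstream closed-form results depend on
#' this sign convention, so it is pinned by regression tests and must not be
#' swapped for the right-handed form.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param psi rotation angle in radians.
#' @return A 3x3 orthogonal matrix with determinant +1, acting on
#'   magnetization column vectors by left-multiplication.
#' @examples
#' rotation_matrix("x", pi / 2) %*% c(0, 0, 1)   # -> (0, 1, 0)
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), psi) {
  axis <- match.arg(axis)
  stopifnot(is.finite(psi), length(psi) == 1L)
  c_ <- cos(psi); s_ <- sin(psi)
  switch(axis,
    x = matrix(c(1, 0, 0,
                 0, c_, s_,
                 0, -s_, c_), 3L, 3L, byrow = TRUE),
    y = matrix(c(c_, 0, -s_,
                 0, 1, 0,
                 s_, 0, c_), 3L, 3L, byrow = TRUE),
    z = matrix(c(c_, s_, 0,
                 -s_, c_, 0,
                 0, 0, 1), 3L, 3L, byrow = TRUE))
}

#' Rotating-frame relaxation matrix
#'
#' Diagonal decay over an interval `tau` with the spin-lock axis along y:
#' `diag(exp(-tau/T2rho), exp(-tau/T1rho), exp(-tau/T2rho))`. T1rho governs
#' the component parallel to the lock axis, T2rho the perpendicular ones.
#'
#' @param tau interval in seconds, non-negative.
#' @param relax a [relaxation_params()] object.
#' @return A 3x3 diagonal matrix; the identity when `tau = 0` or relaxation
#'   is disabled.
#' @export
relaxation_matrix <- function(tau, relax) {
  stopifnot(inherits(relax, "relaxation_params"),
            is.finite(tau), length(tau) == 1L)
  if (tau < 0) stop("tau must be non-negative")
  if (!relax$enabled || tau == 0) return(diag(3))
  e2 <- exp(-tau / relax$t2rho)
  diag(c(e2, exp(-tau / relax$t1rho), e2))
}

#' Hard-pulse propagator
#'
#' Instantaneous rotation for a nominal 90 degree excitation (about x) or
#' 180 degree refocusing pulse (about y). The actual flip angle is the
#' nominal one multiplied by the B1 scale of `fields`; relaxation during
#' hard pulses is neglected.
#'
#' @param kind `"excite90"` or `"refocus180"`.
#' @param sign +1 or -1, the pulse phase (flips the rotation sense).
#' @param fields a [field_conditions()] object.
#' @return A 3x3 rotation matrix.
#' @export
hard_pulse <- function(kind = c("excite90", "refocus180"), sign = 1L,
                       fields) {
  kind <- match.arg(kind)
  stopifnot(sign %in% c(-1, 1), inherits(fields, "field_conditions"))
  if (kind == "excite90") rotation_matrix("x", sign * fields$alpha)
  else rotation_matrix("y", sign * fields$beta)
}

#' Tilted-frame spin-lock segment propagator
#'
#' Propagator for a spin-lock segment of duration `tau` with phase +y or -y.
#' Off-resonance is handled by transforming into the tilted rotating frame
#' (rotation about x by the tilt angle), applying the in-lock rotation and
#' relaxation there, and transforming back:
#' \deqn{SL_+(\tau) = R_x(-\theta)\,E_\rho(\tau)\,R_y(\omega\tau)\,R_x(\theta)}
#' \deqn{SL_-(\tau) = R_x(\theta-\pi)\,E_\rho(\tau)\,R_y(\omega\tau)\,R_x(\pi-\theta)}
#' The rightmost factor acts first in time.
#'
#' The in-lock rotation rate \eqn{\omega} is either the effective-field rate
#' \eqn{\omega_e} (`angle_mode = "effective"`, consistent with the tilted
#' frame geometry) or the spin-lock amplitude \eqn{\omega_{SL}}
#' (`angle_mode = "literal"`, the rate as printed in the classical
#' propagator expressions). The two coincide on resonance.
#'
#' @param phase_sign +1 for a +y spin-lock phase, -1 for -y.
#' @param tau segment duration in seconds.
#' @param fields a [field_conditions()] object.
#' @param relax a [relaxation_params()] object.
#' @param angle_mode `"effective"` or `"literal"`.
#' @return A 3x3 propagation matrix.
#' @export
sl_propagator <- function(phase_sign = 1L, tau, fields, relax,
                          angle_mode = c("effective", "literal")) {
  angle_mode <- match.arg(angle_mode)
  stopifnot(phase_sign %in% c(-1, 1),
            inherits(fields, "field_conditions"),
            inherits(relax, "relaxation_params"))
  if (tau < 0) stop("tau must be non-negative")
  th <- fields$theta
  omega <- if (angle_mode == "effective") fields$omega_e else fields$omega_sl_eff
  core <- relaxation_matrix(tau, relax) %*% rotation_matrix("y", omega * tau)
  if (phase_sign == 1L)
    rotation_matrix("x", -th) %*% core %*% rotation_matrix("x", th)
  else
    rotation_matrix("x", th - pi) %*% core %*% rotation_matrix("x", pi - th)
}
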