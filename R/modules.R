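#' Define a spin-lock preparation module
#'
#' A preparation module is an ordered event program: it starts and ends with
#' a 90 degree hard pulse, and in between alternates spin-lock segments
#' (each a fraction of the total spin-lock time TSL) with optional 180
#' degree refocusing pulses. Events are stored in temporal order; the full
#' propagator multiplies them in reverse order so that the first event acts
#' first on the magnetization.
#'
#' @param name label for the module.
#' @param events list of events, each created by [ev_pulse()] or [ev_sl()],
#'   in temporal order.
#' @return An object of class `"sl_module"`.
#' @seealso [sl_preset()] for the four standard modules,
#'   [sl_n_refocused()] for generic n-refocused variants.
#' @export
sl_module <- function(name, events) {
  stopifnot(is.character(name), length(name) == 1L, is.list(events))
  types <- vapply(events, `[[`, "", "type")
  kinds <- vapply(events, function(e)
    if (e$type == "pulse") e$kind else "sl", "")
  if (kinds[1L] != "excite90" || kinds[length(kinds)] != "excite90")
    stop("first and last events must be 90 degree pulses")
  fr <- vapply(events[types == "sl"], `[[`, 0, "fraction")
  if (length(fr) == 0L) stop("module must contain spin-lock segments")
  if (abs(sum(fr) - 1) > 1e-12)
    stop("spin-lock segment fractions must sum to 1")
  # refocusing pulses must sit between SL segments, not at the ends
  ref_idx <- which(kinds == "refocus180")
  for (i in ref_idx) {
    if (i == 1L || i == length(events) ||
        types[i - 1L] != "sl" || types[i + 1L] != "sl")
      stop("refocusing pulses must lie between spin-lock segments")
  }
  structure(list(name = name, events = events), class = "sl_module")
}

#' Hard-pulse event
#' @param kind `"excite90"` or `"refocus180"`.
#' @param sign pulse phase sign, +1 or -1.
#' @return An event list for [sl_module()].
#' @export
ev_pulse <- function(kind = c("excite90", "refocus180"), sign = 1L) {
  kind <- match.arg(kind)
  stopifnot(sign %in% c(-1, 1))
  list(type = "pulse", kind = kind, sign = as.integer(sign))
}

#' Spin-lock segment event
#' @param sign spin-lock phase sign, +1 (+y) or -1 (-y).
#' @param fraction fraction of the total spin-lock time TSL.
#' @return An event list for [sl_module()].
#' @export
ev_sl <- function(sign = 1L, fraction) {
  stopifnot(sign %in% c(-1, 1), is.finite(fraction), fraction > 0,
            fraction <= 1)
  list(type = "sl", sign = as.integer(sign), fraction = fraction)
}

#' @export
print.sl_module <- function(x, ...) {
  lab <- vapply(x$events, function(e) {
    if (e$type == "pulse") {
      ang <- if (e$kind == "excite90") "90" else "180"
      sprintf("%s(%s)", ang, if (e$sign > 0) "+" else "-")
    } else {
      sprintf("SL%s(%s)", if (e$sign > 0) "+" else "-",
              format(e$fraction))
    }
  }, "")
  cat(sprintf("<sl_module> %s: %s\n", x$name, paste(lab, collapse = " ")))
  invisible(x)
}

#' Standard spin-lock preparation modules
#'
#' Builds the four standard hard-pulse preparation modules:
#' \describe{
#'   \item{`"csl"`}{composite SL: rotary-echo split (1/2, 1/2) around one
#'     refocusing pulse, closing 90 pulse with phase +x.}
#'   \item{`"bsl"`}{balanced SL: fractions (1/4, 1/2, 1/4) around a +y/-y
#'     refocusing pair, closing 90 pulse with phase -x.}
#'   \item{`"trsl"`}{triple-refocused SL: four quarter segments, refocusing
#'     phases (+, +, -) in time.}
#'   \item{`"qrsl"`}{quadruple-refocused SL: five segments with fractions
#'     (1/8, 1/4, 1/4, 1/4, 1/8), rotary-echo phase cycling of the lock
#'     segments, refocusing phases (+, +, -, -) in time, closing 90 pulse
#'     with phase -x.}
#' }
#'
#' @param name one of `"csl"`, `"bsl"`, `"trsl"`, `"qrsl"` (case
#'   insensitive).
#' @return An [sl_module()] object.
#' @examples
#' sl_preset("qrsl")
#' @export
sl_preset <- function(name = c("csl", "bsl", "trsl", "qrsl")) {
  name <- match.arg(tolower(name), c("csl", "bsl", "trsl", "qrsl"))
  ev <- switch(name,
    csl = list(
      ev_pulse("excite90", 1L),
      ev_sl(1L, 1 / 2), ev_pulse("refocus180", 1L), ev_sl(-1L, 1 / 2),
      ev_pulse("excite90", 1L)),
    bsl = list(
      ev_pulse("excite90", 1L),
      ev_sl(1L, 1 / 4), ev_pulse("refocus180", 1L),
      ev_sl(-1L, 1 / 2), ev_pulse("refocus180", -1L),
      ev_sl(1L, 1 / 4),
      ev_pulse("excite90", -1L)),
    trsl = list(
      ev_pulse("excite90", 1L),
      ev_sl(1L, 1 / 4), ev_pulse("refocus180", 1L),
      ev_sl(-1L, 1 / 4), ev_pulse("refocus180", 1L),
      ev_sl(1L, 1 / 4), ev_pulse("refocus180", -1L),
      ev_sl(-1L, 1 / 4),
      ev_pulse("excite90", 1L)),
    qrsl = list(
      ev_pulse("excite90", 1L),
      ev_sl(1L, 1 / 8), ev_pulse("refocus180", 1L),
      ev_sl(-1L, 1 / 4), ev_pulse("refocus180", 1L),
      ev_sl(1L, 1 / 4), ev_pulse("refocus180", -1L),
      ev_sl(-1L, 1 / 4), ev_pulse("refocus180", -1L),
      ev_sl(1L, 1 / 8),
      ev_pulse("excite90", -1L)))
  sl_module(name, ev)
}

#' Generic n-refocused spin-lock module
#'
#' Builds a module with `n_refocus` refocusing pulses and `n_refocus + 1`
#' spin-lock segments. The two end segments get half the interior width
#' (fractions `1/(2 n)` at the ends, `1/n` inside), generalizing the
#' 1/8-1/4 pattern of the quadruple-refocused module; `n_refocus = 1`
#' degenerates to the rotary-echo (1/2, 1/2) split. Spin-lock phases
#' alternate starting from `sl_phase_start`.
#'
#' @param n_refocus number of 180 degree refocusing pulses (>= 1).
#' @param refocus_phases vector of +1/-1 refocusing phases in temporal
#'   order; length must equal `n_refocus`.
#' @param sl_phase_start phase sign of the first spin-lock segment.
#' @param final_90_sign phase sign of the closing 90 degree pulse.
#' @param name optional label.
#' @return An [sl_module()] object. `sl_n_refocused(4, c(1, 1, -1, -1),
#'   final_90_sign = -1)` reproduces `sl_preset("qrsl")` exactly.
#' @export
sl_n_refocused <- function(n_refocus, refocus_phases,
                           sl_phase_start = 1L, final_90_sign = 1L,
                           name = NULL) {
  stopifnot(n_refocus >= 1L, length(refocus_phases) == n_refocus,
            all(refocus_phases %in% c(-1, 1)),
            sl_phase_start %in% c(-1, 1), final_90_sign %in% c(-1, 1))
  n_seg <- n_refocus + 1L
  fr <- rep(1 / n_refocus, n_seg)
  fr[c(1L, n_seg)] <- 1 / (2 * n_refocus)
  sl_sign <- sl_phase_start * (-1L)^(seq_len(n_seg) - 1L)
  ev <- list(ev_pulse("excite90", 1L))
  for (i in seq_len(n_seg)) {
    ev <- c(ev, list(ev_sl(sl_sign[i], fr[i])))
    if (i <= n_refocus)
      ev <- c(ev, list(ev_pulse("refocus180", refocus_phases[i])))
  }
  ev <- c(ev, list(ev_pulse("excite90", as.integer(final_90_sign))))
  if (is.null(name))
    name <- sprintf("n%d[%s]", n_refocus,
                    paste(ifelse(refocus_phases > 0, "+", "-"),
                          collapse = ""))
  sl_module(name, ev)
}

#' Full module propagation matrix
#'
#' Composes the per-event propagators of a module into the single 3x3
#' matrix acting on the ground-state magnetization. Events stored in
#' temporal order are multiplied in reverse order (rightmost factor acts
#' first).
#'
#' @param spec an [sl_module()] object.
#' @param t_sl total spin-lock time in seconds (scalar).
#' @param fields a [field_conditions()] object.
#' @param relax a [relaxation_params()] object.
#' @param angle_mode `"effective"` or `"literal"`, see [sl_propagator()].
#' @return A 3x3 matrix.
#' @export
module_propagator <- function(spec, t_sl, fields, relax,
                              angle_mode = c("effective", "literal")) {
  angle_mode <- match.arg(angle_mode)
  stopifnot(inherits(spec, "sl_module"), length(t_sl) == 1L, t_sl >= 0)
  B <- diag(3)
  for (e in spec$events) {
    P <- if (e$type == "pulse") hard_pulse(e$kind, e$sign, fields)
         else sl_propagator(e$sign, e$fraction * t_sl, fields, relax,
                            angle_mode)
    B <- P %*% B
  }
  B
}

#' Longitudinal magnetization after preparation
#'
#' z-component of the prepared magnetization starting from the ground state
#' (0, 0, 1), evaluated for a whole vector of spin-lock times at once. This
#' is the workhorse of all simulation protocols; the propagation is applied
#' event by event to a 3 x n state matrix, so the cost is linear in the
#' number of events regardless of how many TSL values are requested.
#'
#' @inheritParams module_propagator
#' @param t_sl vector of spin-lock times in seconds.
#' @return Numeric vector of Mz values, one per element of `t_sl`.
#' @examples
#' qr <- sl_preset("qrsl")
#' f0 <- field_conditions(0, 1, 500)
#' rl <- relaxation_params(0.05)
#' mz_after_prep(qr, 0.05, f0, rl)   # exp(-1)
#' @export
mz_after_prep <- function(spec, t_sl, fields, relax,
                          angle_mode = c("effective", "literal")) {
  angle_mode <- match.arg(angle_mode)
  stopifnot(inherits(spec, "sl_module"),
            inherits(fields, "field_conditions"),
            inherits(relax, "relaxation_params"))
  if (any(t_sl < 0)) stop("t_sl must be non-negative")
  n <- length(t_sl)
  mx <- numeric(n); my <- numeric(n); mz <- rep(1, n)
  th <- fields$theta
  omega <- if (angle_mode == "effective") fields$omega_e
           else fields$omega_sl_eff
  rot_x <- function(psi) {  # psi scalar
    c_ <- cos(psi); s_ <- sin(psi)
    y2 <- c_ * my + s_ * mz
    mz <<- -s_ * my + c_ * mz
    my <<- y2
  }
  rot_y_vec <- function(psi) {  # psi vector
    c_ <- cos(psi); s_ <- sin(psi)
    x2 <- c_ * mx - s_ * mz
    mz <<- s_ * mx + c_ * mz
    mx <<- x2
  }
  for (e in spec$events) {
    if (e$type == "pulse") {
      if (e$kind == "excite90") rot_x(e$sign * fields$alpha)
      else rot_y_vec(rep(e$sign * fields$beta, n))
    } else {
      tau <- e$fraction * t_sl
      if (e$sign == 1L) rot_x(th) else rot_x(pi - th)
      rot_y_vec(omega * tau)
      if (relax$enabled) {
        e2 <- exp(-tau / relax$t2rho)
        mx <- mx * e2
        my <- my * exp(-tau / relax$t1rho)
        mz <- mz * e2
      }
      if (e$sign == 1L) rot_x(-th) else rot_x(th - pi)
    }
  }
  mz
}

#' Serialize a module to JSON
#'
#' @param spec an [sl_module()] object.
#' @param path optional file to write; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
module_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "sl_module"))
  x <- list(name = spec$name, events = spec$events)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a module from JSON
#'
#' @param x JSON string or path to a JSON file.
#' @return An [sl_module()] object (revalidated on read).
#' @export
module_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  events <- lapply(obj$events, function(e) {
    if (e$type == "pulse") ev_pulse(e$kind, as.integer(e$sign))
    else ev_sl(as.integer(e$sign), as.numeric(e$fraction))
  })
  sl_module(obj$name, events)
}
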