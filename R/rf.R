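# RF amplitude bookkeeping: per-module RMS RF integrals as a SAR proxy.

#' RF amplitude timeline of a preparation module
#'
#' Expands a module into an ordered (amplitude, duration) table at nominal
#' amplitudes: hard pulses play at `flip / (2 pi duration)` — 250 Hz for a
#' 1 ms 90 degree pulse, 500 Hz for a 1 ms 180 — and spin-lock segments
#' play at the spin-lock frequency for their fraction of TSL.
#'
#' @param spec an [sl_module()] object or preset name.
#' @param f_sl spin-lock frequency in Hz.
#' @param t_sl total spin-lock time in seconds.
#' @param pulse_dur hard-pulse duration in seconds (default 1 ms).
#' @return `data.frame` with columns `event`, `amplitude_hz`,
#'   `duration_s`; total duration is `t_sl + n_pulses * pulse_dur`.
#' @export
rf_timeline <- function(spec, f_sl, t_sl, pulse_dur = 0.001) {
  if (is.character(spec)) spec <- sl_preset(spec)
  stopifnot(inherits(spec, "sl_module"), f_sl > 0, t_sl >= 0,
            pulse_dur > 0)
  rows <- lapply(spec$events, function(e) {
    if (e$type == "pulse") {
      flip <- if (e$kind == "excite90") pi / 2 else pi
      data.frame(event = e$kind,
                 amplitude_hz = flip / (2 * pi * pulse_dur),
                 duration_s = pulse_dur, stringsAsFactors = FALSE)
    } else {
      data.frame(event = "sl", amplitude_hz = f_sl,
                 duration_s = e$fraction * t_sl, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' RMS RF amplitude of a timeline
#'
#' \eqn{\sqrt{\sum_i A_i^2 d_i / W}} with `W` either the timeline's own
#' duration (`window = "module"`) or a fixed window. Depends only on the
#' amplitude histogram, not the event order.
#'
#' @param timeline a [rf_timeline()] data frame.
#' @param window `"module"` or `"fixed"`.
#' @param window_s window length in seconds when `window = "fixed"`; must
#'   be at least the timeline duration.
#' @return RMS amplitude in Hz.
#' @export
rms_rf <- function(timeline, window = c("module", "fixed"),
                   window_s = NULL) {
  window <- match.arg(window)
  tot <- sum(timeline$duration_s)
  w <- if (window == "module") tot else {
    if (is.null(window_s) || window_s <= 0) stop("window_s required")
    if (window_s < tot) stop("fixed window shorter than the timeline")
    window_s
  }
  sqrt(sum(timeline$amplitude_hz^2 * timeline$duration_s) / w)
}

#' Relative RMS increase between two modules
#'
#' @param rms_a,rms_b RMS amplitudes in Hz (numerator / reference).
#' @return Percent increase, `(rms_a / rms_b - 1) * 100`.
#' @export
rf_relative_increase <- function(rms_a, rms_b) {
  (rms_a / rms_b - 1) * 100
}

#' RMS RF report over a grid of frequencies and spin-lock times
#'
#' Tabulates per-module RMS amplitudes and the relative increase over the
#' composite module for a grid of `f_sl` and `t_sl` values (mirroring the
#' typical phantom acquisition grid). By default every module at a given
#' setting is averaged over a common window — the duration of the longest
#' module in the comparison — so that modules with different pulse counts
#' are compared on equal footing, as they would be within a fixed
#' repetition time.
#'
#' @param presets character vector of preset names.
#' @param f_sl_list spin-lock frequencies in Hz.
#' @param t_sl_list spin-lock times in seconds.
#' @param window `"common"` (default, see above), `"module"` or `"fixed"`.
#' @param window_s window length for `window = "fixed"`.
#' @return `data.frame` with columns module, f_sl, t_sl, rms_hz,
#'   rel_increase_vs_csl.
#' @export
rf_report <- function(presets = c("csl", "bsl", "trsl", "qrsl"),
                      f_sl_list = c(100, 500, 1000),
                      t_sl_list = c(0.004, 0.038, 0.040, 0.042, 0.044),
                      window = c("common", "module", "fixed"),
                      window_s = NULL) {
  window <- match.arg(window)
  rows <- list()
  for (f in f_sl_list) for (ts in t_sl_list) {
    tls <- lapply(unique(c("csl", presets)), rf_timeline, f_sl = f,
                  t_sl = ts)
    names(tls) <- unique(c("csl", presets))
    w <- window; ws <- window_s
    if (window == "common") {
      w <- "fixed"
      ws <- max(vapply(tls, function(x) sum(x$duration_s), 0))
    }
    ref <- rms_rf(tls[["csl"]], w, ws)
    for (p in presets) {
      r <- rms_rf(tls[[p]], w, ws)
      rows[[length(rows) + 1L]] <- data.frame(
        module = p, f_sl = f, t_sl = ts, rms_hz = r,
        rel_increase_vs_csl = rf_relative_increase(r, ref),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
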