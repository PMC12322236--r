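# Grid sweeps over B0/B1 field deviations and module comparisons.

#' Inhomogeneity sweep of a preparation module
#'
#' Computes the repetition-averaged quantization errors and the dense
#' trajectory residual for every cell of a B0 x B1 deviation grid. The
#' random spin-lock sampling points are drawn once from the master seed, so
#' sweeping several modules with the same seed gives cell-wise paired
#' comparisons. Cells are mutually independent; execution order does not
#' affect the result.
#'
#' @param spec an [sl_module()] object or preset name.
#' @param f_sl spin-lock frequency in Hz.
#' @param relax a [relaxation_params()] object.
#' @param b0_range off-resonance range in Hz, length-2.
#' @param b1_range fractional B1 deviation range, length-2
#'   (`c(-0.5, 0.5)` means B1 scales 0.5 to 1.5).
#' @param steps grid points per axis (recycled to length 2); endpoints are
#'   included.
#' @param n_reps repetitions per cell for the quantization error.
#' @param n_points random sampling points per repetition.
#' @param rng_seed master seed.
#' @param angle_mode passed to [mz_after_prep()].
#' @param b1_mode B1 error model (the published protocol perturbs pulse
#'   angles only).
#' @param n_dense dense-grid size for the trajectory residual.
#' @return Object of class `"sl_sweep"`: list with axis vectors `delta_f0`
#'   (Hz) and `db1` (fraction), matrices `dq_abs`, `dq_signed`,
#'   `dq_s0_abs`, `rss` (residual sum over the `n_dense` trajectory
#'   points) and `rss_mss` (mean-squared form), indexed [b0, b1], and the
#'   sweep metadata.
#' @export
inhomogeneity_sweep <- function(spec, f_sl = 500, relax,
                                b0_range = c(-600, 600),
                                b1_range = c(-0.5, 0.5),
                                steps = c(100, 100),
                                n_reps = 100, n_points = 8,
                                rng_seed = NULL,
                                angle_mode = c("effective", "literal"),
                                b1_mode = c("pulses_only", "coupled"),
                                n_dense = 200) {
  angle_mode <- match.arg(angle_mode)
  b1_mode <- match.arg(b1_mode)
  if (is.character(spec)) spec <- sl_preset(spec)
  stopifnot(inherits(spec, "sl_module"),
            inherits(relax, "relaxation_params"))
  steps <- rep(as.integer(steps), length.out = 2L)
  if (any(steps < 2)) stop("need at least 2 steps per axis")
  b0_grid <- seq(b0_range[1L], b0_range[2L], length.out = steps[1L])
  b1_grid <- seq(b1_range[1L], b1_range[2L], length.out = steps[2L])
  t_max <- 2 * relax$t1rho
  draws <- tsl_draws(n_reps, n_points, t_max, rng_seed)
  dims <- c(steps[1L], steps[2L])
  dq_abs <- dq_signed <- dq_s0_abs <- rss <- rss_mss <- array(NA_real_, dims)
  for (j in seq_along(b1_grid)) {
    for (i in seq_along(b0_grid)) {
      fields <- field_conditions(b0_grid[i], 1 + b1_grid[j], f_sl, b1_mode)
      q <- mean_delta_q(spec, fields, relax, angle_mode = angle_mode,
                        draws = draws)
      dq_abs[i, j] <- q$dq_abs
      dq_signed[i, j] <- q$dq_signed
      dq_s0_abs[i, j] <- q$dq_s0_abs
      rss[i, j] <- trajectory_rss(spec, fields, relax, n_dense = n_dense,
                                  angle_mode = angle_mode)
      rss_mss[i, j] <- rss[i, j] / n_dense
    }
  }
  structure(list(
    module = spec$name, f_sl = f_sl, relax = relax,
    delta_f0 = b0_grid, db1 = b1_grid,
    dq_abs = dq_abs, dq_signed = dq_signed, dq_s0_abs = dq_s0_abs,
    rss = rss, rss_mss = rss_mss, n_dense = n_dense,
    n_reps = n_reps, n_points = n_points, rng_seed = rng_seed,
    angle_mode = angle_mode, b1_mode = b1_mode
  ), class = "sl_sweep")
}

#' @export
print.sl_sweep <- function(x, ...) {
  cat(sprintf(
    "<sl_sweep> %s: %d x %d grid, df0 in [%g, %g] Hz, dB1 in [%g, %g]\n",
    x$module, length(x$delta_f0), length(x$db1),
    min(x$delta_f0), max(x$delta_f0), min(x$db1), max(x$db1)))
  cat(sprintf("  fSL = %g Hz, %d reps, angle_mode = %s, b1_mode = %s\n",
              x$f_sl, x$n_reps, x$angle_mode, x$b1_mode))
  invisible(x)
}

#' Proportion of grid cells meeting a robustness criterion
#'
#' @param sweep an `"sl_sweep"` object.
#' @param metric `"delta_q"` (repetition-averaged |dq|), `"rss"` (residual
#'   sum over the dense trajectory) or `"rss_mss"` (its mean-squared form).
#' @param threshold criterion threshold; defaults to 0.01 for both
#'   headline metrics (1\% quantization error, 0.01 residual sum).
#' @param signed use |signed mean| instead of the mean of absolute errors
#'   for the `"delta_q"` metric.
#' @return Fraction of grid cells in `[0, 1]` (cells with failed fits count
#'   as not meeting the criterion).
#' @export
proportion_within <- function(sweep, metric = c("delta_q", "rss", "rss_mss"),
                              threshold = 0.01, signed = FALSE) {
  stopifnot(inherits(sweep, "sl_sweep"))
  metric <- match.arg(metric)
  v <- switch(metric,
              delta_q = if (signed) abs(sweep$dq_signed) else sweep$dq_abs,
              rss = sweep$rss,
              rss_mss = sweep$rss_mss)
  mean(!is.na(v) & v < threshold)
}

#' Module robustness versus spin-lock frequency
#'
#' Runs [inhomogeneity_sweep()] for each module at each frequency (with
#' paired draws) and tabulates the proportions of cells meeting the
#' quantization-error and residual criteria.
#'
#' @param specs list of modules or character vector of preset names.
#' @param f_sl_list spin-lock frequencies in Hz (>= 2 unless you only want
#'   a single-frequency table).
#' @param relax a [relaxation_params()] object.
#' @param ... further arguments passed to [inhomogeneity_sweep()].
#' @return `data.frame` with columns module, f_sl, prop_dq, prop_rss.
#' @export
fsl_sweep <- function(specs, f_sl_list, relax, ...) {
  if (is.character(specs)) specs <- lapply(specs, sl_preset)
  rows <- list()
  for (f in f_sl_list) {
    for (sp in specs) {
      sw <- inhomogeneity_sweep(sp, f_sl = f, relax = relax, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        module = sp$name, f_sl = f,
        prop_dq = proportion_within(sw, "delta_q"),
        prop_rss = proportion_within(sw, "rss"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Module robustness versus relaxation-time ratio
#'
#' As [fsl_sweep()], but varying the T1rho:T2rho ratio at fixed T1rho and
#' spin-lock frequency.
#'
#' @param specs list of modules or character vector of preset names.
#' @param ratios T1rho:T2rho ratios (e.g. `c(1/5, 1/2, 1, 2, 5)`).
#' @param f_sl spin-lock frequency in Hz.
#' @param t1rho T1rho in seconds, held fixed; T2rho = t1rho / ratio.
#' @param ... further arguments passed to [inhomogeneity_sweep()].
#' @return `data.frame` with columns module, ratio, prop_dq, prop_rss.
#' @export
ratio_sweep <- function(specs, ratios, f_sl = 500, t1rho = 0.05, ...) {
  if (is.character(specs)) specs <- lapply(specs, sl_preset)
  rows <- list()
  for (r in ratios) {
    relax <- relaxation_params(t1rho, t1rho / r)
    for (sp in specs) {
      sw <- inhomogeneity_sweep(sp, f_sl = f_sl, relax = relax, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        module = sp$name, ratio = r,
        prop_dq = proportion_within(sw, "delta_q"),
        prop_rss = proportion_within(sw, "rss"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Refocusing-phase combination study
#'
#' Compares quadruple-refocused variants that differ only in the phase
#' pattern of the four 180 degree refocusing pulses. For each pattern a
#' grid sweep with shared seeds is run and the grid means of |dQ| and of
#' the trajectory residual are tabulated, ranked by residual.
#'
#' @param combos list of length-4 vectors of +1/-1 refocusing phases.
#'   Defaults to the six self-compensating patterns
#'   (+,+,-,-), (-,-,+,+), (+,-,-,+), (-,+,+,-), (+,-,+,-), (-,+,-,+).
#' @param f_sl spin-lock frequency in Hz.
#' @param relax a [relaxation_params()] object.
#' @param ... further arguments passed to [inhomogeneity_sweep()].
#' @return `data.frame` with columns combo, mean_dq, mean_rss, sorted by
#'   mean_rss.
#' @export
phase_combination_study <- function(combos = NULL, f_sl = 500, relax, ...) {
  if (is.null(combos))
    combos <- list(c(1, 1, -1, -1), c(-1, -1, 1, 1),
                   c(1, -1, -1, 1), c(-1, 1, 1, -1),
                   c(1, -1, 1, -1), c(-1, 1, -1, 1))
  rows <- lapply(combos, function(ph) {
    sp <- sl_n_refocused(4L, ph, final_90_sign = -1L)
    sw <- inhomogeneity_sweep(sp, f_sl = f_sl, relax = relax, ...)
    data.frame(combo = paste(ifelse(ph > 0, "+", "-"), collapse = ""),
               mean_dq = mean(sw$dq_abs, na.rm = TRUE),
               mean_rss = mean(sw$rss, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_rss), ]
}
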