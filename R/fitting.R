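# Mono-exponential relaxometry fitting and quantization-error metrics.

# run expr with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw random spin-lock times
#'
#' Draws `n` spin-lock times i.i.d. uniform on `[0, t_max]` and sorts them.
#' With a seed the draw is reproducible, and reusing the same seed across
#' modules yields identical (paired) sampling points.
#'
#' @param n number of points (>= 3: two fit parameters plus one).
#' @param t_max upper end of the sampling window in seconds (conventionally
#'   twice the true T1rho).
#' @param rng_seed optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return Sorted numeric vector of length `n`.
#' @export
sample_tsl <- function(n = 8, t_max, rng_seed = NULL) {
  if (n < 3) stop("need at least 3 sampling points")
  stopifnot(is.finite(t_max), t_max > 0)
  with_seed(rng_seed, sort(stats::runif(n, 0, t_max)))
}

#' Pre-drawn spin-lock time matrix for repeated simulations
#'
#' Draws the sampling points for a whole repetition block up front, so the
#' identical draws can be reused across preparation modules for paired
#' comparisons.
#'
#' @param n_reps number of repetitions.
#' @param n_points points per repetition.
#' @param t_max sampling window upper end in seconds.
#' @param rng_seed integer seed.
#' @return `n_reps` x `n_points` matrix, each row sorted.
#' @export
tsl_draws <- function(n_reps, n_points, t_max, rng_seed = NULL) {
  stopifnot(n_reps >= 1, n_points >= 3, t_max > 0)
  with_seed(rng_seed, {
    m <- matrix(stats::runif(n_reps * n_points, 0, t_max),
                nrow = n_reps, byrow = TRUE)
    t(apply(m, 1L, sort))
  })
}

#' Fit a mono-exponential decay
#'
#' Unweighted two-parameter nonlinear least squares of
#' \eqn{S(t) = S_0\,e^{-t/T_{1\rho}}} via Levenberg-Marquardt with an
#' analytic Jacobian, initialized from the log-linear fit of the positive
#' samples. There is no offset term.
#'
#' @param t sampling times in seconds.
#' @param y signal values; with `magnitude = TRUE` the fit uses `abs(y)`,
#'   matching magnitude-image relaxometry.
#' @param magnitude fit the absolute value of `y`.
#' @return Object of class `"sl_fit"`: list with `s0`, `t1rho_fit`
#'   (seconds), `residuals` (data minus model), `fitted`, `converged`.
#'   Degenerate inputs (all zero, non-decaying) are flagged via
#'   `converged = FALSE` rather than raising.
#' @examples
#' t <- seq(0.005, 0.1, length.out = 8)
#' f <- fit_monoexponential(t, 0.8 * exp(-t / 0.05))
#' c(f$s0, f$t1rho_fit)
#' @export
fit_monoexponential <- function(t, y, magnitude = FALSE) {
  stopifnot(length(t) == length(y), length(t) >= 3,
            all(is.finite(t)), all(is.finite(y)))
  if (magnitude) y <- abs(y)
  out <- structure(list(s0 = NA_real_, t1rho_fit = NA_real_,
                        residuals = rep(NA_real_, length(y)),
                        fitted = rep(NA_real_, length(y)),
                        converged = FALSE, n = length(y)),
                   class = "sl_fit")
  if (all(abs(y) < .Machine$double.eps)) return(out)
  # log-linear init on clearly positive samples
  pos <- y > max(abs(y)) * 1e-6
  if (sum(pos) >= 2L) {
    cf <- stats::lm.fit(cbind(1, -t[pos]), log(y[pos]))$coefficients
    s0_0 <- exp(cf[[1L]]); r0 <- max(cf[[2L]], 1 / (1e3 * max(t)))
  } else {
    s0_0 <- max(abs(y)); r0 <- 1 / mean(t)
  }
  res_fn <- function(p) y - p[1L] * exp(-p[2L] * t)
  jac_fn <- function(p) {
    e <- exp(-p[2L] * t)
    cbind(-e, p[1L] * t * e)
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = c(s0_0, r0), fn = res_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  s0 <- fit$par[1L]; rate <- fit$par[2L]
  ok <- fit$info %in% 1:4 && is.finite(s0) && is.finite(rate) &&
    rate > 0 && (1 / rate) < 1e3 * max(t)
  out$s0 <- s0
  out$t1rho_fit <- 1 / rate
  out$fitted <- s0 * exp(-rate * t)
  out$residuals <- y - out$fitted
  out$converged <- ok
  out
}

#' @export
print.sl_fit <- function(x, ...) {
  cat(sprintf("mono-exponential fit: S0 = %.6g, T1rho = %.6g s (%s)\n",
              x$s0, x$t1rho_fit,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Relative T1rho quantization error of a single fit
#'
#' \eqn{\Delta q = T_{1\rho,fit}/T_{1\rho,true} - 1}.
#'
#' @param fit an `"sl_fit"` object from [fit_monoexponential()].
#' @param t1rho_true reference T1rho in seconds.
#' @return Dimensionless error; `NA` for a non-converged fit.
#' @export
delta_q <- function(fit, t1rho_true) {
  stopifnot(inherits(fit, "sl_fit"), t1rho_true > 0)
  if (!fit$converged) return(NA_real_)
  fit$t1rho_fit / t1rho_true - 1
}

#' Repetition-averaged quantization error of a preparation module
#'
#' Implements the repeated random-sampling protocol: per repetition, draw
#' `n_points` spin-lock times uniformly in `[0, t_max]`, evaluate the
#' prepared |Mz| at each, fit the mono-exponential model, and record the
#' relative errors of the fitted T1rho (against `relax$t1rho`) and of the
#' fitted amplitude S0 (against the true initial magnetization, 1). Both
#' the signed mean and the mean of absolute errors are reported; the
#' absolute mean is the headline number, since signed means of oscillatory
#' bias largely cancel.
#'
#' @param spec an [sl_module()] object.
#' @param fields a [field_conditions()] object.
#' @param relax a [relaxation_params()] object.
#' @param n_reps number of repetitions.
#' @param n_points sampling points per repetition.
#' @param t_max sampling window; default `2 * relax$t1rho`.
#' @param rng_seed integer seed; the same seed gives identical draws, so
#'   passing one seed to several modules yields paired comparisons.
#' @param angle_mode passed to [mz_after_prep()].
#' @param magnitude fit |Mz| (default) rather than signed Mz.
#' @param draws optional pre-drawn matrix from [tsl_draws()]; overrides
#'   `rng_seed`.
#' @return Object of class `"sl_quant_error"`: list with per-repetition
#'   vectors `dq`, `dq_s0`, aggregates `dq_abs`, `dq_signed`, `dq_s0_abs`,
#'   `dq_s0_signed`, and `n_failed` (non-converged repetitions, excluded
#'   from the means).
#' @export
mean_delta_q <- function(spec, fields, relax, n_reps = 100, n_points = 8,
                         t_max = 2 * relax$t1rho, rng_seed = NULL,
                         angle_mode = c("effective", "literal"),
                         magnitude = TRUE, draws = NULL) {
  angle_mode <- match.arg(angle_mode)
  if (is.null(draws))
    draws <- tsl_draws(n_reps, n_points, t_max, rng_seed)
  stopifnot(is.matrix(draws))
  n_reps <- nrow(draws)
  # one vectorized propagation for the whole block
  mz <- mz_after_prep(spec, as.vector(t(draws)), fields, relax, angle_mode)
  mz <- matrix(mz, nrow = n_reps, byrow = TRUE)
  dq <- dq_s0 <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    ft <- fit_monoexponential(draws[i, ], mz[i, ], magnitude = magnitude)
    if (ft$converged) {
      dq[i] <- ft$t1rho_fit / relax$t1rho - 1
      dq_s0[i] <- ft$s0 - 1
    }
  }
  structure(list(
    module = spec$name,
    dq = dq, dq_s0 = dq_s0,
    dq_abs = mean(abs(dq), na.rm = TRUE),
    dq_signed = mean(dq, na.rm = TRUE),
    dq_s0_abs = mean(abs(dq_s0), na.rm = TRUE),
    dq_s0_signed = mean(dq_s0, na.rm = TRUE),
    n_failed = sum(is.na(dq)), n_reps = n_reps
  ), class = "sl_quant_error")
}

#' @export
print.sl_quant_error <- function(x, ...) {
  cat(sprintf(
    "%s: mean |dq| = %.4g%% (signed %.4g%%), |dS0| = %.4g%%, %d/%d failed\n",
    x$module, 100 * x$dq_abs, 100 * x$dq_signed, 100 * x$dq_s0_abs,
    x$n_failed, x$n_reps))
  invisible(x)
}

#' Residual sum of squares of the dense Mz trajectory
#'
#' Evaluates |Mz| on a dense uniform TSL grid in `[0, t_max]`, fits the
#' mono-exponential model, and returns the residual sum of squares — the
#' banding-artifact susceptibility metric. With `normalize = TRUE` the mean
#' squared residual is returned instead, which is insensitive to the grid
#' size.
#'
#' @inheritParams mean_delta_q
#' @param n_dense number of grid points (>= 20).
#' @param normalize return the mean squared residual instead of the sum.
#' @return Scalar RSS (or MSS); `NA` if the trajectory fit fails.
#' @export
trajectory_rss <- function(spec, fields, relax, n_dense = 200,
                           t_max = 2 * relax$t1rho, normalize = FALSE,
                           angle_mode = c("effective", "literal")) {
  angle_mode <- match.arg(angle_mode)
  if (n_dense < 20) stop("n_dense must be at least 20")
  tg <- seq(0, t_max, length.out = n_dense)
  mz <- mz_after_prep(spec, tg, fields, relax, angle_mode)
  ft <- fit_monoexponential(tg, mz, magnitude = TRUE)
  if (!ft$converged) return(NA_real_)
  if (normalize) mean(ft$residuals^2) else sum(ft$residuals^2)
}

#' Quantization-error and artifact table for a set of modules
#'
#' Convenience driver for the single-condition comparison: runs
#' [mean_delta_q()] and [trajectory_rss()] for each module with paired
#' sampling draws and returns one row per module.
#'
#' @param specs list of [sl_module()] objects (or a character vector of
#'   preset names).
#' @param delta_f0 off-resonance in Hz.
#' @param db1 fractional B1 deviation (e.g. `-0.25` for -25\%).
#' @param f_sl spin-lock frequency in Hz.
#' @param relax a [relaxation_params()] object.
#' @param b1_mode B1 error model; the simulation protocols perturb the
#'   pulse flip angles only, hence the default.
#' @inheritParams mean_delta_q
#' @return `data.frame` with columns module, f_sl, delta_f0, db1,
#'   dQ_abs, dQ_signed, dQ_s0_abs, rss, n_failed (errors as fractions,
#'   not percent).
#' @export
quant_error_table <- function(specs, delta_f0, db1, f_sl, relax,
                              n_reps = 100, n_points = 8,
                              t_max = 2 * relax$t1rho, rng_seed = NULL,
                              angle_mode = c("effective", "literal"),
                              b1_mode = c("pulses_only", "coupled")) {
  angle_mode <- match.arg(angle_mode)
  b1_mode <- match.arg(b1_mode)
  if (identical(specs, "all")) specs <- c("csl", "bsl", "trsl", "qrsl")
  if (is.character(specs)) specs <- lapply(specs, sl_preset)
  if (inherits(specs, "sl_module")) specs <- list(specs)
  fields <- field_conditions(delta_f0, 1 + db1, f_sl, b1_mode)
  draws <- tsl_draws(n_reps, n_points, t_max, rng_seed)
  rows <- lapply(specs, function(sp) {
    q <- mean_delta_q(sp, fields, relax, angle_mode = angle_mode,
                      draws = draws)
    data.frame(module = sp$name, f_sl = f_sl, delta_f0 = delta_f0,
               db1 = db1,
               dQ_abs = q$dq_abs, dQ_signed = q$dq_signed,
               dQ_s0_abs = q$dq_s0_abs,
               rss = trajectory_rss(sp, fields, relax, t_max = t_max,
                                    normalize = TRUE,
                                    angle_mode = angle_mode),
               n_failed = q$n_failed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
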