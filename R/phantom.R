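# Digital tube phantom: geometry, field maps, image synthesis, and the
# field-map estimation operators used to characterize B0/B1 conditions.

#' Digital tube phantom
#'
#' Rasterizes a set of circular tubes onto a 2-D voxel grid. The default
#' geometry mirrors a typical multi-tube relaxometry phantom: five 20-mm
#' tubes in a 120 x 120 mm field of view on a 200 x 200 matrix, arranged
#' as a quincunx. The default per-tube T1rho values (80, 65, 52, 43, 36 ms,
#' T2rho equal) are synthetic placeholders in the range typical of agarose
#' gels of increasing concentration; they are configuration, not measured
#' values.
#'
#' @param matrix_size grid size, length-2 integer.
#' @param fov_mm field of view in mm, length-2.
#' @param centers_mm n x 2 matrix of tube centers in mm (FOV-centered
#'   axes, x increasing with column index).
#' @param diameter_mm tube diameter(s) in mm, recycled.
#' @param t1rho per-tube T1rho in seconds.
#' @param t2rho per-tube T2rho in seconds; defaults to `t1rho`.
#' @param proton_density per-tube proton density, recycled.
#' @return Object of class `"digital_phantom"`: list with integer `label`
#'   matrix (0 = background), voxel-center coordinate vectors `x_mm`,
#'   `y_mm`, `fov_mm`, and per-tube parameter data frame `params`.
#' @export
make_tube_phantom <- function(matrix_size = c(200L, 200L),
                              fov_mm = c(120, 120),
                              centers_mm = NULL,
                              diameter_mm = 20,
                              t1rho = c(0.080, 0.065, 0.052, 0.043, 0.036),
                              t2rho = t1rho,
                              proton_density = 1) {
  if (is.null(centers_mm))
    centers_mm <- rbind(c(-25, -25), c(-25, 25), c(25, -25), c(25, 25),
                        c(0, 0))[seq_along(t1rho), , drop = FALSE]
  centers_mm <- as.matrix(centers_mm)
  n_tube <- nrow(centers_mm)
  stopifnot(length(t1rho) == n_tube, length(t2rho) == n_tube,
            all(t1rho > 0), all(t2rho > 0))
  diameter_mm <- rep(diameter_mm, length.out = n_tube)
  proton_density <- rep(proton_density, length.out = n_tube)
  if (any(abs(centers_mm[, 1L]) + diameter_mm / 2 > fov_mm[1L] / 2) ||
      any(abs(centers_mm[, 2L]) + diameter_mm / 2 > fov_mm[2L] / 2))
    stop("tube extends beyond the field of view")
  if (n_tube > 1L) {
    d <- as.matrix(stats::dist(centers_mm))
    rad <- diameter_mm / 2
    for (a in seq_len(n_tube - 1L)) for (b in (a + 1L):n_tube)
      if (d[a, b] < rad[a] + rad[b]) stop("tubes overlap")
  }
  nx <- matrix_size[1L]; ny <- matrix_size[2L]
  # voxel centers, FOV-centered; x varies with the row index of the matrix
  x_mm <- (seq_len(nx) - (nx + 1) / 2) * fov_mm[1L] / nx
  y_mm <- (seq_len(ny) - (ny + 1) / 2) * fov_mm[2L] / ny
  label <- matrix(0L, nx, ny)
  xg <- matrix(x_mm, nx, ny)
  yg <- matrix(y_mm, nx, ny, byrow = TRUE)
  for (k in seq_len(n_tube)) {
    inside <- (xg - centers_mm[k, 1L])^2 + (yg - centers_mm[k, 2L])^2 <=
      (diameter_mm[k] / 2)^2
    label[inside] <- k
  }
  structure(list(
    label = label, x_mm = x_mm, y_mm = y_mm, fov_mm = fov_mm,
    params = data.frame(tube = seq_len(n_tube),
                        t1rho = t1rho, t2rho = t2rho,
                        proton_density = proton_density,
                        diameter_mm = diameter_mm,
                        cx_mm = centers_mm[, 1L], cy_mm = centers_mm[, 2L])
  ), class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %d x %d over %g x %g mm, %d tube(s)\n",
              nrow(x$label), ncol(x$label), x$fov_mm[1L], x$fov_mm[2L],
              nrow(x$params)))
  invisible(x)
}

#' Spatial B0/B1 field maps for a phantom
#'
#' Builds per-voxel off-resonance and B1-scale maps on the phantom grid.
#' The `"x_gradient"` B0 mode applies a linear ramp along x, zero at the
#' FOV center; specify it either as a total span across the FOV or as a
#' gradient in Hz/cm. The B1 map is a uniform scale.
#'
#' @param phantom a [make_tube_phantom()] object (supplies the geometry).
#' @param b0_mode `"uniform"` (constant `b0_offset_hz`) or `"x_gradient"`.
#' @param b0_span_hz length-2 off-resonance values at the FOV x-edges for
#'   the gradient mode; default `c(-58, 58)`.
#' @param gradient_hz_per_cm alternative gradient specification; overrides
#'   `b0_span_hz` when given.
#' @param b0_offset_hz constant off-resonance for the uniform mode.
#' @param b1_scale global B1 scale (0.8 means a -20\% deviation).
#' @return Object of class `"field_maps"`: list with matrices
#'   `delta_f0` (Hz) and `b1_scale`.
#' @export
make_field_maps <- function(phantom, b0_mode = c("uniform", "x_gradient"),
                            b0_span_hz = c(-58, 58),
                            gradient_hz_per_cm = NULL,
                            b0_offset_hz = 0, b1_scale = 1) {
  b0_mode <- match.arg(b0_mode)
  stopifnot(inherits(phantom, "digital_phantom"), is.finite(b1_scale))
  nx <- length(phantom$x_mm); ny <- length(phantom$y_mm)
  if (b0_mode == "uniform") {
    df0 <- matrix(b0_offset_hz, nx, ny)
  } else {
    slope_hz_per_mm <- if (!is.null(gradient_hz_per_cm))
      gradient_hz_per_cm / 10
    else diff(b0_span_hz) / phantom$fov_mm[1L]
    df0 <- matrix(phantom$x_mm * slope_hz_per_mm, nx, ny)
  }
  structure(list(delta_f0 = df0,
                 b1_scale = matrix(b1_scale, nx, ny)),
            class = "field_maps")
}

#' Synthesize a T1rho-weighted image series
#'
#' Forward model of the phantom experiment: for every voxel the signal at
#' each spin-lock time is the proton density times |Mz| after the
#' preparation module, evaluated under the voxel's local field conditions.
#' The readout is an ideal sampler of the prepared magnetization. Optional
#' noise is complex Gaussian on two quadrature channels, giving a Rician
#' magnitude.
#'
#' @param phantom a [make_tube_phantom()] object.
#' @param spec an [sl_module()] object or preset name.
#' @param tsl spin-lock times in seconds.
#' @param maps a [make_field_maps()] object.
#' @param f_sl spin-lock frequency in Hz.
#' @param noise_sigma standard deviation of the per-channel Gaussian noise
#'   (0 disables noise).
#' @param rng_seed seed for the noise draw.
#' @param angle_mode passed to [mz_after_prep()].
#' @param b1_mode B1 error model; flip-angle-only by default, matching how
#'   B1 deviations are dialled into a scanner protocol.
#' @return Array `nx x ny x length(tsl)` of magnitude images.
#' @export
synthesize_weighted_series <- function(phantom, spec, tsl, maps, f_sl,
                                       noise_sigma = 0, rng_seed = NULL,
                                       angle_mode = c("effective", "literal"),
                                       b1_mode = c("pulses_only", "coupled")) {
  angle_mode <- match.arg(angle_mode)
  b1_mode <- match.arg(b1_mode)
  if (is.character(spec)) spec <- sl_preset(spec)
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(maps, "field_maps"), length(tsl) >= 1)
  nx <- length(phantom$x_mm); ny <- length(phantom$y_mm)
  if (!all(dim(maps$delta_f0) == c(nx, ny)))
    stop("field map geometry does not match the phantom")
  stack <- array(0, c(nx, ny, length(tsl)))
  lab <- phantom$label
  vox <- which(lab > 0L)
  if (length(vox)) {
    # group voxels sharing (tube, df0, b1): one propagation per group
    key <- paste(lab[vox], maps$delta_f0[vox], maps$b1_scale[vox])
    groups <- split(vox, key)
    nt <- length(tsl)
    for (g in groups) {
      v1 <- g[1L]
      k <- lab[v1]
      relax <- relaxation_params(phantom$params$t1rho[k],
                                 phantom$params$t2rho[k])
      fields <- field_conditions(maps$delta_f0[v1], maps$b1_scale[v1],
                                 f_sl, b1_mode)
      sig <- phantom$params$proton_density[k] *
        abs(mz_after_prep(spec, tsl, fields, relax, angle_mode))
      for (m in seq_len(nt)) stack[g + (m - 1L) * nx * ny] <- sig[m]
    }
  }
  if (noise_sigma > 0) {
    stack <- with_seed(rng_seed, {
      n <- length(stack)
      re <- stack + stats::rnorm(n, 0, noise_sigma)
      im <- stats::rnorm(n, 0, noise_sigma)
      array(sqrt(re^2 + im^2), dim(stack))
    })
  }
  stack
}

#' Dual-echo B0 map
#'
#' Off-resonance from the phase difference of two echoes:
#' \eqn{\Delta f_0 = \mathrm{wrap}(\varphi_2 - \varphi_1) /
#' (2\pi(TE_2 - TE_1))}, with the difference wrapped to \eqn{(-\pi, \pi]}.
#' The unambiguous range is \eqn{\pm 1/(2\,\Delta TE)} (±500 Hz at the
#' default echo times); aliasing beyond it is not unwrapped.
#'
#' @param phase_te1,phase_te2 phase maps in radians at the two echo times.
#' @param te1,te2 echo times in seconds; `te2 > te1`.
#' @return Off-resonance map in Hz.
#' @export
b0_map_dual_te <- function(phase_te1, phase_te2,
                           te1 = 0.0025, te2 = 0.0035) {
  stopifnot(all(dim(phase_te1) == dim(phase_te2)), te2 > te1)
  d <- phase_te2 - phase_te1
  wrapped <- atan2(sin(d), cos(d))
  wrapped / (2 * pi * (te2 - te1))
}

#' Double-angle B1 map
#'
#' B1 scale from two magnitude images acquired at nominal flip angles FA
#' and 2 FA: the actual angle is \eqn{\alpha = \arccos(S_2 / (2 S_1))} and
#' the scale is \eqn{\alpha / FA_{nominal}}.
#'
#' @param s1 magnitude image at the nominal flip angle `fa1`.
#' @param s2 magnitude image at twice the nominal flip angle.
#' @param fa1 nominal flip angle of `s1` in radians (default 60 degrees).
#' @return B1 scale map; voxels where `|s2 / (2 s1)| > 1` or `s1 <= 0` are
#'   `NA`, with the invalid count in attribute `"n_invalid"`.
#' @export
b1_map_double_angle <- function(s1, s2, fa1 = pi / 3) {
  stopifnot(all(dim(s1) == dim(s2)), fa1 > 0)
  ratio <- s2 / (2 * s1)
  bad <- !is.finite(ratio) | abs(ratio) > 1 | s1 <= 0
  ratio[bad] <- NA_real_
  out <- acos(ratio) / fa1
  attr(out, "n_invalid") <- sum(bad)
  out
}

#' Write a weighted image series as NIfTI with a JSON sidecar
#'
#' @param stack array `nx x ny x n_tsl` from
#'   [synthesize_weighted_series()].
#' @param tsl spin-lock times in seconds.
#' @param path output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json` (spin-lock times recorded in ms).
#' @param voxel_mm in-plane voxel size in mm, length-2.
#' @param meta named list of extra sidecar fields (module, fSL, seed, ...).
#' @return Invisibly, the NIfTI path.
#' @export
write_weighted_series <- function(stack, tsl, path, voxel_mm = c(0.6, 0.6),
                                  meta = list()) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3L] == length(tsl))
  img <- RNifti::asNifti(stack, pixdim = c(voxel_mm, 1))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii)
  sidecar <- c(list(tsl_ms = tsl * 1000), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(nii)
}

#' Read a weighted image series written by [write_weighted_series()]
#'
#' @param path path without extension.
#' @return List with `stack` (array) and `tsl` (seconds) plus any extra
#'   sidecar fields under `meta`.
#' @export
read_weighted_series <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  stack <- array(as.numeric(img), dim(img))
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  tsl <- sidecar$tsl_ms / 1000
  sidecar$tsl_ms <- NULL
  list(stack = stack, tsl = tsl, meta = sidecar)
}
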