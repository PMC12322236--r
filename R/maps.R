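# Pixel-wise parameter mapping and map-level residual metrics.

#' Pixel-wise T1rho map fitting
#'
#' Fits the mono-exponential model voxel by voxel across a stack of
#' differently T1rho-weighted images.
#'
#' @param stack 3-D array `nx x ny x n_tsl` of magnitude images, one slice
#'   per spin-lock time.
#' @param tsl spin-lock times in seconds, one per stack slice (>= 3).
#' @param mask logical `nx x ny` matrix of voxels to fit; defaults to
#'   voxels with any non-zero signal.
#' @return List with matrices `t1rho`, `s0`, `rss` (per-voxel residual sum
#'   of squares), logical `converged`, and the count `n_failed`. Voxels
#'   outside the mask are `NA`.
#' @export
fit_t1rho_map <- function(stack, tsl, mask = NULL) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3L] == length(tsl))
  if (length(tsl) < 3) stop("need at least 3 spin-lock times")
  nx <- dim(stack)[1L]; ny <- dim(stack)[2L]
  if (is.null(mask)) mask <- apply(stack != 0, c(1L, 2L), any)
  stopifnot(is.logical(mask), all(dim(mask) == c(nx, ny)))
  t1 <- s0 <- rss <- matrix(NA_real_, nx, ny)
  conv <- matrix(FALSE, nx, ny)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    ft <- fit_monoexponential(tsl, stack[i, j, ], magnitude = TRUE)
    if (ft$converged) {
      t1[i, j] <- ft$t1rho_fit
      s0[i, j] <- ft$s0
      rss[i, j] <- sum(ft$residuals^2)
      conv[i, j] <- TRUE
    }
  }
  list(t1rho = t1, s0 = s0, rss = rss, converged = conv,
       n_failed = nrow(idx) - sum(conv))
}

#' Relative residual map between two parameter maps
#'
#' Computes the voxel-wise relative residual `(test - ref) / ref` and the
#' scalar residual metric as the mean of squared relative residuals over
#' the mask. Relative residuals make the metric comparable across phantoms
#' with different absolute relaxation scales.
#'
#' @param map_test parameter map under perturbed conditions.
#' @param map_ref reference map (matching geometry).
#' @param mask logical matrix; defaults to voxels finite in both maps.
#' @return List with `residual` (matrix) and `rss` (scalar mean squared
#'   relative residual); voxels that are `NA` in either map are excluded.
#' @export
residual_rss_map <- function(map_test, map_ref, mask = NULL) {
  stopifnot(all(dim(map_test) == dim(map_ref)))
  ok <- is.finite(map_test) & is.finite(map_ref) & map_ref != 0
  if (is.null(mask)) mask <- ok else mask <- mask & ok
  if (!any(mask)) stop("empty mask")
  res <- matrix(NA_real_, nrow(map_test), ncol(map_test))
  res[mask] <- (map_test[mask] - map_ref[mask]) / map_ref[mask]
  list(residual = res, rss = mean(res[mask]^2))
}
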