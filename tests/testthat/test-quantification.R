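test_that("sample_tsl is deterministic under seed and uniform on the window", {
  a <- sample_tsl(8, 0.1, rng_seed = 31)
  b <- sample_tsl(8, 0.1, rng_seed = 31)
  expect_identical(a, b)
  expect_length(a, 8)
  expect_true(all(a >= 0 & a <= 0.1))
  expect_false(is.unsorted(a))
  expect_error(sample_tsl(2, 0.1))
  # moment check: empirical mean within 3 standard errors of t_max/2
  n <- 1e5
  draws <- sample_tsl(n, 1, rng_seed = 77)
  se <- (1 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("tsl_draws pairs across modules and respects the seed", {
  d1 <- tsl_draws(20, 8, 0.1, rng_seed = 5)
  d2 <- tsl_draws(20, 8, 0.1, rng_seed = 5)
  expect_identical(d1, d2)
  expect_equal(dim(d1), c(20, 8))
  expect_true(all(apply(d1, 1, function(r) !is.unsorted(r))))
  # seed restoration: global RNG stream unaffected
  set.seed(1); x1 <- stats::runif(3)
  set.seed(1); invisible(tsl_draws(5, 4, 0.1, rng_seed = 9))
  x2 <- stats::runif(3)
  expect_identical(x1, x2)
})

test_that("exact exponential data are recovered to high precision", {
  set.seed(8)
  t <- sort(stats::runif(8, 0.001, 0.1))
  f <- fit_monoexponential(t, 0.8 * exp(-t / 0.05))
  expect_true(f$converged)
  expect_equal(f$s0, 0.8, tolerance = 1e-9)
  expect_equal(f$t1rho_fit, 0.05, tolerance = 1e-9)
  # 100 random parameter draws
  for (i in 1:100) {
    s0 <- stats::runif(1, 0.1, 2)
    t1 <- stats::runif(1, 0.01, 0.2)
    tt <- sort(stats::runif(10, 0, 2 * t1))
    ft <- fit_monoexponential(tt, s0 * exp(-tt / t1))
    expect_true(ft$converged)
    expect_lt(abs(ft$s0 / s0 - 1), 1e-8)
    expect_lt(abs(ft$t1rho_fit / t1 - 1), 1e-8)
  }
})

test_that("magnitude fitting recovers inverted trajectories exactly", {
  f0 <- field_conditions(0, 1, 500)
  rl <- relaxation_params(0.05, 0.02)
  t <- seq(0.005, 0.1, length.out = 8)
  y <- mz_after_prep(sl_preset("csl"), t, f0, rl)  # negative branch
  expect_true(all(y < 0))
  ft <- fit_monoexponential(t, y, magnitude = TRUE)
  expect_true(ft$converged)
  expect_equal(ft$t1rho_fit, 0.05, tolerance = 1e-9)
})

test_that("degenerate inputs are flagged, not raised", {
  t <- seq(0.01, 0.1, length.out = 6)
  expect_false(fit_monoexponential(t, rep(0, 6))$converged)
  expect_false(fit_monoexponential(t, rep(0.7, 6))$converged)
})

test_that("delta_q is the exact ratio error and NA when not converged", {
  t <- seq(0.005, 0.1, length.out = 8)
  ft <- fit_monoexponential(t, exp(-t / 0.05))
  expect_equal(delta_q(ft, 0.05), 0, tolerance = 1e-9)
  expect_equal(delta_q(ft, 0.05 / 1.1), 0.1, tolerance = 1e-8)
  expect_equal(delta_q(ft, 0.05 / 0.9), -0.1, tolerance = 1e-8)
  bad <- fit_monoexponential(t, rep(0, 8))
  expect_true(is.na(delta_q(bad, 0.05)))
})

test_that("quantization error vanishes under ideal fields for all presets", {
  f0 <- field_conditions(0, 1, 500)
  rl <- relaxation_params(0.05, 0.02)
  for (m in c("csl", "bsl", "trsl", "qrsl")) {
    q <- mean_delta_q(sl_preset(m), f0, rl, n_reps = 10, rng_seed = 3)
    expect_equal(q$dq_abs, 0, tolerance = 1e-7)
    expect_equal(q$dq_s0_abs, 0, tolerance = 1e-7)
    expect_equal(q$n_failed, 0)
  }
})

test_that("metrics are invariant to overall trajectory sign and time units", {
  rl1 <- relaxation_params(0.05, 0.05)
  rl2 <- relaxation_params(0.5, 0.5)   # all times scaled by 10
  f <- field_conditions(350, 0.75, 500, "pulses_only")
  # time-unit invariance requires scaling fSL and df0 down by 10 too
  f2 <- field_conditions(35, 0.75, 50, "pulses_only")
  q1 <- mean_delta_q(sl_preset("qrsl"), f, rl1, n_reps = 20, rng_seed = 17,
                     angle_mode = "literal")
  q2 <- mean_delta_q(sl_preset("qrsl"), f2, rl2, n_reps = 20, rng_seed = 17,
                     angle_mode = "literal")
  expect_equal(q1$dq_abs, q2$dq_abs, tolerance = 1e-6)
  # C-SL (negative branch) and its mirrored trajectory give identical
  # magnitude-fit metrics
  r1 <- trajectory_rss(sl_preset("csl"), f, rl1, angle_mode = "literal")
  expect_true(is.finite(r1) && r1 >= 0)
  q_c <- mean_delta_q(sl_preset("csl"), f, rl1, n_reps = 20, rng_seed = 17,
                      angle_mode = "literal", magnitude = TRUE)
  expect_true(is.finite(q_c$dq_abs))
})

test_that("trajectory residual behaves across field conditions", {
  rl <- relaxation_params(0.05, 0.05)
  f0 <- field_conditions(0, 1, 500)
  expect_lt(trajectory_rss(sl_preset("qrsl"), f0, rl), 1e-18)
  f <- field_conditions(350, 0.75, 500, "pulses_only")
  rss_qr <- trajectory_rss(sl_preset("qrsl"), f, rl, angle_mode = "literal")
  rss_b <- trajectory_rss(sl_preset("bsl"), f, rl, angle_mode = "literal")
  expect_lt(rss_qr, rss_b)
  # discretization stability of the normalized form
  m1 <- trajectory_rss(sl_preset("qrsl"), f, rl, n_dense = 200,
                       normalize = TRUE, angle_mode = "literal")
  m2 <- trajectory_rss(sl_preset("qrsl"), f, rl, n_dense = 400,
                       normalize = TRUE, angle_mode = "literal")
  expect_lt(abs(m2 / m1 - 1), 0.1)
})

test_that("pixel-wise map fitting round-trips and matches the direct fit", {
  ph <- make_tube_phantom(matrix_size = c(40, 40), fov_mm = c(120, 120))
  tsl <- c(0.004, 0.02, 0.04, 0.06, 0.08)
  maps0 <- make_field_maps(ph, "uniform")
  st <- synthesize_weighted_series(ph, "qrsl", tsl, maps0, 500)
  fit <- fit_t1rho_map(st, tsl)
  for (k in ph$params$tube) {
    vox <- ph$label == k
    expect_lt(max(abs(fit$t1rho[vox] / ph$params$t1rho[k] - 1)), 1e-6)
  }
  expect_equal(fit$n_failed, 0)
  # single-voxel stack equals the direct fit
  i <- which(ph$label == 1, arr.ind = TRUE)[1, ]
  single <- array(st[i[1], i[2], ], c(1, 1, length(tsl)))
  f1 <- fit_t1rho_map(single, tsl, mask = matrix(TRUE, 1, 1))
  fd <- fit_monoexponential(tsl, st[i[1], i[2], ], magnitude = TRUE)
  expect_equal(f1$t1rho[1, 1], fd$t1rho_fit)
  expect_error(fit_t1rho_map(st[, , 1:2], tsl[1:2]))
})

test_that("relative residual maps quantify uniform deviations exactly", {
  ref <- matrix(stats::runif(100, 0.02, 0.1), 10, 10)
  z <- residual_rss_map(ref, ref)
  expect_equal(z$rss, 0)
  expect_true(all(z$residual == 0))
  r10 <- residual_rss_map(1.1 * ref, ref)
  expect_equal(r10$rss, 0.01, tolerance = 1e-12)
  expect_error(residual_rss_map(ref, ref, mask = matrix(FALSE, 10, 10)),
               "empty mask")
})
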