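# Radar DSP: phase round trip, unwrapping, zero-phase filtering, ridge
# closed form, orthogonalization, overlap-add, decimation, alignment.

test_that("phase-to-displacement round-trips a noiseless clutter-free cube", {
  # Forward model and recovery must agree to 1e-9 m up to an additive
  # constant. The modulation depth is set at the first Bessel-J0 zero over
  # whole periods so the oscillation's complex mean vanishes and the static
  # (DC/clutter) term is exactly what per-bin mean removal cancels.
  fs <- 50
  f0 <- 0.25
  n <- 40 / f0 * fs                      # integer breathing periods
  lambda <- radar_wavelength(60e9)
  amp <- 2.404826 * lambda / (4 * pi)    # ~0.96 mm at 60 GHz
  d_true <- amp * sin(2 * pi * f0 * seq_len(n) / fs)
  z <- exp(1i * (4 * pi / lambda) * d_true) + 2   # static offset 2
  cube <- range_bin_cube(matrix(z, ncol = 1L), fs)
  rec <- phase_to_displacement(cube, lambda)$X[, 1L]
  err <- rec - d_true
  expect_lt(max(abs(err - mean(err))), 1e-9)
})

test_that("simulated cube plus recovery reproduces the mixed displacement", {
  fs <- 50; f0 <- 0.25
  n <- 20 / f0 * fs
  lambda <- radar_wavelength(60e9)
  amp <- 2.404826 * lambda / (4 * pi)
  chest <- amp * sin(2 * pi * f0 * seq_len(n) / fs)
  abd <- amp * sin(2 * pi * f0 * seq_len(n) / fs - 0.4)
  rp <- radar_sim_params(n_bins = 2L, per_bin_gain = c(1, 1),
                         per_bin_mix = c(1, 0), clutter_amp = 0,
                         phase_noise_sd = 0, seed = 2)
  cube <- simulate_radar_cube(chest, abd, rp)
  X <- phase_to_displacement(cube, lambda)$X
  err_c <- X[, 1L] - chest
  err_a <- X[, 2L] - abd
  expect_lt(max(abs(err_c - mean(err_c))), 1e-9)
  expect_lt(max(abs(err_a - mean(err_a))), 1e-9)
})

test_that("constant bins are flagged dead and phase ramps unwrap continuously", {
  cube <- range_bin_cube(matrix(exp(1i * 0.7), 100, 1), fs = 50)
  out <- phase_to_displacement(cube, 0.005)
  expect_true(out$dead_bins[1L])
  expect_true(all(out$X == 0))

  # ramp crossing +/- pi repeatedly: unwrapped output has no 2*pi jumps
  ramp <- seq(0, 40, length.out = 2000)
  un <- unwrap_phase(Arg(exp(1i * ramp)))
  expect_lt(max(abs(diff(un))), pi)
  expect_equal(un, ramp, tolerance = 1e-10)
})

test_that("band-pass is zero-phase, kills DC, preserves passband, attenuates stopband", {
  fs <- 50
  t <- seq_len(60 * fs) / fs
  dc <- rep(2, length(t))
  expect_lt(max(abs(bandpass_respiration(dc, fs, 0.1, 0.6))), 1e-6 * 2)

  x_in <- sin(2 * pi * 0.25 * t)
  y <- bandpass_respiration(x_in, fs, 0.1, 0.6)
  expect_length(y, length(x_in))
  expect_lt(abs(fitted_amplitude(y, fs, 0.25, trim_s = 10) - 1), 0.02)

  x_hi <- sin(2 * pi * 5 * t)
  y_hi <- bandpass_respiration(x_hi, fs, 0.1, 0.6)
  expect_lt(fitted_amplitude(y_hi, fs, 5, trim_s = 10), 10^(-20 / 20))

  # zero phase: cross-correlation peak lag of a band-limited signal is 0
  cc <- ccf(y[500:2500], x_in[500:2500], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass_respiration(rnorm(10), fs, 0.1, 0.6), "warm-up")
  expect_error(bandpass_respiration(x_in, fs, 0.6, 0.1), "low_hz")
})

test_that("ridge weights match the closed form and shrink monotonically", {
  withr::with_seed(31, {
    X <- matrix(rnorm(15), 5, 3)
    y <- rnorm(5)
  })
  for (alpha in c(1e-3, 0.5, 10)) {
    w_pkg <- ridge_weights(X, y, alpha)
    w_oracle <- solve(t(X) %*% X + alpha * diag(3)) %*% t(X) %*% y
    expect_lt(max(abs(w_pkg - w_oracle)) / max(abs(w_oracle)), 1e-8)
  }
  norms <- vapply(c(0.01, 0.1, 1, 10, 100, 1000),
                  function(a) sqrt(sum(ridge_weights(X, y, a)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))

  # orthonormal design, alpha -> 0, y = X e1 recovers e1
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3]
  w <- ridge_weights(Q, Q[, 1L], 1e-12)
  expect_equal(as.numeric(w), c(1, 0, 0), tolerance = 1e-6)

  # rank-deficient with alpha = 0 is an error
  Xr <- cbind(X, X[, 1L])
  expect_error(ridge_weights(Xr, y, 0), "rank-deficient")
})

test_that("orthogonalization reduces the cosine between chest/abd weights", {
  withr::with_seed(17, {
    X <- matrix(rnorm(200 * 8), 200, 8)
    w_true <- rnorm(8)
    y_c <- X %*% w_true + rnorm(200, sd = 0.1)
    y_a <- X %*% (w_true + rnorm(8, sd = 0.3)) + rnorm(200, sd = 0.1)
  })
  fit <- orthogonal_ridge_weights(X, y_c, y_a, ridge_config(n_ortho_iters = 2))
  h <- fit$cos_history
  expect_lte(h[length(h)], h[1L] + 1e-12)
  expect_lt(abs(cosine_between <- sum(fit$w_c * fit$w_a) /
                  sqrt(sum(fit$w_c^2) * sum(fit$w_a^2))), 1e-8)
})

test_that("overlap-add equals the brute-force coverage-count mean", {
  withr::with_seed(23, {
    n <- 3000; fs <- 10
    X <- matrix(rnorm(n * 5), n, 5)
    w <- rnorm(5)
    y_c <- as.numeric(X %*% w + rnorm(n, sd = 0.05))
    y_a <- as.numeric(X %*% rev(w) + rnorm(n, sd = 0.05))
  })
  cfg <- ridge_config(window_s = 60, stride_s = 20, standardize = FALSE)
  out <- project_windows_overlap_add(X, y_c, y_a, cfg, fs = fs)

  # independent oracle: accumulate per-window predictions and divide
  win <- 60 * fs; stride <- 20 * fs
  starts <- seq(1L, n - win + 1L, by = stride)
  if (tail(starts, 1L) + win - 1L < n) starts <- c(starts, n - win + 1L)
  acc <- numeric(n); cov <- integer(n)
  for (s in starts) {
    idx <- s:(s + win - 1L)
    fit <- orthogonal_ridge_weights(X[idx, ], y_c[idx], y_a[idx], cfg)
    acc[idx] <- acc[idx] + apneaseg:::predict_ridge(X[idx, ], fit, "c")
    cov[idx] <- cov[idx] + 1L
  }
  expect_lt(max(abs(out$radar_chest - acc / cov)), 1e-12)
  expect_true(all(out$coverage >= 1L))

  # stride = window (no overlap): output equals concatenated predictions
  cfg2 <- ridge_config(window_s = 100, stride_s = 99.9, standardize = FALSE)
  n2 <- 3000
  out2 <- project_windows_overlap_add(X[seq_len(n2), ], y_c[seq_len(n2)],
                                      y_a[seq_len(n2)], cfg2, fs = 10)
  expect_true(all(out2$coverage[1:999] == 1L))

  # a night shorter than one window falls back to a single global fit
  out3 <- project_windows_overlap_add(X[1:300, ], y_c[1:300], y_a[1:300],
                                      cfg, fs = fs)
  fitg <- orthogonal_ridge_weights(X[1:300, ], y_c[1:300], y_a[1:300], cfg)
  expect_equal(out3$radar_chest,
               as.numeric(apneaseg:::predict_ridge(X[1:300, ], fitg, "c")))
})

test_that("identical per-window solutions make overlap-add equal the global fit", {
  # exact linear targets (with mutually orthogonal true weights, so the
  # orthogonality refinement is a no-op) and negligible regularization:
  # every window recovers the same weights and averaging reproduces X w
  withr::with_seed(5, {
    n <- 2000
    X <- matrix(rnorm(n * 4), n, 4)
  })
  w1 <- c(1, -2, 0.5, 3)
  w2 <- c(2, 1, 0, 0)          # orthogonal to w1
  y_c2 <- as.numeric(X %*% w1)
  y_a2 <- as.numeric(X %*% w2)
  cfg <- ridge_config(alpha_ridge = 1e-10, window_s = 50, stride_s = 20,
                      standardize = FALSE)
  out <- project_windows_overlap_add(X, y_c2, y_a2, cfg, fs = 10)
  expect_lt(max(abs(out$radar_chest - y_c2)), 1e-6)
  expect_lt(max(abs(out$radar_abd - y_a2)), 1e-6)
})

test_that("decimation preserves respiration content and lengths", {
  fs <- 50
  t <- seq_len(5000) / fs
  x <- sin(2 * pi * 0.2 * t)
  y <- decimate_signal(x, 50, 10)
  expect_length(y, 1000L)
  expect_lt(abs(peak_frequency(y, 10) - 0.2), 0.01)
  expect_lt(abs(fitted_amplitude(y, 10, 0.2, trim_s = 5) - 1), 0.02)

  # 200 -> 10 Hz (factor 20), 0.3 Hz preserved within 2%
  t2 <- seq_len(40000) / 200
  x2 <- sin(2 * pi * 0.3 * t2)
  y2 <- decimate_signal(x2, 200, 10)
  expect_length(y2, 2000L)
  expect_lt(abs(fitted_amplitude(y2, 10, 0.3, trim_s = 10) - 1), 0.02)

  expect_equal(decimate_signal(rep(3, 500), 50, 10), rep(3, 100))
  expect_error(decimate_signal(x, 50, 15), "integer multiple")
})

test_that("alignment tail-trims to the minimum length", {
  al <- align_and_trim(rnorm(1000), rnorm(998), integer(999))
  expect_true(all(lengths(al) == 998L))
  al2 <- align_and_trim(1:5, 6:10, rep(0L, 5))
  expect_identical(al2$chest, 1:5)
  al3 <- align_and_trim(rnorm(100), rnorm(100), integer(105))
  expect_length(al3$labels, 100L)
  expect_error(align_and_trim(numeric(0), rnorm(5), integer(5)), "empty")
})

test_that("end-to-end radar recovery correlates with the true chest signal", {
  # bins split between pure chest and pure abd mixes at high SNR
  p <- sim_params(duration_s = 600, fs = 50, target_ahi = 10, seed = 14,
                  noise_sd = 0.02)
  rp <- radar_sim_params(n_bins = 8L,
                         per_bin_mix = c(1, 1, 1, 1, 0, 0, 0, 0),
                         per_bin_gain = rep(1, 8), clutter_amp = 0.2,
                         phase_noise_sd = 0.005, seed = 14)
  night <- simulate_night(p, rp)
  disp <- phase_to_displacement(night$cube,
                                radar_wavelength(rp$carrier_freq_hz))
  Xf <- apply(disp$X, 2L, bandpass_respiration, fs = 50,
              low_hz = 0.1, high_hz = 0.6)
  proj <- project_windows_overlap_add(Xf, night$chest, night$abd,
                                      ridge_config(), fs = 50)
  ref <- bandpass_respiration(night$chest, 50, 0.1, 0.6)
  expect_gt(cor(proj$radar_chest, ref), 0.95)
})
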