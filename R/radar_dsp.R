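# FMCW radar slow-time processing: phase-based displacement recovery,
# respiration band-pass, orthogonal ridge projection with overlap-add.

#' Ridge / windowing configuration for radar waveform reconstruction
#'
#' @param alpha_ridge Ridge regularization weight (> 0). Applied to
#'   column-standardized displacement matrices, so 1.0 is a scale-free
#'   default.
#' @param n_ortho_iters Alternating re-solve/project iterations pushing the
#'   chest and abdomen weight vectors toward mutual orthogonality.
#' @param window_s Weight-estimation window length in seconds (120 s).
#' @param stride_s Window stride in seconds (30 s).
#' @param band_hz Respiration passband in Hz; `[0.1, 0.6]` covers 6-36
#'   breaths/min.
#' @param standardize Standardize columns of the displacement matrix before
#'   the ridge solve.
#' @return An object of class `ridge_config`.
#' @export
ridge_config <- function(alpha_ridge = 1.0, n_ortho_iters = 2L,
                         window_s = 120, stride_s = 30,
                         band_hz = c(0.1, 0.6), standardize = TRUE) {
  stopifnot(alpha_ridge > 0, window_s > stride_s, stride_s > 0,
            n_ortho_iters >= 1L)
  structure(list(alpha_ridge = alpha_ridge,
                 n_ortho_iters = as.integer(n_ortho_iters),
                 window_s = window_s, stride_s = stride_s,
                 band_hz = band_hz, standardize = standardize),
            class = "ridge_config")
}

#' Convert per-bin complex slow-time signals to displacement
#'
#' Per bin: subtract the mean complex value (static clutter/DC removal), take
#' the argument, unwrap along time, and scale by `lambda / (4*pi)`. Bins that
#' are numerically zero after mean removal are emitted as zeros and flagged.
#'
#' @param cube A [range_bin_cube()].
#' @param wavelength_m Radar wavelength in meters.
#' @return A list of class `displacement_matrix` with real matrix `X`
#'   (time x bins, meters), `fs`, and logical `dead_bins`.
#' @export
phase_to_displacement <- function(cube, wavelength_m) {
  stopifnot(inherits(cube, "range_bin_cube"), wavelength_m > 0,
            nrow(cube$z) > 0L)
  z <- cube$z
  z[!is.finite(Re(z)) | !is.finite(Im(z))] <- 0 + 0i
  B <- ncol(z)
  X <- matrix(0, nrow(z), B)
  dead <- logical(B)
  scale <- wavelength_m / (4 * pi)
  for (b in seq_len(B)) {
    zc <- z[, b] - mean(z[, b])
    if (max(Mod(zc)) < 1e-12) {
      dead[b] <- TRUE
      next
    }
    X[, b] <- scale * unwrap_phase(Arg(zc))
  }
  if (any(dead)) {
    log_msg("phase_to_displacement: %d dead bin(s) emitted as zeros",
            sum(dead))
  }
  structure(list(X = X, fs = cube$fs, dead_bins = dead),
            class = "displacement_matrix")
}

#' Zero-phase Butterworth band-pass for respiration
#'
#' 4th-order Butterworth design applied forward and backward (`filtfilt`) so
#' the output has no phase distortion; output length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Passband edges, `0 < low < high < fs/2`.
#' @param order Butterworth design order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_respiration <- function(x, fs, low_hz = 0.1, high_hz = 0.6,
                                 order = 4L) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < fs / 2)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  min_n <- 9L * (max(length(bf$b), length(bf$a)) - 1L)
  if (length(x) <= min_n) {
    stop("signal shorter than filter warm-up; need more than ",
         min_n, " samples")
  }
  # padding long relative to the low-edge time constant so start-up
  # transients have fully decayed inside the padding
  pad_n <- min(length(x) - 1L, ceiling(12 / low_hz * fs))
  filtfilt_padded(bf, x, pad_n)
}

# single-pass IIR filter started in steady state for the first sample, so
# constant inputs are in equilibrium from the start
lfilter_ss <- function(bf, x) {
  s0 <- x[1L]
  g <- sum(bf$b) / sum(bf$a)
  as.numeric(signal::filter(bf$b, bf$a, x,
                            init.x = rep(s0, length(bf$b) - 1L),
                            init.y = rep(s0 * g, length(bf$a) - 1L)))
}

# zero-phase (forward-backward) filtering with odd-symmetric reflection
# padding at both ends and steady-state initialization of each pass
filtfilt_padded <- function(bf, x, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1L)
  left <- 2 * x[1L] - x[(pad_n + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad_n)]
  y <- lfilter_ss(bf, c(left, x, right))
  y <- rev(lfilter_ss(bf, rev(y)))
  y[(pad_n + 1L):(pad_n + n)]
}

#' Closed-form ridge regression weights
#'
#' Solves `argmin_w ||X w - y||^2 + alpha ||w||^2` via
#' `(X'X + alpha I)^{-1} X'y`. With `alpha = 0` the matrix must be full
#' column rank; regularization is otherwise mandatory.
#'
#' @param X Numeric design matrix.
#' @param y Numeric target vector.
#' @param alpha Non-negative regularization weight.
#' @return Weight vector of length `ncol(X)`.
#' @export
ridge_weights <- function(X, y, alpha) {
  stopifnot(nrow(X) == length(y), alpha >= 0)
  p <- ncol(X)
  if (alpha == 0 && qr(X)$rank < p) {
    stop("rank-deficient design with alpha = 0: regularization is mandatory")
  }
  solve(crossprod(X) + alpha * diag(p), crossprod(X, y))[, 1L]
}

project_off <- function(w, v) {
  nv <- sum(v * v)
  if (nv < .Machine$double.eps) return(w)
  w - (sum(w * v) / nv) * v
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Orthogonal ridge weights for chest/abdomen separation
#'
#' Solves one ridge problem per target, then alternately re-solves and
#' projects each weight vector onto the orthogonal complement of the other
#' for `n_ortho_iters` iterations, reducing the cosine similarity between
#' the two projections (disentangling chest and abdominal motion
#' contributions spread over multiple range bins).
#'
#' @param X Displacement matrix window (time x bins).
#' @param y_chest,y_abd Reference chest/abdomen targets aligned to the rows
#'   of `X`.
#' @param cfg A [ridge_config()].
#' @return List with `w_c`, `w_a` (in the possibly standardized column
#'   space), centering/scaling vectors, target means, and `cos_history` of
#'   absolute cosine similarity per iteration (initial value first).
#' @export
orthogonal_ridge_weights <- function(X, y_chest, y_abd, cfg = ridge_config()) {
  stopifnot(nrow(X) == length(y_chest), nrow(X) == length(y_abd))
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  Xs <- X
  if (isTRUE(cfg$standardize)) {
    ctr <- colMeans(X)
    Xs <- sweep(X, 2L, ctr)
    scl <- apply(Xs, 2L, sd)
    scl[scl < 1e-12] <- 1
    Xs <- sweep(Xs, 2L, scl, `/`)
  }
  # targets are centred only alongside column standardization; the raw
  # path is the exact ridge problem (matches the closed form)
  if (isTRUE(cfg$standardize)) {
    mu_c <- mean(y_chest); mu_a <- mean(y_abd)
  } else {
    mu_c <- 0; mu_a <- 0
  }
  yc <- y_chest - mu_c; ya <- y_abd - mu_a
  w_c <- ridge_weights(Xs, yc, cfg$alpha_ridge)
  w_a <- ridge_weights(Xs, ya, cfg$alpha_ridge)
  cos_hist <- abs(cosine_sim(w_c, w_a))
  for (i in seq_len(cfg$n_ortho_iters)) {
    w_c <- project_off(ridge_weights(Xs, yc, cfg$alpha_ridge), w_a)
    w_a <- project_off(ridge_weights(Xs, ya, cfg$alpha_ridge), w_c)
    cos_hist <- c(cos_hist, abs(cosine_sim(w_c, w_a)))
  }
  list(w_c = w_c, w_a = w_a, x_center = ctr, x_scale = scl,
       y_c_mean = mu_c, y_a_mean = mu_a, cos_history = cos_hist)
}

predict_ridge <- function(X, fit, which = c("c", "a")) {
  which <- match.arg(which)
  Xs <- sweep(sweep(X, 2L, fit$x_center), 2L, fit$x_scale, `/`)
  if (which == "c") Xs %*% fit$w_c + fit$y_c_mean
  else Xs %*% fit$w_a + fit$y_a_mean
}

#' Windowed orthogonal ridge projection with overlap-add averaging
#'
#' Estimates chest/abdomen weights inside overlapping windows
#' (`window_s` long, `stride_s` stride), predicts within each window, and
#' merges overlapping predictions by an unbiased per-sample mean (sum of
#' covering window predictions divided by coverage count). A tail window
#' anchored at the end guarantees full coverage. Nights shorter than one
#' window fall back to a single global fit.
#'
#' @param disp A `displacement_matrix` (or plain matrix with attribute-free
#'   rows at `fs`).
#' @param y_chest,y_abd Full-night reference targets aligned to the rows.
#' @param cfg A [ridge_config()].
#' @param fs Sampling rate in Hz (taken from `disp$fs` when available).
#' @return List with full-length `radar_chest`, `radar_abd`, and the
#'   per-sample `coverage` counts.
#' @export
project_windows_overlap_add <- function(disp, y_chest, y_abd,
                                        cfg = ridge_config(), fs = NULL) {
  X <- if (inherits(disp, "displacement_matrix")) disp$X else disp
  fs <- fs %||% disp$fs
  n <- nrow(X)
  stopifnot(length(y_chest) == n, length(y_abd) == n)
  win <- round(cfg$window_s * fs)
  stride <- round(cfg$stride_s * fs)
  if (n < win) {
    log_msg("night shorter than one window: single global ridge fit")
    fit <- orthogonal_ridge_weights(X, y_chest, y_abd, cfg)
    return(list(radar_chest = as.numeric(predict_ridge(X, fit, "c")),
                radar_abd = as.numeric(predict_ridge(X, fit, "a")),
                coverage = rep(1L, n)))
  }
  starts <- seq(1L, n - win + 1L, by = stride)
  if (tail(starts, 1L) + win - 1L < n) starts <- c(starts, n - win + 1L)
  acc_c <- numeric(n); acc_a <- numeric(n); cov <- integer(n)
  for (s in starts) {
    idx <- s:(s + win - 1L)
    fit <- orthogonal_ridge_weights(X[idx, , drop = FALSE],
                                    y_chest[idx], y_abd[idx], cfg)
    acc_c[idx] <- acc_c[idx] + predict_ridge(X[idx, , drop = FALSE], fit, "c")
    acc_a[idx] <- acc_a[idx] + predict_ridge(X[idx, , drop = FALSE], fit, "a")
    cov[idx] <- cov[idx] + 1L
  }
  list(radar_chest = acc_c / cov, radar_abd = acc_a / cov, coverage = cov)
}

#' Integer-factor decimation with anti-aliasing
#'
#' Low-pass filters (zero-phase Butterworth at 80% of the target Nyquist)
#' and keeps every q-th sample. Large factors are decomposed into stages of
#' at most 10 for numerical stability. Output length is `ceiling(n / q)`.
#'
#' @param x Numeric signal.
#' @param from_fs,to_fs Source and target sampling rates; `from_fs` must be
#'   an integer multiple of `to_fs`.
#' @return Decimated signal at `to_fs`.
#' @export
decimate_signal <- function(x, from_fs, to_fs) {
  q <- from_fs / to_fs
  if (abs(q - round(q)) > 1e-9) stop("from_fs must be an integer multiple of to_fs")
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  stages <- integer(0)
  qq <- q
  while (qq > 10L) {
    f <- max(Filter(function(d) qq %% d == 0L, 2:10))
    stages <- c(stages, f)
    qq <- qq %/% f
  }
  stages <- c(stages, qq)
  for (f in stages) {
    if (sd(x) < 1e-300 || length(unique(round(x, 12))) == 1L) {
      # constant signal: filtering is a no-op, avoid numerical transients
      x <- x[seq(1L, length(x), by = f)]
      next
    }
    bf <- signal::butter(4L, 0.8 / f, type = "low")
    x <- filtfilt_padded(bf, x, pad_n = min(length(x) - 1L, 30L * f))
    x <- x[seq(1L, length(x), by = f)]
  }
  x
}

#' Trim chest, abdomen and label sequences to a common length
#'
#' Tail-trims all three sequences to the minimum length, preserving the
#' shared t = 0 synchronization point.
#'
#' @param chest,abd Numeric signals at a common rate.
#' @param labels Integer per-sample labels at the same rate.
#' @return List with equal-length `chest`, `abd`, `labels`.
#' @export
align_and_trim <- function(chest, abd, labels) {
  if (length(chest) == 0L || length(abd) == 0L || length(labels) == 0L) {
    stop("empty input sequence")
  }
  L <- min(length(chest), length(abd), length(labels))
  list(chest = chest[seq_len(L)], abd = abd[seq_len(L)],
       labels = labels[seq_len(L)])
}

#' Full radar extraction: cube to normalized 10 Hz respiration channels
#'
#' Runs the radar processing chain: phase-to-displacement conversion,
#' per-bin respiration band-pass, windowed orthogonal ridge projection
#' against the synchronized reference belts with overlap-add merging, a
#' final band-pass, decimation to `to_fs`, and tail alignment with the label
#' sequence. With `mode = "pca"` the first two principal components of the
#' filtered displacement matrix replace the reference targets
#' (reference-free surrogate; not part of the synchronized-reference
#' processing path).
#'
#' @param cube A [range_bin_cube()].
#' @param y_chest,y_abd Reference belts at the cube rate (required for
#'   `mode = "reference"`).
#' @param labels_10 Integer labels at `to_fs` for final alignment.
#' @param cfg A [ridge_config()].
#' @param carrier_freq_hz Carrier frequency used to derive the wavelength.
#' @param to_fs Output rate in Hz (default 10).
#' @param mode `"reference"` (default) or `"pca"`.
#' @return List with `chest`, `abd`, `labels` at `to_fs`.
#' @export
extract_radar_respiration <- function(cube, y_chest = NULL, y_abd = NULL,
                                      labels_10, cfg = ridge_config(),
                                      carrier_freq_hz = 60e9, to_fs = 10,
                                      mode = c("reference", "pca")) {
  mode <- match.arg(mode)
  disp <- phase_to_displacement(cube, radar_wavelength(carrier_freq_hz))
  Xf <- apply(disp$X, 2L, function(col) {
    if (all(col == 0)) col
    else bandpass_respiration(col, cube$fs, cfg$band_hz[1L], cfg$band_hz[2L])
  })
  if (mode == "pca") {
    pc <- stats::prcomp(Xf, center = TRUE, scale. = FALSE)
    y_chest <- pc$x[, 1L]
    y_abd <- pc$x[, 2L]
  } else {
    stopifnot(!is.null(y_chest), !is.null(y_abd))
  }
  proj <- project_windows_overlap_add(Xf, y_chest, y_abd, cfg, fs = cube$fs)
  rc <- bandpass_respiration(proj$radar_chest, cube$fs,
                             cfg$band_hz[1L], cfg$band_hz[2L])
  ra <- bandpass_respiration(proj$radar_abd, cube$fs,
                             cfg$band_hz[1L], cfg$band_hz[2L])
  rc <- decimate_signal(rc, cube$fs, to_fs)
  ra <- decimate_signal(ra, cube$fs, to_fs)
  align_and_trim(rc, ra, labels_10)
}
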