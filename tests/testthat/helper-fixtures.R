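# Shared fixtures: small configs and generators used across test files.

micro_model_config <- function(...) {
  args <- utils::modifyList(
    list(input_len = 32L, base_filters = 4L, depth = 2L,
         n_transformer_blocks = 1L, n_heads = 2L, smooth_kernel = 5L),
    list(...))
  do.call(model_config, args)
}

# dominant periodogram frequency (independent spectral oracle)
peak_frequency <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  sp <- Mod(fft(x))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * fs / n
  freqs[which.max(sp)]
}

# sinusoid amplitude via least-squares sin/cos regression (edge-robust)
fitted_amplitude <- function(x, fs, f, trim_s = 30) {
  n <- length(x)
  i <- seq(round(trim_s * fs) + 1, n - round(trim_s * fs))
  t <- i / fs
  co <- coef(lm(x[i] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# brute-force maximum one-to-one matching over all subsets (oracle)
brute_force_match <- function(pred, truth, theta) {
  np <- nrow(pred); nt <- nrow(truth)
  iou <- matrix(0, max(np, 1), max(nt, 1))
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    iou[i, j] <- interval_iou(c(pred$start[i], pred$end[i]),
                              c(truth$start[j], truth$end[j]))
  }
  best <- 0L
  rec <- function(i, used) {
    if (i > np) return(0L)
    res <- rec(i + 1L, used)  # leave pred i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] > theta) {
        used2 <- used; used2[j] <- TRUE
        res <- max(res, 1L + rec(i + 1L, used2))
      }
    }
    res
  }
  if (np == 0L || nt == 0L) 0L else rec(1L, logical(nt))
}

random_disjoint_events <- function(n, horizon, min_len = 20L, max_len = 120L) {
  if (n == 0L) return(apneaseg:::empty_events())
  lens <- sample(min_len:max_len, n, replace = TRUE)
  gaps <- sample(0:80, n + 1L, replace = TRUE)
  need <- sum(lens) + sum(gaps)
  scale <- if (need > horizon) horizon / need else 1
  starts <- integer(n); cursor <- round(gaps[1L] * scale)
  for (i in seq_len(n)) {
    starts[i] <- cursor
    cursor <- cursor + max(1L, round(lens[i] * scale)) +
      round(gaps[i + 1L] * scale) + 1L
  }
  ends <- starts + pmax(1L, round(lens * scale))
  out <- data.frame(start = as.integer(starts), end = as.integer(ends),
                    code = rep(1L, n))
  class(out) <- c("event_intervals", "data.frame")
  out
}
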