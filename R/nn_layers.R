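# 1D neural-network primitives with exact analytic gradients.
#
# Tensors are base-R arrays of dim (N, T, C): batch, time, channels. All
# heavy lifting is im2col + BLAS matrix products. Every layer is an
# environment holding params, accumulated grads, a trainable flag and (for
# batch norm) running statistics + a frozen flag. forward() functions return
# list(y, cache); backward() functions consume the cache, accumulate grads
# in the layer environment and return the input gradient.

new_layer <- function(kind, name, params = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$name <- name
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)  # zero, same shape/attributes
  e$trainable <- TRUE
  e$frozen_stats <- FALSE
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e
}

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

# ---- conv1d ---------------------------------------------------------------

conv1d_new <- function(name, c_in, c_out, k = 3L, stride = 1L,
                       dilation = 1L) {
  W <- matrix(he_init(k * c_in, k * c_in * c_out), k * c_in, c_out)
  b <- numeric(c_out)
  new_layer("conv1d", name, list(W = W, b = b),
            list(c_in = c_in, c_out = c_out, k = k, stride = stride,
                 dilation = dilation))
}

conv1d_fwd <- function(ly, x) {
  d <- dim(x); N <- d[1L]; T <- d[2L]; C <- d[3L]
  k <- ly$k; dil <- ly$dilation; st <- ly$stride
  p <- ((k - 1L) * dil) %/% 2L
  Tout <- if (st == 1L) T else T %/% st
  Xcol <- matrix(0, N * Tout, C * k)
  for (kk in seq_len(k)) {
    off <- (kk - 1L) * dil - p
    i_all <- (seq_len(Tout) - 1L) * st + 1L + off
    valid <- which(i_all >= 1L & i_all <= T)
    if (length(valid)) {
      rows <- rep((valid - 1L) * N, each = N) + seq_len(N)
      blk <- x[, i_all[valid], , drop = FALSE]
      Xcol[rows, ((kk - 1L) * C + 1L):(kk * C)] <-
        matrix(blk, N * length(valid), C)
    }
  }
  Yf <- Xcol %*% ly$params$W
  Yf <- sweep(Yf, 2L, ly$params$b, `+`)
  list(y = array(Yf, dim = c(N, Tout, ly$c_out)),
       cache = list(Xcol = Xcol, dimx = d, Tout = Tout))
}

conv1d_bwd <- function(ly, cache, dy) {
  d <- cache$dimx; N <- d[1L]; T <- d[2L]; C <- d[3L]
  Tout <- cache$Tout
  k <- ly$k; dil <- ly$dilation; st <- ly$stride
  p <- ((k - 1L) * dil) %/% 2L
  dYf <- matrix(dy, N * Tout, ly$c_out)
  if (ly$trainable) {
    ly$grads$W <- ly$grads$W + crossprod(cache$Xcol, dYf)
    ly$grads$b <- ly$grads$b + colSums(dYf)
  }
  dXcol <- tcrossprod(dYf, ly$params$W)
  dx <- array(0, dim = d)
  for (kk in seq_len(k)) {
    off <- (kk - 1L) * dil - p
    i_all <- (seq_len(Tout) - 1L) * st + 1L + off
    valid <- which(i_all >= 1L & i_all <= T)
    if (length(valid)) {
      rows <- rep((valid - 1L) * N, each = N) + seq_len(N)
      iv <- i_all[valid]
      dx[, iv, ] <- dx[, iv, ] +
        array(dXcol[rows, ((kk - 1L) * C + 1L):(kk * C)],
              dim = c(N, length(valid), C))
    }
  }
  dx
}

# ---- batch norm (per channel over batch x time) ---------------------------

bn_new <- function(name, c, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", name, list(gamma = rep(1, c), beta = numeric(c)),
            list(c = c, momentum = momentum, eps = eps,
                 run_mean = numeric(c), run_var = rep(1, c)))
}

bn_fwd <- function(ly, x, training = FALSE) {
  d <- dim(x); m <- d[1L] * d[2L]
  xm <- matrix(x, m, d[3L])
  use_batch <- training && !ly$frozen_stats
  if (use_batch) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
    ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
  } else {
    mu <- ly$run_mean
    v <- ly$run_var
    xc <- sweep(xm, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + ly$eps)
  xhat <- sweep(xc, 2L, inv_std, `*`)
  y <- sweep(sweep(xhat, 2L, ly$params$gamma, `*`), 2L, ly$params$beta, `+`)
  list(y = array(y, dim = d),
       cache = list(xhat = xhat, inv_std = inv_std, dimx = d,
                    batch_stats = use_batch))
}

bn_bwd <- function(ly, cache, dy) {
  d <- cache$dimx; m <- d[1L] * d[2L]
  dym <- matrix(dy, m, d[3L])
  xhat <- cache$xhat
  if (ly$trainable) {
    ly$grads$gamma <- ly$grads$gamma + colSums(dym * xhat)
    ly$grads$beta <- ly$grads$beta + colSums(dym)
  }
  dxhat <- sweep(dym, 2L, ly$params$gamma, `*`)
  if (cache$batch_stats) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dxm <- sweep(
      dxhat - matrix(s1 / m, m, d[3L], byrow = TRUE) -
        xhat * matrix(s2 / m, m, d[3L], byrow = TRUE),
      2L, cache$inv_std, `*`)
  } else {
    dxm <- sweep(dxhat, 2L, cache$inv_std, `*`)
  }
  array(dxm, dim = d)
}

# ---- activations ----------------------------------------------------------

swish_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = s)
}

swish_bwd <- function(cache, x_s, dy) {
  # cache = sigmoid(x); derivative s * (1 + x * (1 - s)) needs x = y / s
  s <- cache
  dy * (s + x_s * s * (1 - s))  # x_s is the pre-activation input
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dropout --------------------------------------------------------------

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim = dim(x))
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

# ---- pooling / upsampling -------------------------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  a <- x[, seq(1L, d[2L], by = 2L), , drop = FALSE]
  b <- x[, seq(2L, d[2L], by = 2L), , drop = FALSE]
  take_a <- a >= b
  list(y = ifelse(take_a, a, b), cache = list(take_a = take_a, dimx = d))
}

maxpool2_bwd <- function(cache, dy) {
  d <- cache$dimx
  dx <- array(0, dim = d)
  dx[, seq(1L, d[2L], by = 2L), ] <- dy * cache$take_a
  dx[, seq(2L, d[2L], by = 2L), ] <- dy * (!cache$take_a)
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, dim = c(d[1L], 2L * d[2L], d[3L]))
  y[, seq(1L, 2L * d[2L], by = 2L), ] <- x
  y[, seq(2L, 2L * d[2L], by = 2L), ] <- x
  y
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  dy[, seq(1L, d[2L], by = 2L), , drop = FALSE] +
    dy[, seq(2L, d[2L], by = 2L), , drop = FALSE]
}

# ---- dense (applied to (N*T) x C matrices) --------------------------------

dense_new <- function(name, c_in, c_out) {
  W <- matrix(rnorm(c_in * c_out, sd = sqrt(1 / c_in)), c_in, c_out)
  new_layer("dense", name, list(W = W, b = numeric(c_out)),
            list(c_in = c_in, c_out = c_out))
}

dense_fwd <- function(ly, xm) {
  y <- sweep(xm %*% ly$params$W, 2L, ly$params$b, `+`)
  list(y = y, cache = xm)
}

dense_bwd <- function(ly, cache, dy) {
  if (ly$trainable) {
    ly$grads$W <- ly$grads$W + crossprod(cache, dy)
    ly$grads$b <- ly$grads$b + colSums(dy)
  }
  tcrossprod(dy, ly$params$W)
}

# ---- layer norm (per row over channels) -----------------------------------

ln_new <- function(name, c, eps = 1e-5) {
  new_layer("ln", name, list(gamma = rep(1, c), beta = numeric(c)),
            list(c = c, eps = eps))
}

ln_fwd <- function(ly, xm) {
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  inv_std <- 1 / sqrt(v + ly$eps)
  xhat <- xc * inv_std
  y <- sweep(sweep(xhat, 2L, ly$params$gamma, `*`), 2L, ly$params$beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv_std = inv_std))
}

ln_bwd <- function(ly, cache, dy) {
  xhat <- cache$xhat
  C <- ncol(dy)
  if (ly$trainable) {
    ly$grads$gamma <- ly$grads$gamma + colSums(dy * xhat)
    ly$grads$beta <- ly$grads$beta + colSums(dy)
  }
  dxhat <- sweep(dy, 2L, ly$params$gamma, `*`)
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv_std
}

# ---- softmax --------------------------------------------------------------

softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

softmax_rows_bwd <- function(a, da) {
  (da - rowSums(da * a)) * a
}
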