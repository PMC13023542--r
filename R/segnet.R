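# 1D residual U-Net with ASPP-lite and a transformer bottleneck for dense
# per-sample event segmentation. Blocks are assembled in definition order
# (encoder -> bottleneck -> decoder -> head); that order is also the layer
# list used for partial freezing during transfer.

#' Segmentation model configuration
#'
#' Defaults follow the full-scale architecture: 2048 x 2 input, base 32
#' filters, encoder depth 4 (stride-2 convolutional downsampling, channels
#' 32-64-128-256), residual dilated conv blocks (kernel 3, dilations (1,2)),
#' batch norm + swish, ASPP-lite with dilations (1,2,4,8) at the bottleneck,
#' sinusoidal positional encoding, 3 pre-norm transformer blocks with 4
#' heads and FFN multiplier 4, nearest+conv upsampling with skip-connection
#' concatenation, a large-kernel (31) smoothing conv and a sigmoid head.
#'
#' The bottleneck embedding dimension is tied to
#' `base_filters * 2^(depth - 1)` (256 for the defaults) and the bottleneck
#' length to `input_len / 2^depth` (128 for the defaults).
#'
#' Ablation switches: `use_aspp`, `use_transformer` (both off = plain base
#' U-Net), `use_residual` and `downsample = "pool"` remove the residual /
#' learnable-downsampling refinements.
#'
#' @param input_len Window length in samples; divisible by `2^depth`.
#' @param in_channels Input channels (chest + abdomen = 2).
#' @param base_filters Channels of the first encoder stage.
#' @param depth Number of encoder stages.
#' @param dropout Dropout rate inside residual blocks and the FFN.
#' @param kernel_size Conv kernel size.
#' @param block_dilations Dilations of the two convs inside each residual
#'   block.
#' @param aspp_dilations Parallel ASPP branch dilations.
#' @param n_transformer_blocks,n_heads,ffn_mult Transformer bottleneck
#'   geometry.
#' @param smooth_kernel Kernel of the full-resolution smoothing conv
#'   (31 samples = 3.1 s at 10 Hz).
#' @param use_aspp,use_transformer,use_residual Ablation switches.
#' @param downsample `"conv"` (strided conv) or `"pool"` (max pool + conv).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_len = 2048L, in_channels = 2L,
                         base_filters = 32L, depth = 4L, dropout = 0.2,
                         kernel_size = 3L, block_dilations = c(1L, 2L),
                         aspp_dilations = c(1L, 2L, 4L, 8L),
                         n_transformer_blocks = 3L, n_heads = 4L,
                         ffn_mult = 4L, smooth_kernel = 31L,
                         use_aspp = TRUE, use_transformer = TRUE,
                         use_residual = TRUE,
                         downsample = c("conv", "pool")) {
  downsample <- match.arg(downsample)
  if (input_len %% 2^depth != 0L) {
    stop("input_len must be divisible by 2^depth")
  }
  embed_dim <- base_filters * 2L^(depth - 1L)
  if (use_transformer && embed_dim %% n_heads != 0L) {
    stop("bottleneck embedding (", embed_dim,
         ") must be divisible by n_heads")
  }
  structure(list(
    input_len = as.integer(input_len), in_channels = as.integer(in_channels),
    base_filters = as.integer(base_filters), depth = as.integer(depth),
    dropout = dropout, kernel_size = as.integer(kernel_size),
    block_dilations = as.integer(block_dilations),
    aspp_dilations = as.integer(aspp_dilations),
    n_transformer_blocks = as.integer(n_transformer_blocks),
    n_heads = as.integer(n_heads), embed_dim = embed_dim,
    ffn_mult = as.integer(ffn_mult), smooth_kernel = as.integer(smooth_kernel),
    use_aspp = use_aspp, use_transformer = use_transformer,
    use_residual = use_residual, downsample = downsample
  ), class = "model_config")
}

#' Desk-scale model preset
#'
#' Reduced geometry (512-sample windows, base 8 filters, depth 3) for
#' CPU-budget experiments; all structural components are retained.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
tiny_model_config <- function(...) {
  args <- list(input_len = 512L, base_filters = 8L, depth = 3L, ...)
  do.call(model_config, args)
}

#' Sinusoidal positional encoding
#'
#' Interleaved sin/cos encoding: even columns `sin(t / 10000^(2i/dim))`,
#' odd columns the matching cosine, positions 0-based. Parameter-free and
#' deterministic; all entries lie in `[-1, 1]`.
#'
#' @param length Number of positions.
#' @param dim Embedding dimension.
#' @return A `length x dim` matrix.
#' @export
sinusoidal_positional_encoding <- function(length, dim) {
  stopifnot(length > 0, dim > 0)
  pos <- 0:(length - 1L)
  pe <- matrix(0, length, dim)
  n_pair <- ceiling(dim / 2)
  for (i in seq_len(n_pair)) {
    freq <- 1 / 10000^((2 * (i - 1)) / dim)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= dim) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}

# ---- block constructors ---------------------------------------------------

make_res_convs <- function(prefix, c_in, c_out, cfg, shortcut_proj) {
  sub <- list(
    conv1 = conv1d_new(paste0(prefix, ".conv1"), c_in, c_out,
                       k = cfg$kernel_size, dilation = cfg$block_dilations[1L]),
    bn1 = bn_new(paste0(prefix, ".bn1"), c_out),
    conv2 = conv1d_new(paste0(prefix, ".conv2"), c_out, c_out,
                       k = cfg$kernel_size, dilation = cfg$block_dilations[2L]),
    bn2 = bn_new(paste0(prefix, ".bn2"), c_out)
  )
  if (shortcut_proj) {
    sub$conv_sc <- conv1d_new(paste0(prefix, ".conv_sc"), c_in, c_out, k = 1L)
    sub$bn_sc <- bn_new(paste0(prefix, ".bn_sc"), c_out)
  }
  sub
}

make_enc_stage <- function(name, c_in, c_out, cfg) {
  sub <- if (cfg$downsample == "conv") {
    list(down_conv = conv1d_new(paste0(name, ".down"), c_in, c_out,
                                k = cfg$kernel_size, stride = 2L),
         down_bn = bn_new(paste0(name, ".down_bn"), c_out))
  } else {
    list(down_conv = conv1d_new(paste0(name, ".down"), c_in, c_out,
                                k = cfg$kernel_size),
         down_bn = bn_new(paste0(name, ".down_bn"), c_out))
  }
  sub <- c(sub, make_res_convs(name, c_out, c_out, cfg, shortcut_proj = FALSE))
  list(kind = "enc_stage", name = name, sub = sub,
       dropout = cfg$dropout, use_residual = cfg$use_residual,
       downsample = cfg$downsample)
}

make_dec_stage <- function(name, c_in, c_out, has_skip, cfg) {
  sub <- list(
    up_conv = conv1d_new(paste0(name, ".up"), c_in, c_out,
                         k = cfg$kernel_size),
    up_bn = bn_new(paste0(name, ".up_bn"), c_out)
  )
  fuse_in <- if (has_skip) 2L * c_out else c_out
  sub <- c(sub, make_res_convs(name, fuse_in, c_out, cfg,
                               shortcut_proj = has_skip))
  list(kind = "dec_stage", name = name, sub = sub,
       dropout = cfg$dropout, use_residual = cfg$use_residual,
       has_skip = has_skip, c_out = c_out)
}

make_aspp <- function(name, c, cfg) {
  cb <- max(1L, c %/% 4L)
  sub <- list()
  for (i in seq_along(cfg$aspp_dilations)) {
    d <- cfg$aspp_dilations[i]
    sub[[paste0("branch", i, "_conv")]] <-
      conv1d_new(paste0(name, ".b", i), c, cb, k = cfg$kernel_size,
                 dilation = d)
    sub[[paste0("branch", i, "_bn")]] <- bn_new(paste0(name, ".b", i, "_bn"), cb)
  }
  sub$fuse_conv <- conv1d_new(paste0(name, ".fuse"),
                              cb * length(cfg$aspp_dilations), c, k = 1L)
  sub$fuse_bn <- bn_new(paste0(name, ".fuse_bn"), c)
  list(kind = "aspp", name = name, sub = sub,
       n_branch = length(cfg$aspp_dilations), cb = cb)
}

make_transformer <- function(name, c, cfg) {
  sub <- list(
    ln1 = ln_new(paste0(name, ".ln1"), c),
    wq = dense_new(paste0(name, ".wq"), c, c),
    wk = dense_new(paste0(name, ".wk"), c, c),
    wv = dense_new(paste0(name, ".wv"), c, c),
    wo = dense_new(paste0(name, ".wo"), c, c),
    ln2 = ln_new(paste0(name, ".ln2"), c),
    ffn1 = dense_new(paste0(name, ".ffn1"), c, c * cfg$ffn_mult),
    ffn2 = dense_new(paste0(name, ".ffn2"), c * cfg$ffn_mult, c)
  )
  list(kind = "transformer", name = name, sub = sub,
       n_heads = cfg$n_heads, dropout = cfg$dropout)
}

#' Build a segmentation model
#'
#' Constructs the full block graph from a [model_config()]; initialization
#' is seeded, so two builds from the same seed have identical parameters.
#'
#' @param cfg A `model_config`.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `segnet`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  withr::with_seed(derive_seed(seed, "model_init"), {
    blocks <- list()
    c_enc <- cfg$base_filters * 2L^(0:(cfg$depth - 1L))
    c_prev <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      blocks[[paste0("enc", i)]] <-
        make_enc_stage(paste0("enc", i), c_prev, c_enc[i], cfg)
      c_prev <- c_enc[i]
    }
    if (cfg$use_aspp) {
      blocks$aspp <- make_aspp("aspp", cfg$embed_dim, cfg)
    }
    if (cfg$use_transformer) {
      for (b in seq_len(cfg$n_transformer_blocks)) {
        blocks[[paste0("transformer", b)]] <-
          make_transformer(paste0("transformer", b), cfg$embed_dim, cfg)
      }
    }
    for (j in seq_len(cfg$depth)) {
      c_in <- c_enc[cfg$depth - j + 1L]
      has_skip <- j < cfg$depth
      c_out <- if (has_skip) c_enc[cfg$depth - j] else cfg$base_filters
      blocks[[paste0("dec", j)]] <-
        make_dec_stage(paste0("dec", j), c_in, c_out, has_skip, cfg)
    }
    blocks$smooth_conv <- list(
      kind = "smooth", name = "smooth_conv",
      sub = list(conv = conv1d_new("smooth_conv.conv", cfg$base_filters,
                                   cfg$base_filters, k = cfg$smooth_kernel),
                 bn = bn_new("smooth_conv.bn", cfg$base_filters)))
    blocks$head <- list(
      kind = "head", name = "head",
      sub = list(conv = conv1d_new("head.conv", cfg$base_filters, 1L, k = 1L)))
  })
  pe <- sinusoidal_positional_encoding(cfg$input_len %/% 2L^cfg$depth,
                                       cfg$embed_dim)
  structure(list(cfg = cfg, blocks = blocks, pe = pe), class = "segnet")
}

# ---- block forward / backward ---------------------------------------------

res_convs_fwd <- function(bk, h, z_in, training) {
  # z_in: input to the residual unit (may differ from stage input h)
  c1 <- conv1d_fwd(bk$sub$conv1, z_in)
  b1 <- bn_fwd(bk$sub$bn1, c1$y, training)
  s1 <- swish_fwd(b1$y)
  dp <- dropout_fwd(s1$y, bk$dropout %||% 0, training)
  c2 <- conv1d_fwd(bk$sub$conv2, dp$y)
  b2 <- bn_fwd(bk$sub$bn2, c2$y, training)
  if (isTRUE(bk$use_residual)) {
    if (!is.null(bk$sub$conv_sc)) {
      sc_c <- conv1d_fwd(bk$sub$conv_sc, z_in)
      sc_b <- bn_fwd(bk$sub$bn_sc, sc_c$y, training)
      sc <- sc_b$y
      sc_cache <- list(sc_c = sc_c$cache, sc_b = sc_b$cache)
    } else {
      sc <- z_in
      sc_cache <- NULL
    }
    pre <- b2$y + sc
  } else {
    pre <- b2$y
    sc_cache <- NULL
  }
  s2 <- swish_fwd(pre)
  list(y = s2$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, b1y = b1$y,
                    s1 = s1$cache, dp = dp$cache, c2 = c2$cache,
                    b2 = b2$cache, pre = pre, s2 = s2$cache,
                    sc = sc_cache))
}

res_convs_bwd <- function(bk, cache, dy) {
  ds2 <- swish_bwd(cache$s2, cache$pre, dy)
  dz_extra <- NULL
  if (isTRUE(bk$use_residual)) {
    if (!is.null(cache$sc)) {
      d_sc <- bn_bwd(bk$sub$bn_sc, cache$sc$sc_b, ds2)
      dz_extra <- conv1d_bwd(bk$sub$conv_sc, cache$sc$sc_c, d_sc)
    } else {
      dz_extra <- ds2
    }
  }
  d <- bn_bwd(bk$sub$bn2, cache$b2, ds2)
  d <- conv1d_bwd(bk$sub$conv2, cache$c2, d)
  d <- dropout_bwd(cache$dp, d)
  d <- swish_bwd(cache$s1, cache$b1y, d)
  d <- bn_bwd(bk$sub$bn1, cache$b1, d)
  d <- conv1d_bwd(bk$sub$conv1, cache$c1, d)
  if (!is.null(dz_extra)) d <- d + dz_extra
  d
}

enc_stage_fwd <- function(bk, x, training) {
  if (bk$downsample == "conv") {
    cd <- conv1d_fwd(bk$sub$down_conv, x)
    mp_cache <- NULL
    h_in <- cd$y
  } else {
    mp <- maxpool2_fwd(x)
    mp_cache <- mp$cache
    cd <- conv1d_fwd(bk$sub$down_conv, mp$y)
    h_in <- cd$y
  }
  bd <- bn_fwd(bk$sub$down_bn, h_in, training)
  sd_ <- swish_fwd(bd$y)
  rc <- res_convs_fwd(bk, sd_$y, sd_$y, training)
  list(y = rc$y,
       cache = list(mp = mp_cache, cd = cd$cache, bd = bd$cache,
                    bdy = bd$y, sd = sd_$cache, rc = rc$cache))
}

enc_stage_bwd <- function(bk, cache, dy) {
  d <- res_convs_bwd(bk, cache$rc, dy)
  d <- swish_bwd(cache$sd, cache$bdy, d)
  d <- bn_bwd(bk$sub$down_bn, cache$bd, d)
  d <- conv1d_bwd(bk$sub$down_conv, cache$cd, d)
  if (!is.null(cache$mp)) d <- maxpool2_bwd(cache$mp, d)
  d
}

dec_stage_fwd <- function(bk, x, skip, training) {
  u <- upsample2_fwd(x)
  cu <- conv1d_fwd(bk$sub$up_conv, u)
  bu <- bn_fwd(bk$sub$up_bn, cu$y, training)
  su <- swish_fwd(bu$y)
  h <- su$y
  if (isTRUE(bk$has_skip)) {
    d <- dim(h)
    z_in <- array(0, dim = c(d[1L], d[2L], d[3L] + dim(skip)[3L]))
    z_in[, , seq_len(d[3L])] <- h
    z_in[, , d[3L] + seq_len(dim(skip)[3L])] <- skip
  } else {
    z_in <- h
  }
  rc <- res_convs_fwd(bk, h, z_in, training)
  list(y = rc$y,
       cache = list(cu = cu$cache, bu = bu$cache, buy = bu$y,
                    su = su$cache, rc = rc$cache, c_up = dim(h)[3L],
                    has_skip = isTRUE(bk$has_skip)))
}

dec_stage_bwd <- function(bk, cache, dy) {
  dz <- res_convs_bwd(bk, cache$rc, dy)
  if (cache$has_skip) {
    c_up <- cache$c_up
    dh <- dz[, , seq_len(c_up), drop = FALSE]
    dskip <- dz[, , (c_up + 1L):dim(dz)[3L], drop = FALSE]
  } else {
    dh <- dz
    dskip <- NULL
  }
  d <- swish_bwd(cache$su, cache$buy, dh)
  d <- bn_bwd(bk$sub$up_bn, cache$bu, d)
  d <- conv1d_bwd(bk$sub$up_conv, cache$cu, d)
  d <- upsample2_bwd(d)
  list(dx = d, dskip = dskip)
}

aspp_fwd <- function(bk, x, training) {
  nb <- bk$n_branch
  branches <- vector("list", nb)
  d <- dim(x)
  ycat <- array(0, dim = c(d[1L], d[2L], bk$cb * nb))
  for (i in seq_len(nb)) {
    cc <- conv1d_fwd(bk$sub[[paste0("branch", i, "_conv")]], x)
    bb <- bn_fwd(bk$sub[[paste0("branch", i, "_bn")]], cc$y, training)
    ss <- swish_fwd(bb$y)
    branches[[i]] <- list(cc = cc$cache, bb = bb$cache, bby = bb$y,
                          ss = ss$cache)
    ycat[, , ((i - 1L) * bk$cb + 1L):(i * bk$cb)] <- ss$y
  }
  fc <- conv1d_fwd(bk$sub$fuse_conv, ycat)
  fb <- bn_fwd(bk$sub$fuse_bn, fc$y, training)
  fsw <- swish_fwd(fb$y)
  list(y = fsw$y,
       cache = list(branches = branches, fc = fc$cache, fb = fb$cache,
                    fby = fb$y, fsw = fsw$cache, dimx = d))
}

aspp_bwd <- function(bk, cache, dy) {
  d <- swish_bwd(cache$fsw, cache$fby, dy)
  d <- bn_bwd(bk$sub$fuse_bn, cache$fb, d)
  dcat <- conv1d_bwd(bk$sub$fuse_conv, cache$fc, d)
  dx <- array(0, dim = cache$dimx)
  for (i in seq_len(bk$n_branch)) {
    br <- cache$branches[[i]]
    db <- dcat[, , ((i - 1L) * bk$cb + 1L):(i * bk$cb), drop = FALSE]
    db <- swish_bwd(br$ss, br$bby, db)
    db <- bn_bwd(bk$sub[[paste0("branch", i, "_bn")]], br$bb, db)
    dx <- dx + conv1d_bwd(bk$sub[[paste0("branch", i, "_conv")]], br$cc, db)
  }
  dx
}

transformer_fwd <- function(bk, x, training) {
  d <- dim(x); N <- d[1L]; Tb <- d[2L]; C <- d[3L]
  h <- bk$n_heads; dh <- C %/% h
  scl <- 1 / sqrt(dh)
  xm <- matrix(x, N * Tb, C)
  l1 <- ln_fwd(bk$sub$ln1, xm)
  q <- dense_fwd(bk$sub$wq, l1$y)
  kk <- dense_fwd(bk$sub$wk, l1$y)
  v <- dense_fwd(bk$sub$wv, l1$y)
  A <- vector("list", N * h)
  O <- matrix(0, N * Tb, C)
  for (n in seq_len(N)) {
    ridx <- seq(n, N * Tb, by = N)
    for (hh in seq_len(h)) {
      cidx <- ((hh - 1L) * dh + 1L):(hh * dh)
      Qn <- q$y[ridx, cidx, drop = FALSE]
      Kn <- kk$y[ridx, cidx, drop = FALSE]
      Vn <- v$y[ridx, cidx, drop = FALSE]
      An <- softmax_rows(tcrossprod(Qn, Kn) * scl)
      A[[(n - 1L) * h + hh]] <- An
      O[ridx, cidx] <- An %*% Vn
    }
  }
  o <- dense_fwd(bk$sub$wo, O)
  do1 <- dropout_fwd(o$y, bk$dropout, training)
  x2 <- xm + do1$y
  l2 <- ln_fwd(bk$sub$ln2, x2)
  f1 <- dense_fwd(bk$sub$ffn1, l2$y)
  sf <- swish_fwd(f1$y)
  do2 <- dropout_fwd(sf$y, bk$dropout, training)
  f2 <- dense_fwd(bk$sub$ffn2, do2$y)
  y <- x2 + f2$y
  list(y = array(y, dim = d),
       cache = list(l1 = l1$cache, q = q$cache, k = kk$cache, v = v$cache,
                    qy = q$y, ky = kk$y, vy = v$y, A = A, O = O,
                    o = o$cache, do1 = do1$cache, x2 = x2, l2 = l2$cache,
                    f1 = f1$cache, f1y = f1$y, sf = sf$cache,
                    do2 = do2$cache, f2 = f2$cache, dimx = d))
}

transformer_bwd <- function(bk, cache, dy) {
  d <- cache$dimx; N <- d[1L]; Tb <- d[2L]; C <- d[3L]
  h <- bk$n_heads; dh <- C %/% h
  scl <- 1 / sqrt(dh)
  dym <- matrix(dy, N * Tb, C)
  dx2 <- dym
  dd <- dense_bwd(bk$sub$ffn2, cache$f2, dym)
  dd <- dropout_bwd(cache$do2, dd)
  dd <- swish_bwd(cache$sf, cache$f1y, dd)
  dd <- dense_bwd(bk$sub$ffn1, cache$f1, dd)
  dx2 <- dx2 + ln_bwd(bk$sub$ln2, cache$l2, dd)
  dxm <- dx2
  do_ <- dropout_bwd(cache$do1, dx2)
  dO <- dense_bwd(bk$sub$wo, cache$o, do_)
  dq <- matrix(0, N * Tb, C)
  dk <- matrix(0, N * Tb, C)
  dv <- matrix(0, N * Tb, C)
  for (n in seq_len(N)) {
    ridx <- seq(n, N * Tb, by = N)
    for (hh in seq_len(h)) {
      cidx <- ((hh - 1L) * dh + 1L):(hh * dh)
      An <- cache$A[[(n - 1L) * h + hh]]
      Qn <- cache$qy[ridx, cidx, drop = FALSE]
      Kn <- cache$ky[ridx, cidx, drop = FALSE]
      Vn <- cache$vy[ridx, cidx, drop = FALSE]
      dOn <- dO[ridx, cidx, drop = FALSE]
      dA <- tcrossprod(dOn, Vn)
      dv[ridx, cidx] <- crossprod(An, dOn)
      dS <- softmax_rows_bwd(An, dA)
      dq[ridx, cidx] <- dS %*% Kn * scl
      dk[ridx, cidx] <- crossprod(dS, Qn) * scl
    }
  }
  dl1 <- dense_bwd(bk$sub$wq, cache$q, dq) +
    dense_bwd(bk$sub$wk, cache$k, dk) +
    dense_bwd(bk$sub$wv, cache$v, dv)
  dxm <- dxm + ln_bwd(bk$sub$ln1, cache$l1, dl1)
  array(dxm, dim = d)
}

smooth_fwd <- function(bk, x, training) {
  cc <- conv1d_fwd(bk$sub$conv, x)
  bb <- bn_fwd(bk$sub$bn, cc$y, training)
  ss <- swish_fwd(bb$y)
  list(y = ss$y, cache = list(cc = cc$cache, bb = bb$cache, bby = bb$y,
                              ss = ss$cache))
}

smooth_bwd <- function(bk, cache, dy) {
  d <- swish_bwd(cache$ss, cache$bby, dy)
  d <- bn_bwd(bk$sub$bn, cache$bb, d)
  conv1d_bwd(bk$sub$conv, cache$cc, d)
}

# ---- model forward / backward ---------------------------------------------

#' Forward pass through the segmentation model
#'
#' @param model A [build_model()] object.
#' @param x Input array `N x input_len x in_channels` (a matrix is treated
#'   as one window).
#' @param training Use batch statistics and dropout.
#' @param capture Optional block name whose output activation is recorded
#'   (e.g. `"smooth_conv"` for domain-gap features).
#' @return List with `p` (N x input_len probability matrix), `tape`
#'   (caches for [segnet_backward()]), and `captured` activation when
#'   requested.
#' @export
segnet_forward <- function(model, x, training = FALSE, capture = NULL) {
  cfg <- model$cfg
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L || dim(x)[2L] != cfg$input_len ||
      dim(x)[3L] != cfg$in_channels) {
    stop("input must be N x ", cfg$input_len, " x ", cfg$in_channels)
  }
  if (!is.null(capture) && !capture %in% names(model$blocks)) {
    stop("unknown layer '", capture, "'; available: ",
         paste(names(model$blocks), collapse = ", "))
  }
  tape <- list()
  captured <- NULL
  h <- x
  skips <- list()
  for (i in seq_len(cfg$depth)) {
    nm <- paste0("enc", i)
    r <- enc_stage_fwd(model$blocks[[nm]], h, training)
    h <- r$y
    tape[[nm]] <- r$cache
    if (i < cfg$depth) skips[[i]] <- h
    if (identical(capture, nm)) captured <- h
  }
  if (cfg$use_aspp) {
    r <- aspp_fwd(model$blocks$aspp, h, training)
    h <- r$y
    tape$aspp <- r$cache
    if (identical(capture, "aspp")) captured <- h
  }
  if (cfg$use_transformer) {
    h <- h + rep(model$pe, each = dim(h)[1L])  # broadcast over batch
    for (b in seq_len(cfg$n_transformer_blocks)) {
      nm <- paste0("transformer", b)
      r <- transformer_fwd(model$blocks[[nm]], h, training)
      h <- r$y
      tape[[nm]] <- r$cache
      if (identical(capture, nm)) captured <- h
    }
  }
  for (j in seq_len(cfg$depth)) {
    nm <- paste0("dec", j)
    bk <- model$blocks[[nm]]
    skip <- if (isTRUE(bk$has_skip)) skips[[cfg$depth - j]] else NULL
    r <- dec_stage_fwd(bk, h, skip, training)
    h <- r$y
    tape[[nm]] <- r$cache
    if (identical(capture, nm)) captured <- h
  }
  r <- smooth_fwd(model$blocks$smooth_conv, h, training)
  h <- r$y
  tape$smooth_conv <- r$cache
  if (identical(capture, "smooth_conv")) captured <- h
  r <- conv1d_fwd(model$blocks$head$sub$conv, h)
  tape$head <- r$cache
  z <- r$y[, , 1L, drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, nrow = dim(x)[1L])
  p <- sigmoid(z)
  if (identical(capture, "head")) captured <- r$y
  list(p = p, tape = tape, captured = captured)
}

#' Backward pass: accumulate parameter gradients
#'
#' Propagates `dL/dp` (gradient with respect to the output probabilities)
#' through the sigmoid and the whole block graph, accumulating gradients in
#' the layer environments. Returns the gradient with respect to the input.
#'
#' @param model A `segnet`.
#' @param fwd Result of [segnet_forward()] (with `training = TRUE` caches).
#' @param dp N x input_len matrix of loss gradients w.r.t. probabilities.
#' @param p_clip Clipped probabilities used for the sigmoid derivative.
#' @return Input gradient array (invisibly usable for diagnostics).
#' @export
segnet_backward <- function(model, fwd, dp, p_clip = NULL) {
  cfg <- model$cfg
  p <- if (is.null(p_clip)) fwd$p else p_clip
  dz <- dp * p * (1 - p)
  N <- nrow(dz)
  dh <- array(dz, dim = c(N, cfg$input_len, 1L))
  dh <- conv1d_bwd(model$blocks$head$sub$conv, fwd$tape$head, dh)
  dh <- smooth_bwd(model$blocks$smooth_conv, fwd$tape$smooth_conv, dh)
  dskips <- vector("list", cfg$depth)
  for (j in rev(seq_len(cfg$depth))) {
    nm <- paste0("dec", j)
    bk <- model$blocks[[nm]]
    r <- dec_stage_bwd(bk, fwd$tape[[nm]], dh)
    dh <- r$dx
    if (isTRUE(bk$has_skip)) dskips[[cfg$depth - j]] <- r$dskip
  }
  if (cfg$use_transformer) {
    for (b in rev(seq_len(cfg$n_transformer_blocks))) {
      nm <- paste0("transformer", b)
      dh <- transformer_bwd(model$blocks[[nm]], fwd$tape[[nm]], dh)
    }
  }
  if (cfg$use_aspp) {
    dh <- aspp_bwd(model$blocks$aspp, fwd$tape$aspp, dh)
  }
  for (i in rev(seq_len(cfg$depth))) {
    nm <- paste0("enc", i)
    if (i < cfg$depth && !is.null(dskips[[i]])) {
      dh <- dh + dskips[[i]]
    }
    dh <- enc_stage_bwd(model$blocks[[nm]], fwd$tape[[nm]], dh)
  }
  invisible(dh)
}

#' Predict window probabilities in evaluation mode
#'
#' Normalization layers use stored statistics, so results are
#' batch-size-invariant and deterministic.
#'
#' @param model A `segnet`.
#' @param X `N x input_len x in_channels` array.
#' @param batch_size Windows per forward chunk.
#' @return `N x input_len` matrix of probabilities.
#' @export
segnet_predict <- function(model, X, batch_size = 64L) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, dim(X)))
  N <- dim(X)[1L]
  out <- matrix(0, N, model$cfg$input_len)
  for (s in seq(1L, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, N)
    out[idx, ] <- segnet_forward(model, X[idx, , , drop = FALSE],
                                 training = FALSE)$p
  }
  out
}

#' Extract per-window features from a named layer
#'
#' Temporal mean-pooling of the named block's output activation; used for
#' PSG-vs-radar domain-gap diagnostics (canonically the `smooth_conv`
#' layer).
#'
#' @param model A `segnet`.
#' @param X `N x input_len x in_channels` array.
#' @param layer_name Block name (see `names(model$blocks)`).
#' @param batch_size Windows per forward chunk.
#' @return `N x C` feature matrix.
#' @export
extract_features <- function(model, X, layer_name = "smooth_conv",
                             batch_size = 64L) {
  if (is.matrix(X)) X <- array(X, dim = c(1L, dim(X)))
  N <- dim(X)[1L]
  feats <- NULL
  for (s in seq(1L, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, N)
    r <- segnet_forward(model, X[idx, , , drop = FALSE], training = FALSE,
                        capture = layer_name)
    f <- apply(r$captured, c(1L, 3L), mean)
    if (is.null(dim(f))) f <- matrix(f, nrow = length(idx))
    feats <- rbind(feats, f)
  }
  feats
}

# ---- parameter plumbing ---------------------------------------------------

# flat list of layer environments in definition order
layer_envs <- function(model) {
  out <- list()
  for (bk in model$blocks) {
    for (nm in names(bk$sub)) out[[bk$sub[[nm]]$name]] <- bk$sub[[nm]]
  }
  out
}

#' Get all model weights as a named list of arrays
#' @param model A `segnet`.
#' @return Named list `"<layer>/<param>"` -> array; includes batch-norm
#'   running statistics under `"<layer>/run_mean"` / `"/run_var"`.
#' @export
get_weights <- function(model) {
  out <- list()
  for (ly in layer_envs(model)) {
    for (pn in names(ly$params)) {
      out[[paste0(ly$name, "/", pn)]] <- ly$params[[pn]]
    }
    if (ly$kind == "bn") {
      out[[paste0(ly$name, "/run_mean")]] <- ly$run_mean
      out[[paste0(ly$name, "/run_var")]] <- ly$run_var
    }
  }
  out
}

#' Load weights into a model (shapes must match exactly)
#' @param model A `segnet`.
#' @param weights Named list from [get_weights()].
#' @return The model, invisibly (layers are modified in place).
#' @export
set_weights <- function(model, weights) {
  for (ly in layer_envs(model)) {
    for (pn in names(ly$params)) {
      key <- paste0(ly$name, "/", pn)
      w <- weights[[key]]
      if (is.null(w)) stop("missing weight: ", key)
      if (length(w) != length(ly$params[[pn]])) {
        stop("shape mismatch for ", key)
      }
      ly$params[[pn]][] <- w
    }
    if (ly$kind == "bn") {
      ly$run_mean <- weights[[paste0(ly$name, "/run_mean")]]
      ly$run_var <- weights[[paste0(ly$name, "/run_var")]]
    }
  }
  invisible(model)
}

#' Deterministic parameter checksum
#' @param model A `segnet`.
#' @return A single numeric summarizing all parameters.
#' @export
param_checksum <- function(model) {
  w <- get_weights(model)
  sum(vapply(w, function(p) sum(p) + sum(p^2), numeric(1)))
}

zero_grads <- function(model) {
  for (ly in layer_envs(model)) {
    for (pn in names(ly$grads)) ly$grads[[pn]][] <- 0
  }
  invisible(model)
}

#' Count trainable and total parameters
#' @param model A `segnet`.
#' @return List with `total` and `trainable` counts.
#' @export
count_params <- function(model) {
  tot <- 0L; tr <- 0L
  for (ly in layer_envs(model)) {
    n <- sum(vapply(ly$params, length, integer(1)))
    tot <- tot + n
    if (ly$trainable) tr <- tr + n
  }
  list(total = tot, trainable = tr)
}
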