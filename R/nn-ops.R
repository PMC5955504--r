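# Tensor backend for the U-net implementation.
#
# Tensors are dense 4-D arrays laid out (height, width, batch, channel).
# With this layout the im2col lowering of a convolution and the reshape of
# the resulting BLAS matrix product are plain `dim<-` changes (no
# transposition copies): the (Ho*Wo*N) x (k*k*C_in) patch matrix is row-
# ordered (h, w, n) and channel-within-shift column-ordered, matching a
# (k*k*C_in) x C_out weight matrix. Patch-gather index matrices depend only
# on the tensor shape and are cached across batches and epochs. All
# operations come in forward/backward pairs so the network is trainable by
# reverse-mode accumulation without external frameworks.

.nn_cache <- new.env(parent = emptyenv())

as_tensor <- function(x) {
  # single matrix -> (H, W, 1, 1)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4)
  x
}

pad_tensor <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(x, k, pad) {
  d <- dim(x)
  ho <- d[1] + 2L * pad - k + 1L
  wo <- d[2] + 2L * pad - k + 1L
  if (ho < 1 || wo < 1) {
    abort(sprintf("convolution grid collapsed: %dx%d input, kernel %d, pad %d",
                  d[1], d[2], k, pad))
  }
  list(m = im2col_cpp(x, d[1], d[2], d[3], d[4], k, pad), ho = ho, wo = wo)
}

col2im <- function(dm, k, pad, xdim) {
  col2im_cpp(dm, xdim[1], xdim[2], xdim[3], xdim[4], k, pad)
}

# Base-R reference implementations (shift-and-copy), used as oracles in the
# kernel tests.
im2col_ref <- function(x, k, pad) {
  d <- dim(x)
  ho <- d[1] + 2L * pad - k + 1L
  wo <- d[2] + 2L * pad - k + 1L
  xp <- pad_tensor(x, pad)
  n <- d[3]; ch <- d[4]
  m <- matrix(0, ho * wo * n, k * k * ch)
  blk <- 0L
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      sl <- xp[dy:(dy + ho - 1L), dx:(dx + wo - 1L), , , drop = FALSE]
      dim(sl) <- c(ho * wo * n, ch)
      m[, blk + seq_len(ch)] <- sl
      blk <- blk + ch
    }
  }
  m
}

col2im_ref <- function(dm, k, pad, xdim) {
  h <- xdim[1]; w <- xdim[2]; n <- xdim[3]; ch <- xdim[4]
  ho <- h + 2L * pad - k + 1L
  wo <- w + 2L * pad - k + 1L
  gp <- array(0, c(h + 2L * pad, w + 2L * pad, n, ch))
  blk <- 0L
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      b <- dm[, blk + seq_len(ch), drop = FALSE]
      dim(b) <- c(ho, wo, n, ch)
      idr <- dy:(dy + ho - 1L); idc <- dx:(dx + wo - 1L)
      gp[idr, idc, , ] <- gp[idr, idc, , , drop = FALSE] + b
      blk <- blk + ch
    }
  }
  if (pad > 0) gp[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE] else gp
}

conv_fwd <- function(x, w, b, pad, keep_cache = FALSE) {
  d <- dim(x); n <- d[3]; ch <- d[4]
  k <- as.integer(round(sqrt(nrow(w) / ch)))
  stopifnot(k * k * ch == nrow(w))
  cout <- ncol(w)
  ic <- im2col(x, k, pad)
  y <- ic$m %*% w
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(ic$ho, ic$wo, n, cout)
  if (keep_cache) list(y = y, m = ic$m, xdim = d) else list(y = y)
}

conv_bwd <- function(dy, cache, w, pad, need_dx = TRUE) {
  d <- dim(dy)
  ch <- cache$xdim[4]
  k <- as.integer(round(sqrt(nrow(w) / ch)))
  dy_m <- dy
  dim(dy_m) <- c(d[1] * d[2] * d[3], d[4])
  dw <- crossprod(cache$m, dy_m)
  db <- colSums(dy_m)
  dx <- NULL
  if (need_dx) {
    dm <- tcrossprod(dy_m, w)
    dx <- col2im(dm, k, pad, cache$xdim)
  }
  list(dx = dx, dw = dw, db = db)
}

pool_fwd <- function(x) {
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    abort(sprintf("max-pooling needs an even grid, got %dx%d", d[1], d[2]))
  }
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  x1 <- x[ro, co, , , drop = FALSE]; x2 <- x[re, co, , , drop = FALSE]
  x3 <- x[ro, ce, , , drop = FALSE]; x4 <- x[re, ce, , , drop = FALSE]
  y <- pmax(x1, x2, x3, x4)
  m1 <- x1 == y
  m2 <- (x2 == y) & !m1
  m3 <- (x3 == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(y = y, masks = list(m1, m2, m3, m4), xdim = d)
}

pool_bwd <- function(dy, cache) {
  d <- cache$xdim
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dx[ro, co, , ] <- dy * cache$masks[[1]]
  dx[re, co, , ] <- dy * cache$masks[[2]]
  dx[ro, ce, , ] <- dy * cache$masks[[3]]
  dx[re, ce, , ] <- dy * cache$masks[[4]]
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dy[ro, co, , , drop = FALSE] + dy[re, co, , , drop = FALSE] +
    dy[ro, ce, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
}

lrelu_fwd <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

lrelu_bwd <- function(dy, x, slope) dy * (slope + (1 - slope) * (x > 0))

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_channels <- function(x) {
  # stable softmax over the channel dimension of (H, W, N, C)
  d <- dim(x)
  xp <- x
  dim(xp) <- c(d[1] * d[2] * d[3], d[4])
  mx <- do.call(pmax, lapply(seq_len(d[4]), function(j) xp[, j]))
  e <- exp(xp - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

dropout_fwd <- function(x, rate) {
  keep <- 1 - rate
  mask <- array((runif(length(x)) < keep) / keep, dim(x))
  list(y = x * mask, mask = mask)
}

# Centre-crop the spatial dims of a tensor by `crop` pixels per edge.
crop_tensor <- function(x, crop) {
  if (crop == 0) return(x)
  d <- dim(x)
  x[(crop + 1L):(d[1] - crop), (crop + 1L):(d[2] - crop), , , drop = FALSE]
}

# Embed a gradient back into the uncropped spatial extent.
uncrop_tensor <- function(dy, crop, full_dim) {
  if (crop == 0) return(dy)
  g <- array(0, full_dim)
  d <- dim(dy)
  g[(crop + 1L):(crop + d[1]), (crop + 1L):(crop + d[2]), , ] <- dy
  g
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:3] == db[1:3])) {
    abort("skip connection shapes differ; cannot concatenate")
  }
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}
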