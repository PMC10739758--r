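# Low-level differentiable tensor operations.
#
# Feature maps are numeric arrays of dim c(N, H, W, C) (batch leading).
# Every *_fwd returns list(out = ..., cache = ...); the matching *_bwd takes the
# upstream gradient plus the cache and returns the input gradient and, where the
# op has parameters, their gradients. All backward passes are checked against
# central finite differences in the test suite.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L, 4L)))
    stop("expected an array of dim (H,W), (H,W,C) or (N,H,W,C)")
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) {
    dim(x) <- c(1L, d)
    attr(x, "was_single") <- TRUE
  }
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  if (d[1L] == 1L) array(x, d[-1L]) else x
}

# ---- convolution (stride 1, symmetric zero padding, odd kernel) --------------

#' @noRd
conv_init <- function(k, c_in, c_out, seed_rng = NULL) {
  fan_in <- k * k * c_in
  w <- matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out)
  attr(w, "kernel") <- k
  attr(w, "c_in") <- c_in
  attr(w, "c_out") <- c_out
  w
}

# im2col: rows are pixels in (n, i, j) linear order, columns are (c within
# (di, dj)) blocks ordered dj-outer, di-inner, matching conv weight row layout.
im2col <- function(x, k) {
  d <- dim(x)
  n <- d[1L]; h <- d[2L]; w <- d[3L]; ch <- d[4L]
  p <- (k - 1L) %/% 2L
  if (p > 0L) {
    xp <- array(0, c(n, h + 2L * p, w + 2L * p, ch))
    xp[, (p + 1L):(p + h), (p + 1L):(p + w), ] <- x
  } else xp <- x
  cols <- vector("list", k * k)
  idx <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    s <- xp[, (1L + di):(h + di), (1L + dj):(w + dj), , drop = FALSE]
    cols[[idx]] <- matrix(s, n * h * w, ch)
    idx <- idx + 1L
  }
  do.call(cbind, cols)
}

col2im <- function(dcol, dimx, k) {
  n <- dimx[1L]; h <- dimx[2L]; w <- dimx[3L]; ch <- dimx[4L]
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(n, h + 2L * p, w + 2L * p, ch))
  idx <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    blk <- array(dcol[, ((idx - 1L) * ch + 1L):(idx * ch)], c(n, h, w, ch))
    cur <- dxp[, (1L + di):(h + di), (1L + dj):(w + dj), , drop = FALSE]
    dxp[, (1L + di):(h + di), (1L + dj):(w + dj), ] <- cur + blk
    idx <- idx + 1L
  }
  if (p > 0L) dxp[, (p + 1L):(p + h), (p + 1L):(p + w), , drop = FALSE] else dxp
}

conv_fwd <- function(x, w, b) {
  k <- attr(w, "kernel")
  d <- dim(x)
  xcol <- if (k == 1L) matrix(x, prod(d[1:3]), d[4L]) else im2col(x, k)
  out <- xcol %*% w
  out <- out + rep(b, each = nrow(out))
  list(out = array(out, c(d[1:3], ncol(w))), cache = list(xcol = xcol, dimx = d, w = w))
}

conv_bwd <- function(dout, cache) {
  k <- attr(cache$w, "kernel")
  dmat <- matrix(dout, nrow(cache$xcol), attr(cache$w, "c_out"))
  dw <- crossprod(cache$xcol, dmat)
  attributes(dw) <- attributes(cache$w)
  db <- colSums(dmat)
  dcol <- tcrossprod(dmat, cache$w)
  dx <- if (k == 1L) array(dcol, cache$dimx) else col2im(dcol, cache$dimx, k)
  list(dx = dx, dw = dw, db = db)
}

# ---- batch normalisation (per channel over N*H*W) ----------------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, prod(d[1:3]), d[4L])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    va <- pmax(va, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean
    va <- run_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(istd, each = nrow(xm))
  y <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  list(out = array(y, d),
       cache = list(xhat = xhat, istd = istd, gamma = gamma, dimx = d, training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dout, cache) {
  d <- cache$dimx
  n <- prod(d[1:3])
  dy <- matrix(dout, n, d[4L])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(cache$gamma, each = n)
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dx <- (dxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
      rep(cache$istd, each = n)
  } else {
    dx <- dxhat * rep(cache$istd, each = n)
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU --------------------------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, cache = m)
}

relu_bwd <- function(dout, cache) dout * cache

# ---- 2x2 stride-2 max pooling with argmax indices ----------------------------

# Returns, besides the pooled map, the linear indices (into as.vector(x)) of
# each window maximum: these are the pooling indices routed to the decoder's
# max-unpooling stages.
maxpool_fwd <- function(x) {
  d <- dim(x)
  n <- d[1L]; h <- d[2L]; w <- d[3L]; ch <- d[4L]
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("max pooling requires even spatial dims, got ", h, "x", w)
  hp <- h %/% 2L; wp <- w %/% 2L
  v <- cbind(
    as.vector(x[, seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE]),
    as.vector(x[, seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE]),
    as.vector(x[, seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE]),
    as.vector(x[, seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]))
  choice <- max.col(v, ties.method = "first")
  out <- v[cbind(seq_len(nrow(v)), choice)]
  t0 <- seq_len(nrow(v)) - 1L
  nn <- t0 %% n
  rest <- t0 %/% n
  ph <- rest %% hp
  rest <- rest %/% hp
  pw <- rest %% wp
  cc <- rest %/% wp
  di <- c(0L, 1L, 0L, 1L)[choice]
  dj <- c(0L, 0L, 1L, 1L)[choice]
  i <- 2L * ph + di
  j <- 2L * pw + dj
  lin <- nn + n * (i + h * (j + w * cc)) + 1L
  list(out = array(out, c(n, hp, wp, ch)),
       indices = lin, in_dim = d)
}

maxpool_bwd <- function(dout, indices, in_dim) {
  dx <- numeric(prod(in_dim))
  dx[indices] <- as.vector(dout)
  array(dx, in_dim)
}

# Max unpooling: place each pooled value back at its recorded argmax
# coordinate, zeros elsewhere.
unpool_fwd <- function(z, indices, out_dim) {
  if (length(indices) != length(z))
    stop("pooling indices do not match feature shape")
  v <- numeric(prod(out_dim))
  v[indices] <- as.vector(z)
  array(v, out_dim)
}

unpool_bwd <- function(dout, indices, z_dim) {
  array(as.vector(dout)[indices], z_dim)
}

# ---- dense / layer norm / softmax (token matrices, n_tokens x width) ---------

linear_fwd <- function(x, w, b = NULL) {
  out <- x %*% w
  if (!is.null(b)) out <- out + rep(b, each = nrow(x))
  list(out = out, cache = list(x = x, w = w, has_b = !is.null(b)))
}

linear_bwd <- function(dout, cache) {
  list(dx = tcrossprod(dout, cache$w),
       dw = crossprod(cache$x, dout),
       db = if (cache$has_b) colSums(dout) else NULL)
}

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(out = y, cache = list(xhat = xhat, istd = istd, gamma = gamma))
}

layernorm_bwd <- function(dout, cache) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) * cache$istd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

# d/ds of softmax applied rowwise: da is gradient w.r.t. the softmax output a.
softmax_rows_bwd <- function(da, a) {
  a * (da - rowSums(da * a))
}

# ---- bilinear interpolation as a precomputed linear map ----------------------

# 1-D interpolation matrix mapping n_in samples to n_out samples with
# half-pixel centre alignment; resizing a grid is Rr %*% G %*% t(Rc) per
# channel, so the backward pass is the transpose map.
interp_matrix <- function(n_out, n_in) {
  m <- matrix(0, n_out, n_in)
  if (n_in == 1L) { m[, 1L] <- 1; return(m) }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  fr <- src - lo
  for (i in seq_len(n_out)) {
    m[i, lo[i] + 1L] <- m[i, lo[i] + 1L] + (1 - fr[i])
    if (fr[i] > 0) m[i, lo[i] + 2L] <- m[i, lo[i] + 2L] + fr[i]
  }
  m
}

# Resize a (H,W,C) grid bilinearly to (h_out, w_out).
resize_bilinear <- function(g, h_out, w_out) {
  d <- dim(g)
  rr <- interp_matrix(h_out, d[1L])
  rc <- interp_matrix(w_out, d[2L])
  out <- array(0, c(h_out, w_out, d[3L]))
  for (ch in seq_len(d[3L])) out[, , ch] <- rr %*% g[, , ch] %*% t(rc)
  out
}

resize_bilinear_bwd <- function(dout, h_in, w_in) {
  d <- dim(dout)
  rr <- interp_matrix(d[1L], h_in)
  rc <- interp_matrix(d[2L], w_in)
  dg <- array(0, c(h_in, w_in, d[3L]))
  for (ch in seq_len(d[3L])) dg[, , ch] <- t(rr) %*% dout[, , ch] %*% rc
  dg
}
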