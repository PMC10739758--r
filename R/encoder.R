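# Five-level convolutional encoder of shape-preservation blocks (SPBs) and
# residual blocks (RBs).
#
# SPB (4 conv, 4 BN, 2 ReLU), spatial dims preserved:
#   main: conv3x3-BN-ReLU-conv3x3-BN;  shortcut: conv1x1-BN;
#   sum -> ReLU -> conv3x3-BN.
# RB (3 conv, 3 BN, 2 ReLU, 1 maxpool), spatial dims halved:
#   main: conv3x3-BN-ReLU-conv3x3-BN;  shortcut: conv1x1-BN;
#   sum -> ReLU -> 2x2 stride-2 max pool with argmax indices.

bn_init <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       run_mean = rep(0, ch), run_var = rep(1, ch))
}

bn_call <- function(x, bnp, training) {
  f <- bn_fwd(x, bnp$gamma, bnp$beta, bnp$run_mean, bnp$run_var, training)
  bnp$run_mean <- f$run_mean
  bnp$run_var <- f$run_var
  list(out = f$out, cache = f$cache, bnp = bnp)
}

log_op <- function(recorder, op) {
  if (!is.null(recorder)) recorder$ops <- c(recorder$ops, op)
  invisible(NULL)
}

#' Initialise a shape-preservation block
#' @param c_in,c_out input/output channel counts.
#' @return parameter list (4 convolutions, 4 batch norms).
#' @export
init_spb_params <- function(c_in, c_out) {
  list(conv1 = list(W = conv_init(3L, c_in, c_out), b = rep(0, c_out)),
       bn1 = bn_init(c_out),
       conv2 = list(W = conv_init(3L, c_out, c_out), b = rep(0, c_out)),
       bn2 = bn_init(c_out),
       conv3 = list(W = conv_init(1L, c_in, c_out), b = rep(0, c_out)),
       bn3 = bn_init(c_out),
       conv4 = list(W = conv_init(3L, c_out, c_out), b = rep(0, c_out)),
       bn4 = bn_init(c_out))
}

#' Initialise a residual block
#' @param c_in,c_out input/output channel counts.
#' @return parameter list (3 convolutions, 3 batch norms).
#' @export
init_rb_params <- function(c_in, c_out) {
  list(conv1 = list(W = conv_init(3L, c_in, c_out), b = rep(0, c_out)),
       bn1 = bn_init(c_out),
       conv2 = list(W = conv_init(3L, c_out, c_out), b = rep(0, c_out)),
       bn2 = bn_init(c_out),
       conv3 = list(W = conv_init(1L, c_in, c_out), b = rep(0, c_out)),
       bn3 = bn_init(c_out))
}

spb_fwd <- function(x, sp, training = FALSE, recorder = NULL) {
  c1 <- conv_fwd(x, sp$conv1$W, sp$conv1$b); log_op(recorder, "conv")
  b1 <- bn_call(c1$out, sp$bn1, training); log_op(recorder, "bn")
  r1 <- relu_fwd(b1$out); log_op(recorder, "relu")
  c2 <- conv_fwd(r1$out, sp$conv2$W, sp$conv2$b); log_op(recorder, "conv")
  b2 <- bn_call(c2$out, sp$bn2, training); log_op(recorder, "bn")
  c3 <- conv_fwd(x, sp$conv3$W, sp$conv3$b); log_op(recorder, "conv")
  b3 <- bn_call(c3$out, sp$bn3, training); log_op(recorder, "bn")
  s <- b2$out + b3$out
  r2 <- relu_fwd(s); log_op(recorder, "relu")
  c4 <- conv_fwd(r2$out, sp$conv4$W, sp$conv4$b); log_op(recorder, "conv")
  b4 <- bn_call(c4$out, sp$bn4, training); log_op(recorder, "bn")
  sp$bn1 <- b1$bnp; sp$bn2 <- b2$bnp; sp$bn3 <- b3$bnp; sp$bn4 <- b4$bnp
  list(out = b4$out, params = sp,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache, c2 = c2$cache,
                    b2 = b2$cache, c3 = c3$cache, b3 = b3$cache, r2 = r2$cache,
                    c4 = c4$cache, b4 = b4$cache))
}

spb_bwd <- function(dout, cache) {
  g4b <- bn_bwd(dout, cache$b4)
  g4 <- conv_bwd(g4b$dx, cache$c4)
  gr2 <- relu_bwd(g4$dx, cache$r2)
  g2b <- bn_bwd(gr2, cache$b2)
  g2 <- conv_bwd(g2b$dx, cache$c2)
  gr1 <- relu_bwd(g2$dx, cache$r1)
  g1b <- bn_bwd(gr1, cache$b1)
  g1 <- conv_bwd(g1b$dx, cache$c1)
  g3b <- bn_bwd(gr2, cache$b3)
  g3 <- conv_bwd(g3b$dx, cache$c3)
  list(dx = g1$dx + g3$dx,
       grads = list(
         conv1 = list(W = g1$dw, b = g1$db),
         bn1 = list(gamma = g1b$dgamma, beta = g1b$dbeta),
         conv2 = list(W = g2$dw, b = g2$db),
         bn2 = list(gamma = g2b$dgamma, beta = g2b$dbeta),
         conv3 = list(W = g3$dw, b = g3$db),
         bn3 = list(gamma = g3b$dgamma, beta = g3b$dbeta),
         conv4 = list(W = g4$dw, b = g4$db),
         bn4 = list(gamma = g4b$dgamma, beta = g4b$dbeta)))
}

rb_fwd <- function(x, rp, training = FALSE, recorder = NULL) {
  c1 <- conv_fwd(x, rp$conv1$W, rp$conv1$b); log_op(recorder, "conv")
  b1 <- bn_call(c1$out, rp$bn1, training); log_op(recorder, "bn")
  r1 <- relu_fwd(b1$out); log_op(recorder, "relu")
  c2 <- conv_fwd(r1$out, rp$conv2$W, rp$conv2$b); log_op(recorder, "conv")
  b2 <- bn_call(c2$out, rp$bn2, training); log_op(recorder, "bn")
  c3 <- conv_fwd(x, rp$conv3$W, rp$conv3$b); log_op(recorder, "conv")
  b3 <- bn_call(c3$out, rp$bn3, training); log_op(recorder, "bn")
  s <- b2$out + b3$out
  r2 <- relu_fwd(s); log_op(recorder, "relu")
  mp <- maxpool_fwd(r2$out); log_op(recorder, "maxpool")
  rp$bn1 <- b1$bnp; rp$bn2 <- b2$bnp; rp$bn3 <- b3$bnp
  list(out = mp$out, indices = mp$indices, prepool = r2$out, params = rp,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache, c2 = c2$cache,
                    b2 = b2$cache, c3 = c3$cache, b3 = b3$cache, r2 = r2$cache,
                    mp_indices = mp$indices, mp_in_dim = mp$in_dim))
}

# dprepool: extra gradient injected at the pre-pool activation (from the
# decoder's skip connection); may be NULL.
rb_bwd <- function(dout, cache, dprepool = NULL) {
  dpool <- maxpool_bwd(dout, cache$mp_indices, cache$mp_in_dim)
  if (!is.null(dprepool)) dpool <- dpool + dprepool
  gr2 <- relu_bwd(dpool, cache$r2)
  g2b <- bn_bwd(gr2, cache$b2)
  g2 <- conv_bwd(g2b$dx, cache$c2)
  gr1 <- relu_bwd(g2$dx, cache$r1)
  g1b <- bn_bwd(gr1, cache$b1)
  g1 <- conv_bwd(g1b$dx, cache$c1)
  g3b <- bn_bwd(gr2, cache$b3)
  g3 <- conv_bwd(g3b$dx, cache$c3)
  list(dx = g1$dx + g3$dx,
       grads = list(
         conv1 = list(W = g1$dw, b = g1$db),
         bn1 = list(gamma = g1b$dgamma, beta = g1b$dbeta),
         conv2 = list(W = g2$dw, b = g2$db),
         bn2 = list(gamma = g2b$dgamma, beta = g2b$dbeta),
         conv3 = list(W = g3$dw, b = g3$db),
         bn3 = list(gamma = g3b$dgamma, beta = g3b$dbeta)))
}

#' Forward pass of a shape-preservation block
#'
#' Spatial dimensions are preserved exactly; the block applies 4
#' convolutions, 4 batch normalisations and 2 ReLUs (main path
#' conv-BN-ReLU-conv-BN, projection shortcut conv-BN, elementwise sum, ReLU,
#' then conv-BN).
#'
#' @param x `(H, W, C_in)` or `(N, H, W, C_in)` feature array.
#' @param params from [init_spb_params()].
#' @param training use batch statistics (and update running stats) in the
#'   batch norms.
#' @param recorder optional environment; every applied primitive op is
#'   appended to `recorder$ops` (layer-census audits).
#' @return feature array with the same spatial dims and `c_out` channels.
#' @export
spb_forward <- function(x, params, training = FALSE, recorder = NULL) {
  xb <- as_batch(x)
  out <- spb_fwd(xb, params, training, recorder)$out
  if (isTRUE(attr(xb, "was_single"))) drop_batch(out) else out
}

#' Forward pass of a residual block
#'
#' Applies 3 convolutions, 3 batch normalisations, 2 ReLUs and one 2x2
#' stride-2 max pooling; spatial dims are halved and the argmax pooling
#' indices are returned for the decoder's max-unpooling.
#'
#' @inheritParams spb_forward
#' @param params from [init_rb_params()].
#' @return list: `out` (pooled features), `indices` (linear argmax indices
#'   into the pre-pool tensor), `prepool` (pre-pool activation, the encoder
#'   skip feature).
#' @export
rb_forward <- function(x, params, training = FALSE, recorder = NULL) {
  xb <- as_batch(x)
  f <- rb_fwd(xb, params, training, recorder)
  if (isTRUE(attr(xb, "was_single"))) {
    f$out <- drop_batch(f$out)
    f$prepool <- drop_batch(f$prepool)
  }
  f[c("out", "indices", "prepool")]
}

init_encoder_params <- function(cfg) {
  w <- cfg$widths
  levels <- vector("list", 5L)
  c_in <- 3L
  for (i in 1:5) {
    spbs <- vector("list", cfg$spb_per_level[i])
    cin <- c_in
    for (j in seq_along(spbs)) {
      spbs[[j]] <- init_spb_params(cin, w[i])
      cin <- w[i]
    }
    levels[[i]] <- list(spbs = spbs, rb = init_rb_params(w[i], w[i]))
    c_in <- w[i]
  }
  levels
}

encoder_fwd_full <- function(enc, x, training = FALSE, recorder = NULL) {
  skips <- indices <- caches <- vector("list", 5L)
  z <- x
  for (i in 1:5) {
    lev <- enc[[i]]
    spb_caches <- vector("list", length(lev$spbs))
    for (j in seq_along(lev$spbs)) {
      f <- spb_fwd(z, lev$spbs[[j]], training, recorder)
      lev$spbs[[j]] <- f$params
      spb_caches[[j]] <- f$cache
      z <- f$out
    }
    f <- rb_fwd(z, lev$rb, training, recorder)
    lev$rb <- f$params
    skips[[i]] <- f$prepool
    indices[[i]] <- f$indices
    caches[[i]] <- list(spbs = spb_caches, rb = f$cache)
    z <- f$out
    enc[[i]] <- lev
  }
  list(f_e = z, skips = skips, indices = indices, caches = caches, params = enc)
}

# dfe: gradient at f_e; dskips: list of gradients injected at each level's
# pre-pool skip feature (NULL entries allowed).
encoder_bwd_full <- function(dfe, caches, dskips = NULL) {
  grads <- vector("list", 5L)
  dz <- dfe
  for (i in 5:1) {
    cc <- caches[[i]]
    dsk <- if (!is.null(dskips)) dskips[[i]] else NULL
    g <- rb_bwd(dz, cc$rb, dsk)
    rb_grads <- g$grads
    dz <- g$dx
    spb_grads <- vector("list", length(cc$spbs))
    for (j in rev(seq_along(cc$spbs))) {
      g <- spb_bwd(dz, cc$spbs[[j]])
      spb_grads[[j]] <- g$grads
      dz <- g$dx
    }
    grads[[i]] <- list(spbs = spb_grads, rb = rb_grads)
  }
  list(dx = dz, grads = grads)
}

#' Full encoder forward pass
#'
#' Applies levels E-1..E-5 in order (each level: its SPBs, then its RB),
#' downsampling by 2^5 in total.
#'
#' @param x `(H, W, 3)` or `(N, H, W, 3)` image array; spatial dims must be
#'   divisible by 32.
#' @param params encoder parameter list (e.g. `build_model(cfg)$params$enc`).
#' @inheritParams spb_forward
#' @return list: `f_e` (latent features at 1/32 resolution), `skips` (5
#'   pre-pool activations), `indices` (5 pooling index vectors).
#' @export
encoder_forward <- function(x, params, training = FALSE, recorder = NULL) {
  xb <- as_batch(x)
  d <- dim(xb)
  if (any(d[2:3] %% 32L != 0L))
    stop("encoder input dims must be divisible by 2^5 = 32, got ",
         d[2L], "x", d[3L])
  f <- encoder_fwd_full(params, xb, training, recorder)
  if (isTRUE(attr(xb, "was_single"))) {
    f$f_e <- drop_batch(f$f_e)
    f$skips <- lapply(f$skips, drop_batch)
  }
  f[c("f_e", "skips", "indices")]
}

# Count conv / BN parameter tensors in a (nested) parameter list, recognising
# entries by their initialiser layout.
count_conv_bn <- function(p) {
  conv <- 0L; bn <- 0L
  walk <- function(x) {
    if (!is.list(x)) return(invisible(NULL))
    nm <- names(x)
    if (!is.null(nm) && all(c("W", "b") %in% nm) && !is.null(attr(x$W, "kernel"))) {
      conv <<- conv + 1L
    } else if (!is.null(nm) && all(c("gamma", "beta", "run_mean", "run_var") %in% nm)) {
      bn <<- bn + 1L
    } else {
      for (e in x) walk(e)
    }
  }
  walk(p)
  c(conv = conv, bn = bn)
}

#' Audit the encoder's block composition
#'
#' Introspects an encoder parameter list and reports the number of SPBs and
#' RBs per level plus total convolution / batch-norm layer counts.
#' @param params encoder parameter list.
#' @return list with `spb_total`, `rb_total`, `spb_per_level`, `conv`, `bn`.
#' @export
encoder_census <- function(params) {
  spb_per_level <- vapply(params, function(l) length(l$spbs), integer(1))
  counts <- count_conv_bn(params)
  list(spb_total = sum(spb_per_level), rb_total = length(params),
       spb_per_level = spb_per_level,
       conv = unname(counts["conv"]), bn = unname(counts["bn"]))
}
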