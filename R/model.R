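# Full model: convolutional encoder + cascaded patch-transformer branch,
# fused into f_d, decoded by index-routed max-unpooling with skip connections
# to a per-pixel class probability map.

#' Build a segmentation model
#'
#' Initialises all parameters (He initialisation for convolutions, Xavier for
#' dense maps, learned positional embeddings) for the configured
#' convolutional-transformer network.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the initialisation.
#' @return model list: `params` (nested parameter lists for `enc`, `tr`,
#'   `fus`, `dec`), `config`, `hash` (config hash embedded in checkpoints).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  with_seed(seed, {
    w <- config$widths
    c5 <- w[5L]
    params <- list(enc = init_encoder_params(config))
    if (config$use_transformer) {
      p <- config$transformer$patch_size
      l <- config$transformer$width
      params$tr <- init_transformer_params(
        n_p = config$n_p, patch_dim = p * p * 3L, l = l,
        h = config$transformer$heads, ff_width = config$transformer$ff_width,
        depth = config$transformer$depth)
      fus_in <- if (config$fusion == "concat") 2L * c5 else c5
      params$fus <- list(
        proj = list(W = matrix(stats::rnorm(l * c5, sd = sqrt(2 / (l + c5))), l, c5),
                    b = rep(0, c5)),
        conv = list(W = conv_init(3L, fus_in, c5), b = rep(0, c5)))
    }
    dec <- vector("list", 5L)
    for (i in 5:1) {
      cout <- if (i > 1L) w[i - 1L] else w[1L]
      dec[[i]] <- list(conv = list(W = conv_init(3L, w[i], cout), b = rep(0, cout)),
                       bn = bn_init(cout))
    }
    params$dec <- dec
    params$out <- list(W = conv_init(1L, w[1L], config$n_classes),
                       b = rep(0, config$n_classes))
    structure(list(params = params, config = config, hash = config_hash(config)),
              class = "tf_model")
  })
}

#' Total number of trainable parameters
#' @param model a model from [build_model()].
#' @export
param_count <- function(model) {
  n <- 0L
  walk <- function(x, nm = "") {
    if (is.list(x)) {
      for (k in seq_along(x)) walk(x[[k]], if (!is.null(names(x))) names(x)[k] else "")
    } else if (is.numeric(x) && !nm %in% c("run_mean", "run_var")) {
      n <<- n + length(x)
    }
  }
  walk(model$params)
  n
}

#' Fuse convolutional features with transformer projections
#'
#' The token sequence `p_t` is arranged on its patch grid, bilinearly resized
#' to the spatial dims of `f_e`, linearly projected to `f_e`'s channel width
#' and fused (elementwise product, so the projections act as a multiplicative
#' filter on the latent features — or channel concatenation when
#' `fusion = "concat"`); a 3x3 convolution then produces `f_d`.
#'
#' @param f_e `(h, w, C)` latent feature map (single sample).
#' @param p_t `(n_p, l)` transformer projections.
#' @param params fusion parameters (`build_model(cfg)$params$fus`).
#' @param grid `c(rows, cols)` of the patch grid (`prod(grid) = n_p`).
#' @param fusion `"product"` or `"concat"`.
#' @return `(h, w, C)` fused feature map `f_d`.
#' @export
fuse <- function(f_e, p_t, params, grid, fusion = "product") {
  f <- fuse_fwd(as_batch(f_e), list(p_t), params, grid, fusion)
  drop_batch(f$out)
}

# token matrix -> (gh, gw, l) grid (row-major token order)
tokens_to_grid <- function(p_t, grid) {
  g <- array(0, c(grid[1L], grid[2L], ncol(p_t)))
  k <- 1L
  for (gi in seq_len(grid[1L])) for (gj in seq_len(grid[2L])) {
    g[gi, gj, ] <- p_t[k, ]
    k <- k + 1L
  }
  g
}

grid_to_tokens <- function(g) {
  d <- dim(g)
  out <- matrix(0, d[1L] * d[2L], d[3L])
  k <- 1L
  for (gi in seq_len(d[1L])) for (gj in seq_len(d[2L])) {
    out[k, ] <- g[gi, gj, ]
    k <- k + 1L
  }
  out
}

# Batched fusion: p_t_list has one (n_p x l) matrix per sample.
fuse_fwd <- function(f_e, p_t_list, fp, grid, fusion) {
  d <- dim(f_e)
  n <- d[1L]; h <- d[2L]; w <- d[3L]; ch <- d[4L]
  if (length(p_t_list) != n) stop("one token matrix per sample required")
  gate <- array(0, c(n, h, w, ch))
  gcaches <- vector("list", n)
  for (s in seq_len(n)) {
    p_t <- p_t_list[[s]]
    if (nrow(p_t) != prod(grid)) stop("token count does not match the patch grid")
    tg <- tokens_to_grid(p_t, grid)
    rg <- resize_bilinear(tg, h, w)
    pl <- linear_fwd(matrix(rg, h * w, dim(tg)[3L]), fp$proj$W, fp$proj$b)
    gate[s, , , ] <- array(pl$out, c(h, w, ch))
    gcaches[[s]] <- list(lin = pl$cache, grid_dim = dim(tg))
  }
  pre <- if (fusion == "concat") {
    ar <- array(0, c(n, h, w, 2L * ch)); ar[, , , 1:ch] <- f_e
    ar[, , , (ch + 1L):(2L * ch)] <- gate; ar
  } else f_e * gate
  cv <- conv_fwd(pre, fp$conv$W, fp$conv$b)
  list(out = cv$out,
       cache = list(conv = cv$cache, gate = gate, f_e = f_e, gcaches = gcaches,
                    fusion = fusion, dims = d))
}

fuse_bwd <- function(dout, cache) {
  d <- cache$dims
  n <- d[1L]; h <- d[2L]; w <- d[3L]; ch <- d[4L]
  gc <- conv_bwd(dout, cache$conv)
  if (cache$fusion == "concat") {
    dfe <- gc$dx[, , , 1:ch, drop = FALSE]
    dgate <- gc$dx[, , , (ch + 1L):(2L * ch), drop = FALSE]
  } else {
    dfe <- gc$dx * cache$gate
    dgate <- gc$dx * cache$f_e
  }
  dproj_W <- 0; dproj_b <- 0
  dtok <- vector("list", n)
  for (s in seq_len(n)) {
    gcs <- cache$gcaches[[s]]
    gl <- linear_bwd(matrix(dgate[s, , , ], h * w, ch), gcs$lin)
    dproj_W <- dproj_W + gl$dw
    dproj_b <- dproj_b + gl$db
    drg <- array(gl$dx, c(h, w, gcs$grid_dim[3L]))
    dtg <- resize_bilinear_bwd(drg, gcs$grid_dim[1L], gcs$grid_dim[2L])
    dtok[[s]] <- grid_to_tokens(dtg)
  }
  list(dfe = dfe, dtok = dtok,
       grads = list(proj = list(W = dproj_W, b = dproj_b),
                    conv = list(W = gc$dw, b = gc$db)))
}

decoder_fwd_full <- function(dec, outp, f_d, indices, skips, training = FALSE,
                             recorder = NULL) {
  z <- f_d
  caches <- vector("list", 5L)
  for (i in 5:1) {
    prepool_dim <- dim(skips[[i]])
    z <- unpool_fwd(z, indices[[i]], prepool_dim); log_op(recorder, "unpool")
    zdim_pooled <- c(prepool_dim[1L], prepool_dim[2L] %/% 2L,
                     prepool_dim[3L] %/% 2L, prepool_dim[4L])
    z <- z + skips[[i]]
    cv <- conv_fwd(z, dec[[i]]$conv$W, dec[[i]]$conv$b); log_op(recorder, "conv")
    bn <- bn_call(cv$out, dec[[i]]$bn, training); log_op(recorder, "bn")
    rl <- relu_fwd(bn$out); log_op(recorder, "relu")
    dec[[i]]$bn <- bn$bnp
    caches[[i]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                        indices = indices[[i]], zdim = zdim_pooled)
    z <- rl$out
  }
  ov <- conv_fwd(z, outp$W, outp$b); log_op(recorder, "conv")
  list(logits = ov$out, params = dec,
       cache = list(stages = caches, out = ov$cache))
}

decoder_bwd_full <- function(dlogits, cache) {
  go <- conv_bwd(dlogits, cache$out)
  dz <- go$dx
  grads <- vector("list", 5L)
  dskips <- vector("list", 5L)
  for (i in 1:5) {
    cc <- cache$stages[[i]]
    gr <- relu_bwd(dz, cc$relu)
    gb <- bn_bwd(gr, cc$bn)
    gc <- conv_bwd(gb$dx, cc$conv)
    dskips[[i]] <- gc$dx
    dz <- unpool_bwd(gc$dx, cc$indices, cc$zdim)
    grads[[i]] <- list(conv = list(W = gc$dw, b = gc$db),
                       bn = list(gamma = gb$dgamma, beta = gb$dbeta))
  }
  list(dfd = dz, dskips = dskips,
       grads = list(dec = grads, out = list(W = go$dw, b = go$db)))
}

#' Decoder forward pass
#'
#' Five mirror stages (max-unpooling routed by the encoder's stored argmax
#' indices, elementwise addition of the matching skip feature, then a
#' rescaling unit conv-BN-ReLU), followed by a 1x1 convolution to the class
#' logits and a softmax over the class axis.
#'
#' @param f_d fused features at 1/32 resolution (`(h, w, C)` or batched).
#' @param indices list of 5 pooling index vectors from the paired encoder
#'   pass.
#' @param skips list of 5 encoder skip features.
#' @param params list with `dec` (5 rescaling units) and `out` (final 1x1
#'   conv), e.g. from `build_model(cfg)$params`.
#' @param tau softmax temperature for the probability map.
#' @return list: `logits` (`R x C x c_se`), `probs` (softmax of logits).
#' @export
decoder_forward <- function(f_d, indices, skips, params, tau = 1) {
  fd <- as_batch(f_d)
  single <- isTRUE(attr(fd, "was_single"))
  skips_b <- if (single) lapply(skips, as_batch) else skips
  f <- decoder_fwd_full(params$dec, params$out, fd, indices, skips_b)
  logits <- if (single) drop_batch(f$logits) else f$logits
  list(logits = logits, probs = temperature_softmax(logits, tau))
}

# Full network forward with caches (batched input (N,H,W,3)).
net_fwd <- function(params, config, x, training = FALSE, recorder = NULL) {
  enc <- encoder_fwd_full(params$enc, x, training, recorder)
  params$enc <- enc$params
  cache <- list(enc = enc$caches)
  if (config$use_transformer) {
    n <- dim(x)[1L]
    p <- config$transformer$patch_size
    grid <- c(dim(x)[2L] %/% p, dim(x)[3L] %/% p)
    p_t <- vector("list", n)
    trc <- vector("list", n)
    for (s in seq_len(n)) {
      tb <- transformer_branch_fwd(array(x[s, , , ], dim(x)[-1L]), params$tr,
                                   config$n_p)
      p_t[[s]] <- tb$out
      trc[[s]] <- tb$cache
    }
    fu <- fuse_fwd(enc$f_e, p_t, params$fus, grid, config$fusion)
    f_d <- fu$out
    cache$tr <- trc
    cache$fus <- fu$cache
  } else {
    f_d <- enc$f_e
  }
  dc <- decoder_fwd_full(params$dec, params$out, f_d, enc$indices, enc$skips,
                         training, recorder)
  params$dec <- dc$params
  cache$dec <- dc$cache
  list(logits = dc$logits, cache = cache, params = params)
}

net_bwd <- function(dlogits, cache, params, config) {
  gd <- decoder_bwd_full(dlogits, cache$dec)
  grads <- list(dec = gd$grads$dec, out = gd$grads$out)
  if (config$use_transformer) {
    gf <- fuse_bwd(gd$dfd, cache$fus)
    grads$fus <- gf$grads
    dfe <- gf$dfe
    tr_grads <- NULL
    for (s in seq_along(gf$dtok)) {
      g <- transformer_branch_bwd(gf$dtok[[s]], cache$tr[[s]], params$tr)
      tr_grads <- if (is.null(tr_grads)) g else add_grad_trees(tr_grads, g)
    }
    grads$tr <- tr_grads
  } else {
    dfe <- gd$dfd
  }
  ge <- encoder_bwd_full(dfe, cache$enc, gd$dskips)
  grads$enc <- ge$grads
  grads
}

add_grad_trees <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- add_grad_trees(a[[k]], b[[k]])
    a
  } else if (is.null(a)) b else a + b
}

#' Full model forward pass
#'
#' Runs the encoder, the transformer branch (unless the model was built with
#' `use_transformer = FALSE`, the fully convolutional ablation variant), the
#' fusion stage and the decoder, returning the per-pixel class probability
#' map at full input resolution.
#'
#' @param model a [build_model()] model.
#' @param x `(R, C, 3)` image in `[0,1]` (or a batched `(N, R, C, 3)` array).
#' @param tau softmax temperature applied to the logits.
#' @return list: `probs` (`R x C x c_se`, rows on the simplex), `logits`, and
#'   `mask` (argmax labels in `0..c_se-1`).
#' @export
model_forward <- function(model, x, tau = 1) {
  xb <- as_batch(x)
  f <- net_fwd(model$params, model$config, xb, training = FALSE)
  logits <- if (isTRUE(attr(xb, "was_single"))) drop_batch(f$logits) else f$logits
  probs <- temperature_softmax(logits, tau)
  mask <- prob_to_mask(probs)
  list(probs = probs, logits = logits, mask = mask)
}

#' Argmax label mask from a probability map
#' @param probs array with trailing class axis.
#' @return integer array of labels `0..c_se-1` (class axis dropped).
#' @export
prob_to_mask <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, prod(d[-length(d)]), d[length(d)])
  array(max.col(m, ties.method = "first") - 1L, d[-length(d)])
}
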