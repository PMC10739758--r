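# Patch-transformer branch: patch partitioning, positional + linear
# embeddings, contextual multi-head self-attention (CMSA) and a cascade of
# t encoders whose final projections p_t are fused with the convolutional
# features.

#' Patch side length for a given patch count
#'
#' `P = sqrt(R*C/n_p)`. Note that a valid tiling additionally requires `P` to
#' be an integer dividing both `R` and `C`; [patchify()] enforces this.
#' @param rows,cols image dims; @param n_p patch count.
#' @export
patch_size_for <- function(rows, cols, n_p) sqrt(rows * cols / n_p)

#' Partition an image into non-overlapping square patches
#'
#' Splits an `R x C x C_h` image into `n_p` square patches of side
#' `P = sqrt(R*C/n_p)`, in row-major grid order. Each patch is flattened into
#' one row of the returned matrix (within-patch order: rows, then columns,
#' then channels).
#'
#' @param x numeric array of dim `(R, C, C_h)`, values typically in `[0,1]`.
#' @param n_p number of patches; `R*C/n_p` must be a perfect square whose root
#'   divides both `R` and `C`.
#' @return matrix of dim `(n_p, P*P*C_h)` with attributes `patch_size`,
#'   `grid` (rows, cols of the patch grid) and `channels`.
#' @examples
#' x <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' p <- patchify(x, 64)       # P = 8
#' stopifnot(all(unpatchify(p) == x))
#' @export
patchify <- function(x, n_p) {
  d <- dim(x)
  if (length(d) != 3L) stop("patchify expects an (R, C, C_h) array")
  r <- d[1L]; cc <- d[2L]; ch <- d[3L]
  p2 <- r * cc / n_p
  p <- sqrt(p2)
  if (p != floor(p) || r %% p != 0L || cc %% p != 0L) {
    divs <- integer(0)
    for (q in seq_len(min(r, cc))) if (r %% q == 0L && cc %% q == 0L) divs <- c(divs, q)
    stop("n_p = ", n_p, " does not tile a ", r, "x", cc, " image; valid n_p: ",
         paste(rev(r * cc / (divs^2)), collapse = ", "))
  }
  p <- as.integer(p)
  gr <- r %/% p; gc <- cc %/% p
  out <- matrix(0, n_p, p * p * ch)
  k <- 1L
  for (gi in seq_len(gr)) for (gj in seq_len(gc)) {
    out[k, ] <- as.vector(x[((gi - 1L) * p + 1L):(gi * p),
                            ((gj - 1L) * p + 1L):(gj * p), , drop = FALSE])
    k <- k + 1L
  }
  attr(out, "patch_size") <- p
  attr(out, "grid") <- c(gr, gc)
  attr(out, "channels") <- ch
  out
}

#' Reassemble an image from its patch sequence
#'
#' Exact inverse of [patchify()].
#' @param patches matrix produced by [patchify()].
#' @return the original `(R, C, C_h)` array.
#' @export
unpatchify <- function(patches) {
  p <- attr(patches, "patch_size")
  g <- attr(patches, "grid")
  ch <- attr(patches, "channels")
  if (is.null(p)) stop("missing patch attributes; use the output of patchify()")
  x <- array(0, c(g[1L] * p, g[2L] * p, ch))
  k <- 1L
  for (gi in seq_len(g[1L])) for (gj in seq_len(g[2L])) {
    x[((gi - 1L) * p + 1L):(gi * p), ((gj - 1L) * p + 1L):(gj * p), ] <-
      array(patches[k, ], c(p, p, ch))
    k <- k + 1L
  }
  x
}

#' Linear + positional patch embedding
#'
#' Token i is the linear projection of flattened patch i plus its (flattened)
#' positional embedding: `q_i = proj(x^p_i) + pos_i`, giving the combined
#' projection sequence `q^o`.
#'
#' @param patches `(n_p, P^2*C_h)` patch matrix from [patchify()].
#' @param positional `(n_p, l)` positional embedding matrix.
#' @param projection list with `W` (`P^2*C_h x l`) and optional bias `b`.
#' @return `(n_p, l)` token matrix.
#' @export
embed_sequence <- function(patches, positional, projection) {
  if (ncol(patches) != nrow(projection$W))
    stop("projection maps ", nrow(projection$W), " dims but patches have ",
         ncol(patches))
  if (nrow(positional) != nrow(patches) || ncol(positional) != ncol(projection$W))
    stop("positional embeddings must be n_p x l")
  out <- patches %*% projection$W
  if (!is.null(projection$b)) out <- out + rep(projection$b, each = nrow(out))
  out + positional
}

#' Contextual multi-head self-attention
#'
#' For already-normalised tokens, head `j` computes
#' `A_j = softmax(Q_j K_j^T / sqrt(l)) V_j` with `Q = tokens w_q`,
#' `K = tokens w_k`, `V = tokens w_v`; head outputs are concatenated and
#' merged back to width `l`. Note the scaling denominator is `sqrt(l)` (the
#' full token width), not `sqrt(d_head)`.
#'
#' @param tokens `(n_p, l)` layer-normalised token matrix.
#' @param params list: `w_q`, `w_k`, `w_v` are lists of `h` matrices
#'   (`l x d_head` each, `h*d_head = l`); `w_o` is the `(h*d_head) x l` merge.
#' @param return_attention also return the per-head attention matrices.
#' @return `(n_p, l)` matrix; with `return_attention`, a list
#'   `(out, attention)`.
#' @export
cmsa <- function(tokens, params, return_attention = FALSE) {
  f <- cmsa_fwd(tokens, params)
  if (!all(is.finite(f$out))) stop("non-finite attention scores")
  if (return_attention) list(out = f$out, attention = f$cache$attn) else f$out
}

cmsa_fwd <- function(tokens, params) {
  h <- length(params$w_q)
  l <- ncol(tokens)
  scale <- 1 / sqrt(l)
  heads <- vector("list", h)
  attn <- vector("list", h)
  qkv <- vector("list", h)
  for (j in seq_len(h)) {
    q <- tokens %*% params$w_q[[j]]
    k <- tokens %*% params$w_k[[j]]
    v <- tokens %*% params$w_v[[j]]
    a <- softmax_rows(tcrossprod(q, k) * scale)
    heads[[j]] <- a %*% v
    attn[[j]] <- a
    qkv[[j]] <- list(q = q, k = k, v = v)
  }
  concat <- do.call(cbind, heads)
  out <- concat %*% params$w_o
  list(out = out,
       cache = list(tokens = tokens, params = params, attn = attn, qkv = qkv,
                    concat = concat, scale = scale))
}

cmsa_bwd <- function(dout, cache) {
  p <- cache$params
  h <- length(p$w_q)
  dh <- ncol(p$w_q[[1L]])
  dconcat <- tcrossprod(dout, p$w_o)
  dwo <- crossprod(cache$concat, dout)
  dtok <- matrix(0, nrow(cache$tokens), ncol(cache$tokens))
  dwq <- dwk <- dwv <- vector("list", h)
  for (j in seq_len(h)) {
    dhead <- dconcat[, ((j - 1L) * dh + 1L):(j * dh), drop = FALSE]
    a <- cache$attn[[j]]
    q <- cache$qkv[[j]]$q; k <- cache$qkv[[j]]$k; v <- cache$qkv[[j]]$v
    da <- tcrossprod(dhead, v)
    dv <- crossprod(a, dhead)
    ds <- softmax_rows_bwd(da, a) * cache$scale
    dq <- ds %*% k
    dk <- crossprod(ds, q)
    dwq[[j]] <- crossprod(cache$tokens, dq)
    dwk[[j]] <- crossprod(cache$tokens, dk)
    dwv[[j]] <- crossprod(cache$tokens, dv)
    dtok <- dtok + tcrossprod(dq, p$w_q[[j]]) + tcrossprod(dk, p$w_k[[j]]) +
      tcrossprod(dv, p$w_v[[j]])
  }
  list(dx = dtok, dwq = dwq, dwk = dwk, dwv = dwv, dwo = dwo)
}

# One transformer encoder, pre-layer-norm:
#   u = CMSA(LN1(q0)) + q0 ; v = LN2(u) ; out = FF(v) + v
# so the output minus the feedforward term equals the normalised
# attention-residual sum.
encoder_fwd <- function(q0, ep) {
  ln1 <- layernorm_fwd(q0, ep$ln1.gamma, ep$ln1.beta)
  at <- cmsa_fwd(ln1$out, list(w_q = ep$w_q, w_k = ep$w_k, w_v = ep$w_v,
                               w_o = ep$w_o))
  u <- at$out + q0
  ln2 <- layernorm_fwd(u, ep$ln2.gamma, ep$ln2.beta)
  f1 <- linear_fwd(ln2$out, ep$ff.W1, ep$ff.b1)
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(r1$out, ep$ff.W2, ep$ff.b2)
  out <- f2$out + ln2$out
  list(out = out, cache = list(ln1 = ln1$cache, at = at$cache, ln2 = ln2$cache,
                               f1 = f1$cache, r1 = r1$cache, f2 = f2$cache))
}

encoder_bwd <- function(dout, cache) {
  g2 <- linear_bwd(dout, cache$f2)
  gr <- relu_bwd(g2$dx, cache$r1)
  g1 <- linear_bwd(gr, cache$f1)
  dv <- g1$dx + dout
  gl2 <- layernorm_bwd(dv, cache$ln2)
  du <- gl2$dx
  ga <- cmsa_bwd(du, cache$at)
  gl1 <- layernorm_bwd(ga$dx, cache$ln1)
  dq0 <- gl1$dx + du
  list(dx = dq0,
       grads = list(ln1.gamma = gl1$dgamma, ln1.beta = gl1$dbeta,
                    w_q = ga$dwq, w_k = ga$dwk, w_v = ga$dwv, w_o = ga$dwo,
                    ln2.gamma = gl2$dgamma, ln2.beta = gl2$dbeta,
                    ff.W1 = g1$dw, ff.b1 = g1$db, ff.W2 = g2$dw, ff.b2 = g2$db))
}

#' Single transformer encoder layer
#'
#' Pre-layer-norm encoder: normalise, CMSA, add the token residual, normalise
#' again, apply the learnable feedforward (linear-ReLU-linear) and add the
#' normalised sum as residual.
#'
#' @param tokens `(n_p, l)` token matrix `q^o`.
#' @param params one element of [init_transformer_params()]`$layers`.
#' @return `(n_p, l)` projection matrix.
#' @export
transformer_encoder <- function(tokens, params) encoder_fwd(tokens, params)$out

#' Cascade of transformer encoders
#'
#' Applies `t` encoder layers sequentially to the combined projections `q^o`
#' and returns the final projections `p_t` (the last encoder's output).
#' Layers have independent weights.
#'
#' @param q_o `(n_p, l)` token matrix from [embed_sequence()].
#' @param params full transformer parameter set from
#'   [init_transformer_params()].
#' @return `(n_p, l)` projection matrix `p_t`.
#' @export
transformer_stack <- function(q_o, params) {
  if (length(params$layers) < 1L) stop("transformer depth must be >= 1")
  x <- q_o
  for (ep in params$layers) x <- encoder_fwd(x, ep)$out
  x
}

#' Initialise transformer-branch parameters
#'
#' @param n_p number of patches; @param patch_dim flattened patch width
#'   (`P^2*C_h`); @param l embedding width; @param h head count (`l` must be
#'   divisible by `h`); @param ff_width hidden width of the feedforward;
#'   @param depth number of cascaded encoders (default 3).
#' @return list with `proj` (patch projection), `pos` (learned positional
#'   embeddings) and `layers` (per-encoder parameter lists).
#' @export
init_transformer_params <- function(n_p, patch_dim, l, h, ff_width, depth = 3L) {
  if (depth < 1L) stop("transformer depth must be >= 1 (use use_transformer = FALSE to ablate the branch)")
  if (l %% h != 0L) stop("embedding width l must be divisible by head count h")
  dh <- l %/% h
  xav <- function(ni, no) matrix(stats::rnorm(ni * no, sd = sqrt(2 / (ni + no))), ni, no)
  layers <- vector("list", depth)
  for (k in seq_len(depth)) {
    layers[[k]] <- list(
      ln1.gamma = rep(1, l), ln1.beta = rep(0, l),
      w_q = lapply(seq_len(h), function(j) xav(l, dh)),
      w_k = lapply(seq_len(h), function(j) xav(l, dh)),
      w_v = lapply(seq_len(h), function(j) xav(l, dh)),
      w_o = xav(l, l),
      ln2.gamma = rep(1, l), ln2.beta = rep(0, l),
      ff.W1 = xav(l, ff_width), ff.b1 = rep(0, ff_width),
      ff.W2 = xav(ff_width, l), ff.b2 = rep(0, l))
  }
  list(proj = list(W = xav(patch_dim, l), b = rep(0, l)),
       pos = matrix(stats::rnorm(n_p * l, sd = 0.02), n_p, l),
       layers = layers)
}

# Full branch forward/backward on one image (used inside the model).
transformer_branch_fwd <- function(x, tp, n_p) {
  patches <- patchify(x, n_p)
  q0 <- embed_sequence(patches, tp$pos, tp$proj)
  caches <- vector("list", length(tp$layers))
  z <- q0
  for (k in seq_along(tp$layers)) {
    e <- encoder_fwd(z, tp$layers[[k]])
    caches[[k]] <- e$cache
    z <- e$out
  }
  list(out = z, cache = list(patches = patches, caches = caches,
                             grid = attr(patches, "grid")))
}

transformer_branch_bwd <- function(dout, cache, tp) {
  layer_grads <- vector("list", length(tp$layers))
  dz <- dout
  for (k in rev(seq_along(tp$layers))) {
    g <- encoder_bwd(dz, cache$caches[[k]])
    layer_grads[[k]] <- g$grads
    dz <- g$dx
  }
  # q0 = patches %*% W + b + pos; gradient tree mirrors the parameter tree
  dW <- crossprod(cache$patches, dz)
  db <- colSums(dz)
  list(proj = list(W = dW, b = db), pos = dz, layers = layer_grads)
}
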