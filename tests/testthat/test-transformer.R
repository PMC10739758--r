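# Patch partitioning, embeddings, contextual multi-head self-attention and
# the cascaded encoder stack.

test_that("patchify tiles row-major and unpatchify inverts it exactly", {
  x <- rand_array(c(64, 64, 3), 101)
  p <- patchify(x, 64)
  expect_identical(dim(p), c(64L, 8L * 8L * 3L))
  expect_identical(attr(p, "patch_size"), 8L)
  expect_identical(unpatchify(p), x)
  # first patch is the top-left 8x8 tile
  expect_identical(p[1, ], as.vector(x[1:8, 1:8, ]))
  # non-square canvas round-trips too
  y <- rand_array(c(32, 64, 3), 102)
  expect_identical(unpatchify(patchify(y, 32)), y)
})

test_that("patch-size arithmetic follows P = sqrt(RC/n_p), tiling enforced", {
  expect_identical(patch_size_for(64, 64, 64), 8)
  # the published input size gives P = 12 by the formula, but 12 does not
  # divide 640, so no valid tiling exists and patchify must say which n_p do
  expect_identical(patch_size_for(540, 640, 2400), 12)
  expect_error(patchify(rand_array(c(540, 640, 3), 1), 2400), "valid n_p")
  expect_error(patchify(rand_array(c(64, 64, 3), 1), 37), "valid n_p")
})

test_that("embedding is projection plus positional, matching a loop oracle", {
  x <- rand_array(c(16, 16, 3), 103)
  patches <- patchify(x, 4)   # P = 8
  n_p <- 4L; l <- 6L
  # zero weights and zero positions give zero tokens
  z <- embed_sequence(patches, matrix(0, n_p, l),
                      list(W = matrix(0, ncol(patches), l)))
  expect_true(all(z == 0))
  # single-patch sequence is the plain sum of Eq-style terms
  p1 <- patchify(x, 1)
  set.seed(104)
  W <- matrix(rnorm(ncol(p1) * l), ncol(p1), l)
  pos1 <- matrix(rnorm(l), 1, l)
  expect_equal(embed_sequence(p1, pos1, list(W = W)),
               p1 %*% W + pos1, tolerance = 1e-12)
  # loop oracle, token by token
  set.seed(105)
  Wp <- matrix(rnorm(ncol(patches) * l), ncol(patches), l)
  b <- rnorm(l)
  pos <- matrix(rnorm(n_p * l), n_p, l)
  got <- embed_sequence(patches, pos, list(W = Wp, b = b))
  for (i in seq_len(n_p)) {
    tok <- numeric(l)
    for (d in seq_len(l))
      tok[d] <- sum(patches[i, ] * Wp[, d]) + b[d] + pos[i, d]
    expect_equal(got[i, ], tok, tolerance = 1e-6)
  }
  expect_error(embed_sequence(patches, pos, list(W = Wp[-1, ])), "projection maps")
})

test_that("cmsa reduces to V for a single token and is uniform over identical tokens", {
  params <- rand_attention_params(l = 8, h = 1, seed = 106)
  tok <- matrix(rnorm(8), 1, 8)
  got <- cmsa(tok, params, return_attention = TRUE)
  expect_equal(got$attention[[1]], matrix(1, 1, 1))
  expect_equal(got$out, (tok %*% params$w_v[[1]]) %*% params$w_o,
               tolerance = 1e-10)
  # n identical tokens -> every attention row is uniform 1/n
  n <- 5
  toks <- matrix(rep(rnorm(8), each = n), n, 8)
  a <- cmsa(toks, rand_attention_params(8, 2, 107), return_attention = TRUE)
  for (h in 1:2) expect_equal(a$attention[[h]], matrix(1 / n, n, n),
                              tolerance = 1e-12)
})

test_that("cmsa equals the triple-nested-loop oracle on 20 seeded cases", {
  for (case in 1:20) {
    set.seed(200 + case)
    n <- sample(2:6, 1)
    l <- sample(c(4, 8), 1)
    h <- sample(c(1, 2), 1)
    toks <- matrix(rnorm(n * l), n, l)
    params <- rand_attention_params(l, h, 300 + case)
    got <- cmsa(toks, params, return_attention = TRUE)
    expect_lt(max(abs(got$out - cmsa_loop_oracle(toks, params))), 1e-6)
    for (j in seq_len(h))
      expect_equal(rowSums(got$attention[[j]]), rep(1, n), tolerance = 1e-6)
  }
})

test_that("cmsa without positional information is permutation-equivariant", {
  set.seed(108)
  toks <- matrix(rnorm(6 * 8), 6, 8)
  params <- rand_attention_params(8, 2, 109)
  base <- cmsa(toks, params)
  for (rep in 1:5) {
    perm <- sample(6)
    expect_equal(cmsa(toks[perm, ], params), base[perm, ], tolerance = 1e-10)
  }
})

test_that("encoder layer follows normalise-attend-residual-normalise-feedforward-residual", {
  tp <- init_transformer_params(n_p = 4, patch_dim = 12, l = 8, h = 2,
                                ff_width = 16, depth = 1)
  ep <- tp$layers[[1]]
  set.seed(110)
  q0 <- matrix(rnorm(4 * 8), 4, 8)
  # zero feedforward: output equals the normalised attention-residual term
  ep0 <- ep
  ep0$ff.W1[] <- 0; ep0$ff.b1[] <- 0; ep0$ff.W2[] <- 0; ep0$ff.b2[] <- 0
  out0 <- transformer_encoder(q0, ep0)
  ln1 <- tomaformer:::layernorm_fwd(q0, ep$ln1.gamma, ep$ln1.beta)
  att <- cmsa(ln1$out, list(w_q = ep$w_q, w_k = ep$w_k, w_v = ep$w_v,
                            w_o = ep$w_o))
  u <- att + q0
  v <- tomaformer:::layernorm_fwd(u, ep$ln2.gamma, ep$ln2.beta)$out
  expect_equal(out0, v, tolerance = 1e-10)
  # residual identity: out - FF(v) = v, with FF applied explicitly
  out <- transformer_encoder(q0, ep)
  ff <- pmax(v %*% ep$ff.W1 + rep(ep$ff.b1, each = 4), 0) %*% ep$ff.W2 +
    rep(ep$ff.b2, each = 4)
  expect_equal(out - ff, v, tolerance = 1e-10)
})

test_that("the stack composes encoders sequentially and rejects depth 0", {
  tp <- init_transformer_params(n_p = 4, patch_dim = 12, l = 8, h = 2,
                                ff_width = 16, depth = 3)
  set.seed(111)
  q0 <- matrix(rnorm(4 * 8), 4, 8)
  step <- q0
  for (k in 1:3) step <- transformer_encoder(step, tp$layers[[k]])
  expect_equal(transformer_stack(q0, tp), step, tolerance = 1e-12)
  tp1 <- tp; tp1$layers <- tp$layers[1]
  expect_equal(transformer_stack(q0, tp1),
               transformer_encoder(q0, tp$layers[[1]]), tolerance = 1e-12)
  expect_error(init_transformer_params(4, 12, 8, 2, 16, depth = 0),
               "depth must be >= 1")
  expect_error(model_config(transformer = list(depth = 0L)), "depth must be >= 1")
})
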