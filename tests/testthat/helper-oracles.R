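# Brute-force reference implementations ("oracles") kept deliberately
# independent of the package's vectorised code paths, plus small fixture
# builders. Everything is generated in code; no stored fixtures.

rand_array <- function(dims, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

rand_mask <- function(h, w, seed, n_classes = 4L) {
  set.seed(seed)
  matrix(sample(0:(n_classes - 1L), h * w, replace = TRUE), h, w)
}

# --- attention: triple-nested-loop CMSA oracle -------------------------------

cmsa_loop_oracle <- function(tokens, params) {
  n <- nrow(tokens); l <- ncol(tokens)
  h <- length(params$w_q)
  dh <- ncol(params$w_q[[1]])
  concat <- matrix(0, n, h * dh)
  for (j in seq_len(h)) {
    q <- matrix(0, n, dh); k <- matrix(0, n, dh); v <- matrix(0, n, dh)
    for (i in seq_len(n)) for (d in seq_len(dh)) {
      for (e in seq_len(l)) {
        q[i, d] <- q[i, d] + tokens[i, e] * params$w_q[[j]][e, d]
        k[i, d] <- k[i, d] + tokens[i, e] * params$w_k[[j]][e, d]
        v[i, d] <- v[i, d] + tokens[i, e] * params$w_v[[j]][e, d]
      }
    }
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (i2 in seq_len(n)) {
        for (d in seq_len(dh)) s[i2] <- s[i2] + q[i, d] * k[i2, d]
        s[i2] <- s[i2] / sqrt(l)
      }
      a <- exp(s - max(s)); a <- a / sum(a)
      for (d in seq_len(dh)) {
        acc <- 0
        for (i2 in seq_len(n)) acc <- acc + a[i2] * v[i2, d]
        concat[i, (j - 1) * dh + d] <- acc
      }
    }
  }
  concat %*% params$w_o
}

rand_attention_params <- function(l, h, seed) {
  set.seed(seed)
  dh <- l %/% h
  rm <- function(a, b) matrix(stats::rnorm(a * b, sd = 0.3), a, b)
  list(w_q = lapply(seq_len(h), function(j) rm(l, dh)),
       w_k = lapply(seq_len(h), function(j) rm(l, dh)),
       w_v = lapply(seq_len(h), function(j) rm(l, dh)),
       w_o = rm(l, l))
}

# --- pooling: per-window loop oracle -----------------------------------------

maxpool_window_oracle <- function(x) {
  # x: (H, W, C) single sample
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  pos <- array(0L, c(d[1] / 2, d[2] / 2, d[3], 2))
  for (ch in seq_len(d[3])) for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2)) {
    win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]
    out[i, j, ch] <- max(win)
    w <- which(win == max(win), arr.ind = TRUE)[1, ]
    pos[i, j, ch, ] <- c(2 * i - 2 + w[1], 2 * j - 2 + w[2])
  }
  list(out = out, pos = pos)
}

# --- losses: per-pixel loop oracles ------------------------------------------

softmax_vec <- function(z) { e <- exp(z - max(z)); e / sum(e) }

dice_loop_oracle <- function(truth, probs) {
  # truth/probs: (N, H, W, C)
  d <- dim(truth)
  per <- numeric(d[1])
  for (s in seq_len(d[1])) {
    num <- 0; den <- 0
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) for (c in seq_len(d[4])) {
      num <- num + truth[s, i, j, c] * probs[s, i, j, c]
      den <- den + truth[s, i, j, c]^2 + probs[s, i, j, c]^2
    }
    per[s] <- 1 - 2 * num / den
  }
  mean(per)
}

ce_loop_oracle <- function(truth, logits, tau) {
  d <- dim(truth)
  tot <- 0
  for (s in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    p <- softmax_vec(logits[s, i, j, ] / tau)
    for (c in seq_len(d[4]))
      tot <- tot - truth[s, i, j, c] * log(max(p[c], 1e-12))
  }
  tot / (d[1] * d[2] * d[3])
}

# --- components: flood-fill (BFS) oracle -------------------------------------

flood_fill_components <- function(binary, connectivity = 8L) {
  b <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  h <- nrow(b); w <- ncol(b)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  k <- 0L
  for (sr in seq_len(h)) for (sc in seq_len(w)) {
    if (!b[sr, sc] || lab[sr, sc] > 0L) next
    k <- k + 1L
    queue <- list(c(sr, sc))
    lab[sr, sc] <- k
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[q, 1]; c2 <- p[2] + nb[q, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            b[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- k
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# --- AP: exhaustive precision-recall enumeration oracle ----------------------

ap_enumeration_oracle <- function(pred, truth, iou_threshold) {
  # pred/truth: data frames with box columns + score; single class assumed
  if (nrow(pred) == 0L) return(if (nrow(truth) == 0L) NA_real_ else 0)
  if (nrow(truth) == 0L) return(0)
  ord <- order(-pred$score)
  pred <- pred[ord, , drop = FALSE]
  # recompute the greedy matching from scratch for every ranked prefix
  prec <- rec <- numeric(nrow(pred))
  for (k in seq_len(nrow(pred))) {
    matched <- logical(nrow(truth))
    tp <- 0
    for (i in seq_len(k)) {
      best <- 0; bj <- 0L
      for (j in seq_len(nrow(truth))) {
        if (matched[j]) next
        v <- box_iou(pred[i, ], truth[j, ])
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0L && best >= iou_threshold) { matched[bj] <- TRUE; tp <- tp + 1 }
    }
    prec[k] <- tp / k
    rec[k] <- tp / nrow(truth)
  }
  ap <- 0; prev <- 0
  for (k in seq_len(nrow(pred))) {
    if (rec[k] > prev) {
      ap <- ap + (rec[k] - prev) * max(prec[k:length(prec)])
      prev <- rec[k]
    }
  }
  ap
}

# --- AUC: exhaustive pairwise comparison oracle ------------------------------

auc_pairwise_oracle <- function(scores, labels) {
  pos <- which(labels)
  neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

box_df <- function(..., score = 1, class_label = 1L) {
  b <- rbind(...)
  data.frame(class_label = class_label, row_min = b[, 1], col_min = b[, 2],
             row_max = b[, 3], col_max = b[, 4],
             score = rep_len(score, nrow(b)), pixels = NA_integer_)
}

tiny_scene <- function(seed = 11) {
  generate_scene(scene_config(seed = seed))
}
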