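# The composite training objective L_t = beta1 * L_s1 + beta2 * L_s2:
# a per-sample soft-Dice term and a temperature-softened cross-entropy, both
# evaluated on the temperature-softened probability map p(L^{se,tau}).

#' Loss configuration
#'
#' @param beta1 weight of the soft-Dice term (default 0.9, the ablation
#'   optimum).
#' @param beta2 weight of the cross-entropy term; `beta1 + beta2` must equal 1
#'   (the ablation grid's constraint `beta2 = 1 - beta1`).
#' @param tau softmax temperature (> 0); default 1.5, the ablation optimum.
#' @param c_se class count including background (default 4).
#' @export
loss_config <- function(beta1 = 0.9, beta2 = 0.1, tau = 1.5, c_se = 4L) {
  if (abs(beta1 + beta2 - 1) > 1e-9)
    stop("beta1 + beta2 must equal 1 (got ", beta1 + beta2, ")")
  if (beta1 < 0 || beta2 < 0) stop("beta weights must be in [0, 1]")
  if (tau <= 0) stop("temperature tau must be > 0")
  if (c_se < 2L) stop("need at least 2 classes")
  structure(list(beta1 = beta1, beta2 = beta2, tau = tau, c_se = as.integer(c_se)),
            class = "tf_loss_config")
}

#' One-hot encoding of a label mask
#'
#' @param mask `(H, W)` or `(N, H, W)` integer array with labels in
#'   `0..n_classes-1`.
#' @param n_classes number of classes.
#' @return array with a trailing class axis; exactly one 1 per pixel.
#' @export
one_hot <- function(mask, n_classes = 4L) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  v <- as.integer(mask)
  if (any(v < 0L | v >= n_classes)) stop("labels outside 0..", n_classes - 1L)
  out <- numeric(prod(d) * n_classes)
  out[seq_along(v) + as.numeric(v) * prod(d)] <- 1
  array(out, c(d, n_classes))
}

# Reshape (H,W,c), (N,H,W,c) logits/probability arrays to a pixel x class
# matrix; returns the matrix plus bookkeeping to restore the shape.
.class_mat <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("expected an array with a class axis")
  cse <- d[length(d)]
  list(m = matrix(x, prod(d[-length(d)]), cse), dim = d,
       n_sample = if (length(d) == 4L) d[1L] else 1L)
}

#' Temperature-softened softmax
#'
#' `p = softmax(logits / tau)` along the class axis; `tau = 1` recovers the
#' standard softmax and the probability ordering is preserved for any `tau`.
#'
#' @param logits array with a trailing class axis (`(H,W,c)` or `(N,H,W,c)`;
#'   a plain matrix is treated as pixels x classes).
#' @param tau temperature, > 0.
#' @return probability array of the same shape; rows sum to 1.
#' @export
temperature_softmax <- function(logits, tau = 1.5) {
  if (tau <= 0) stop("temperature tau must be > 0")
  cm <- .class_mat(logits)
  p <- softmax_rows(cm$m / tau)
  array(p, cm$dim)
}

#' Soft-Dice loss
#'
#' Per sample i: `1 - 2 * sum(T*p) / sum(T^2 + p^2)`, the sums running
#' jointly over all pixels and classes of the sample, averaged over the
#' batch. 0 on perfect one-hot agreement, 1 on fully disjoint one-hot
#' predictions; always in `[0, 1]`.
#'
#' @param truth one-hot target, same shape as `probs`.
#' @param probs probability array (each pixel's class vector on the simplex).
#' @return scalar loss.
#' @export
soft_dice_loss <- function(truth, probs) {
  if (!identical(dim(truth), dim(probs))) stop("truth/probs shape mismatch")
  d <- dim(truth)
  n <- if (length(d) == 4L) d[1L] else 1L
  tm <- matrix(truth, n, prod(d) / n)
  pm <- matrix(probs, n, prod(d) / n)
  num <- 2 * rowSums(tm * pm)
  den <- rowSums(tm * tm + pm * pm)
  per <- ifelse(den < 1e-12, 0, 1 - num / den)
  mean(per)
}

#' Temperature-softened cross-entropy loss
#'
#' `-mean_i mean_pix sum_j T_ij log p(L^{se,tau})_ij` with
#' `p = softmax(logits/tau)`. Predicted probabilities are clamped at 1e-12,
#' so the loss is finite for any logits; `tau = 1` gives standard
#' cross-entropy. For a single pixel with uniform logits over `c` classes the
#' value is `log(c)`.
#'
#' @param truth one-hot target, same shape as `logits`.
#' @param logits raw network outputs with trailing class axis.
#' @param tau temperature, > 0.
#' @return scalar loss, >= 0.
#' @export
temperature_cross_entropy <- function(truth, logits, tau = 1.5) {
  if (!identical(dim(truth), dim(logits))) stop("truth/logits shape mismatch")
  p <- temperature_softmax(logits, tau)
  cm <- .class_mat(p)
  tmat <- .class_mat(truth)$m
  ll <- -rowSums(tmat * log(pmax(cm$m, 1e-12)))
  mean(ll) # average over pixels and batch jointly
}

#' Composite segmentation loss L_t
#'
#' `L_t = beta1 * L_s1 + beta2 * L_s2`: the soft-Dice term and the
#' temperature-softened cross-entropy, both computed from the same
#' temperature-softened probability map. Defaults `beta1 = 0.9`,
#' `beta2 = 0.1`, `tau = 1.5` are the published ablation optima.
#'
#' @param truth one-hot target array.
#' @param logits raw network outputs, same shape.
#' @param config a [loss_config()].
#' @return scalar `L_t` with attributes `dice` (`L_s1`) and `ce` (`L_s2`).
#' @export
total_loss <- function(truth, logits, config = loss_config()) {
  # zero-weighted terms are genuinely not evaluated (degenerate-weight
  # configs train without invoking the unused component)
  ls1 <- if (config$beta1 > 0) {
    p <- temperature_softmax(logits, config$tau)
    soft_dice_loss(truth, p)
  } else 0
  ls2 <- if (config$beta2 > 0)
    temperature_cross_entropy(truth, logits, config$tau) else 0
  structure(config$beta1 * ls1 + config$beta2 * ls2, dice = ls1, ce = ls2,
            dice_evaluated = config$beta1 > 0, ce_evaluated = config$beta2 > 0)
}

#' Analytic gradient of L_t with respect to the logits
#'
#' Used by the training loop; verified against central finite differences in
#' the test suite.
#'
#' @inheritParams total_loss
#' @return array of `d L_t / d logits`, same shape as `logits`.
#' @export
total_loss_grad <- function(truth, logits, config = loss_config()) {
  d <- dim(logits)
  n <- if (length(d) == 4L) d[1L] else 1L
  npix <- prod(d[-length(d)]) / n
  cse <- d[length(d)]
  p <- temperature_softmax(logits, config$tau)
  pm <- .class_mat(p)$m
  tm <- .class_mat(truth)$m

  g <- 0
  if (config$beta1 > 0) {
    # dice: per sample, L_i = 1 - num/den with num = 2*sum(T p), den = sum(T^2+p^2)
    ts <- matrix(truth, n, npix * cse)
    ps <- matrix(p, n, npix * cse)
    num <- 2 * rowSums(ts * ps)
    den <- pmax(rowSums(ts * ts + ps * ps), 1e-12)
    # dL_i/dp = (-2 T den + 2 num p) / den^2, then / n for the batch mean
    dice_dp_s <- (-2 * ts * den + 2 * num * ps) / (den * den) / n
    g <- g + config$beta1 * .class_mat(array(dice_dp_s, d))$m
  }
  if (config$beta2 > 0) {
    # cross-entropy enters through the shared softmax jacobian below via
    # dCE/dp = -T/p / (n*npix)
    g <- g - config$beta2 * (tm / pmax(pm, 1e-12)) / (n * npix)
  }
  # softmax jacobian per pixel, with the 1/tau chain factor
  dlogit <- (pm * (g - rowSums(g * pm))) / config$tau
  array(dlogit, d)
}
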