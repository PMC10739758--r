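# Composite objective: temperature softmax, soft-Dice, softened
# cross-entropy, their combination and gradients.

test_that("temperature softmax preserves ordering, tau=1 is standard softmax", {
  z <- array(c(2, 0, 1, -1), c(1, 1, 4))
  p1 <- temperature_softmax(z, 1)
  expect_equal(as.vector(p1), softmax_vec(c(2, 0, 1, -1)), tolerance = 1e-12)
  # closed form at tau = 2: softmax(logits/2)
  z2 <- array(c(2, 0), c(1, 1, 2))
  expect_equal(as.vector(temperature_softmax(z2, 2)),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  # uniform logits give 1/c for any tau
  for (tau in c(0.5, 1, 1.5, 10)) {
    pu <- temperature_softmax(array(3, c(2, 2, 4)), tau)
    expect_true(all(abs(pu - 0.25) < 1e-12))
  }
  # large tau flattens distinct logits toward uniform
  pl <- temperature_softmax(array(c(5, -3, 1, 0), c(1, 1, 4)), 1e6)
  expect_true(all(abs(pl - 0.25) < 1e-4))
  expect_error(temperature_softmax(z, 0), "> 0")
  # ordering preserved
  for (tau in c(0.7, 1.5, 3)) {
    p <- as.vector(temperature_softmax(z, tau))
    expect_identical(order(p), order(c(2, 0, 1, -1)))
  }
})

test_that("true-class probability decreases monotonically in tau when it holds the max logit", {
  z <- array(c(3, 0.5, -1, 0), c(1, 1, 4))
  taus <- c(0.5, 1, 1.5, 2, 4, 8)
  ptrue <- vapply(taus, function(t) temperature_softmax(z, t)[1, 1, 1], numeric(1))
  expect_true(all(diff(ptrue) < 0))
})

test_that("soft-Dice hits its closed-form anchors", {
  t1 <- one_hot(matrix(c(0, 1, 2, 3), 2, 2), 4)
  expect_equal(soft_dice_loss(t1, t1), 0)
  # fully disjoint one-hot prediction
  disj <- one_hot(matrix(c(1, 2, 3, 0), 2, 2), 4)
  expect_equal(soft_dice_loss(t1, disj), 1)
  # hand-expanded 2-pixel, 2-class toy
  truth <- array(c(1, 0, 0, 1), c(1, 1, 2, 2))  # pixels (1,0) and (0,1)
  probs <- array(c(0.8, 0.4, 0.2, 0.6), c(1, 1, 2, 2))
  hand <- 1 - 2 * (0.8 + 0.6) / ((1 + 1) + (0.64 + 0.04 + 0.16 + 0.36))
  expect_equal(soft_dice_loss(truth, probs), hand, tolerance = 1e-12)
})

test_that("cross-entropy hits its closed-form anchors", {
  # probability 1 on every true class
  t1 <- one_hot(matrix(c(0, 1), 1, 2), 4)
  big <- array(-50, c(1, 2, 4))
  big[1, 1, 1] <- 50; big[1, 2, 2] <- 50
  expect_lt(temperature_cross_entropy(t1, big, 1), 1e-10)
  # uniform logits over 4 classes, single pixel: log 4
  tu <- one_hot(matrix(2L, 1, 1), 4)
  expect_equal(temperature_cross_entropy(tu, array(0, c(1, 1, 4)), 1.5),
               log(4), tolerance = 1e-12)
  # zero predicted probability at the target is clamped, never NaN
  bad <- array(0, c(1, 1, 4)); bad[1, 1, 2] <- 1e4
  v <- temperature_cross_entropy(one_hot(matrix(0L, 1, 1), 4), bad, 1)
  expect_true(is.finite(v))
})

test_that("losses match per-pixel loop oracles on 50 random cases", {
  for (case in 1:50) {
    set.seed(500 + case)
    n <- sample(1:2, 1); h <- sample(2:4, 1); w <- sample(2:4, 1)
    tau <- sample(c(1, 1.5, 2), 1)
    logits <- array(rnorm(n * h * w * 4), c(n, h, w, 4))
    truth <- one_hot(array(sample(0:3, n * h * w, TRUE), c(n, h, w)), 4)
    probs <- temperature_softmax(logits, tau)
    expect_equal(soft_dice_loss(truth, probs),
                 dice_loop_oracle(truth, probs), tolerance = 1e-6)
    expect_equal(temperature_cross_entropy(truth, logits, tau),
                 ce_loop_oracle(truth, logits, tau), tolerance = 1e-6)
    # range invariants
    expect_gte(soft_dice_loss(truth, probs), 0)
    expect_lte(soft_dice_loss(truth, probs), 1)
    expect_gte(temperature_cross_entropy(truth, logits, tau), 0)
  }
})

test_that("the composite loss is the exact beta-weighted sum", {
  set.seed(510)
  logits <- array(rnorm(2 * 2 * 2 * 4), c(2, 2, 2, 4))
  truth <- one_hot(array(sample(0:3, 8, TRUE), c(2, 2, 2)), 4)
  lc <- loss_config(beta1 = 0.9, beta2 = 0.1, tau = 1.5)
  lt <- total_loss(truth, logits, lc)
  probs <- temperature_softmax(logits, 1.5)
  expect_equal(as.numeric(lt),
               0.9 * soft_dice_loss(truth, probs) +
                 0.1 * temperature_cross_entropy(truth, logits, 1.5),
               tolerance = 1e-12)
  # degenerate weights select a single term
  l1 <- total_loss(truth, logits, loss_config(beta1 = 1, beta2 = 0))
  expect_equal(as.numeric(l1), soft_dice_loss(truth, probs), tolerance = 1e-12)
  expect_false(attr(l1, "ce_evaluated"))
  l2 <- total_loss(truth, logits, loss_config(beta1 = 0, beta2 = 1))
  expect_equal(as.numeric(l2),
               temperature_cross_entropy(truth, logits, 1.5), tolerance = 1e-12)
  # the 2-pixel toy, cross-checked against the two sub-losses by arithmetic
  truth2 <- array(c(1, 0, 0, 1), c(1, 1, 2, 2))
  # pad to 4 classes for the config contract
  t4 <- array(0, c(1, 1, 2, 4)); t4[, , , 1:2] <- truth2
  z4 <- array(-30, c(1, 1, 2, 4))
  z4[1, 1, 1, 1:2] <- c(log(0.8), log(0.2)) * 1.5
  z4[1, 1, 2, 1:2] <- c(log(0.4), log(0.6)) * 1.5
  lt2 <- total_loss(t4, z4, lc)
  p4 <- temperature_softmax(z4, 1.5)
  expect_equal(as.numeric(lt2),
               0.9 * soft_dice_loss(t4, p4) +
                 0.1 * temperature_cross_entropy(t4, z4, 1.5), tolerance = 1e-12)
  expect_error(loss_config(beta1 = 0.9, beta2 = 0.3), "must equal 1")
})

test_that("analytic loss gradients match central finite differences", {
  lc <- loss_config()
  for (case in 1:10) {
    set.seed(520 + case)
    logits <- array(rnorm(1 * 2 * 3 * 4), c(1, 2, 3, 4))
    truth <- one_hot(array(sample(0:3, 6, TRUE), c(1, 2, 3)), 4)
    g <- total_loss_grad(truth, logits, lc)
    expect_true(all(is.finite(g)))
    for (probe in 1:4) {
      idx <- sample(length(logits), 1)
      eps <- 1e-5
      zp <- logits; zp[idx] <- zp[idx] + eps
      zm <- logits; zm[idx] <- zm[idx] - eps
      fd <- (as.numeric(total_loss(truth, zp, lc)) -
               as.numeric(total_loss(truth, zm, lc))) / (2 * eps)
      expect_equal(g[idx], fd, tolerance = 1e-4)
    }
  }
})
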