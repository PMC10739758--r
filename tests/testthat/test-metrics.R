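# Segmentation metrics and the mask-derived bounding-box mAP protocol.

test_that("confusion matrix tallies pixels exactly", {
  m <- matrix(c(0, 1, 2, 3), 2, 2)
  cm <- confusion_matrix(m, m)
  expect_identical(unname(diag(cm)), rep(1L, 4))
  expect_identical(sum(cm), 4L)
  # constant-background prediction puts everything in one column
  truth <- rand_mask(4, 4, 600)
  cm2 <- confusion_matrix(matrix(0L, 4, 4), truth)
  expect_true(all(cm2[, -1] == 0L))
  expect_identical(as.integer(rowSums(cm2)),
                   tabulate(as.vector(truth) + 1L, 4L))
  # random masks vs per-pixel loop tally
  pred <- rand_mask(4, 4, 601)
  cm3 <- confusion_matrix(pred, truth)
  for (a in 0:3) for (b in 0:3)
    expect_identical(cm3[a + 1, b + 1], sum(truth == a & pred == b))
  expect_error(confusion_matrix(matrix(5L, 2, 2), matrix(0L, 2, 2)), "labels")
})

test_that("IoU and Dice hit hand-counted anchors and satisfy their identity", {
  # identical masks
  m <- rand_mask(6, 6, 602)
  r <- iou_and_dice(confusion_matrix(m, m))
  expect_true(all(stats::na.omit(r$classwise_iou) == 1))
  expect_identical(r$mean_dice, 1)
  # disjoint single-class masks
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  r2 <- iou_and_dice(confusion_matrix(a, b))
  expect_identical(unname(r2$classwise_iou["unripe"]), 0)
  # 4x4 toy: 2x2 truth square of class 1 vs prediction shifted by 1 px
  truth <- matrix(0L, 4, 4); truth[2:3, 2:3] <- 1L
  pred <- matrix(0L, 4, 4); pred[2:3, 3:4] <- 1L
  r3 <- iou_and_dice(confusion_matrix(pred, truth))
  expect_equal(unname(r3$classwise_iou["unripe"]), 1 / 3)
  expect_equal(unname(r3$classwise_dice["unripe"]), 1 / 2)
  # Dice = 2 IoU / (1 + IoU) on random confusions
  for (case in 1:20) {
    cm <- matrix(sample(0:30, 16, TRUE), 4, 4)
    r4 <- iou_and_dice(cm)
    ok <- !is.na(r4$classwise_iou)
    expect_equal(r4$classwise_dice[ok],
                 2 * r4$classwise_iou[ok] / (1 + r4$classwise_iou[ok]),
                 tolerance = 1e-12)
  }
})

test_that("component labelling agrees with a flood-fill oracle at 4 and 8 connectivity", {
  for (case in 1:10) {
    set.seed(610 + case)
    b <- matrix(runif(12 * 12) < 0.4, 12, 12)
    for (conn in c(4L, 8L)) {
      got <- label_components(b, conn)
      oracle <- flood_fill_components(b, conn)
      # same partition: component counts and pixel-set equality
      expect_identical(max(got), max(oracle))
      for (k in seq_len(max(oracle)))
        expect_identical(length(unique(got[oracle == k])), 1L)
    }
  }
  # two blobs touching only diagonally: 1 component at 8-, 2 at 4-connectivity
  d <- matrix(FALSE, 4, 4); d[1:2, 1:2] <- TRUE; d[3:4, 3:4] <- TRUE
  expect_identical(max(label_components(d, 8L)), 1L)
  expect_identical(max(label_components(d, 4L)), 2L)
})

test_that("instance boxes are min/max extents scored by mean confidence", {
  mask <- matrix(0L, 12, 12)
  mask[3:7, 2:8] <- 3L  # 5x7 fully-ripe rectangle
  probs <- array(0.05, c(12, 12, 4))
  probs[, , 4] <- 0.8
  inst <- masks_to_instances(mask, probs)
  expect_identical(nrow(inst), 1L)
  expect_identical(c(inst$row_min, inst$col_min, inst$row_max, inst$col_max),
                   c(3L, 2L, 7L, 8L))
  expect_equal(inst$score, 0.8)
  expect_identical(inst$pixels, 35L)
  # empty mask
  expect_identical(nrow(masks_to_instances(matrix(0L, 4, 4))), 0L)
  # diagonal-touch blobs, both connectivities (flood-fill verified above)
  m2 <- matrix(0L, 4, 4); m2[1:2, 1:2] <- 1L; m2[3:4, 3:4] <- 1L
  expect_identical(nrow(masks_to_instances(m2, connectivity = 8L)), 1L)
  expect_identical(nrow(masks_to_instances(m2, connectivity = 4L)), 2L)
})

test_that("AP matches the exhaustive PR-enumeration oracle on constructed rankings", {
  gt1 <- box_df(c(2, 2, 5, 5))
  cases <- list(
    # perfect detection
    list(pred = box_df(c(2, 2, 5, 5), score = 0.9), truth = gt1),
    # match, miss, duplicate-match ranking
    list(pred = box_df(c(2, 2, 5, 5), c(10, 10, 12, 12), c(2, 2, 5, 5),
                       score = c(0.9, 0.8, 0.7)), truth = gt1),
    # miss ranked first
    list(pred = box_df(c(10, 10, 12, 12), c(2, 2, 5, 5),
                       score = c(0.9, 0.2)), truth = gt1),
    # two ground truths, one found
    list(pred = box_df(c(2, 2, 5, 5), score = 0.6),
         truth = box_df(c(2, 2, 5, 5), c(8, 8, 11, 11))),
    # partial-overlap below threshold
    list(pred = box_df(c(4, 4, 7, 7), score = 0.5), truth = gt1),
    # overlapping preds fighting for one gt
    list(pred = box_df(c(2, 2, 5, 5), c(2, 2, 5, 6), c(3, 2, 5, 5),
                       score = c(0.3, 0.8, 0.5)), truth = gt1),
    # many gts, interleaved hits and misses
    list(pred = box_df(c(1, 1, 2, 2), c(9, 9, 9, 9), c(5, 5, 6, 6), c(12, 1, 13, 2),
                       score = c(0.9, 0.7, 0.6, 0.4)),
         truth = box_df(c(1, 1, 2, 2), c(5, 5, 6, 6), c(20, 20, 21, 21))),
    # duplicate scores (tie handling must still be deterministic)
    list(pred = box_df(c(2, 2, 5, 5), c(9, 9, 10, 10), score = c(0.5, 0.5)),
         truth = gt1),
    # no predictions
    list(pred = box_df(c(2, 2, 5, 5), score = 1)[0, ], truth = gt1),
    # no ground truth but predictions
    list(pred = box_df(c(2, 2, 5, 5), score = 1), truth = gt1[0, ]))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    got <- average_precision(cs$pred, cs$truth)$ap[["unripe"]]
    want <- ap_enumeration_oracle(cs$pred, cs$truth, 0.5)
    expect_equal(got, want, info = paste("case", i), tolerance = 1e-12)
  }
  # identical boxes for all three classes give mAP 1
  all3 <- do.call(rbind, lapply(1:3, function(cl)
    box_df(c(2, 2, 5, 5), class_label = cl)))
  expect_identical(average_precision(all3, all3)$map, 1)
  # empty everything: every class excluded
  e <- all3[0, ]
  expect_identical(average_precision(e, e)$map, 1)
  expect_error(average_precision(all3, all3, iou_threshold = 1.2), "\\(0, 1\\)")
})

test_that("adding a correct top-ranked detection never lowers AP", {
  set.seed(620)
  truth <- box_df(c(1, 1, 4, 4), c(8, 8, 11, 11), c(20, 20, 23, 23))
  pred <- box_df(c(1, 1, 4, 4), c(30, 30, 31, 31), score = c(0.6, 0.5))
  base <- average_precision(pred, truth)$ap[["unripe"]]
  better <- rbind(box_df(c(8, 8, 11, 11), score = 0.9), pred)
  expect_gte(average_precision(better, truth)$ap[["unripe"]], base)
})

test_that("pixel AUC equals exhaustive pairwise counting, including ties", {
  # 8-pixel toy with ties
  truth <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L), 2, 4)
  probs <- array(0, c(2, 4, 4))
  probs[, , 2] <- matrix(c(0.9, 0.8, 0.8, 0.1, 0.5, 0.5, 0.3, 0.2), 2, 4)
  got <- pixel_auc(probs, truth)
  want <- auc_pairwise_oracle(as.vector(probs[, , 2]), as.vector(truth == 1L))
  expect_equal(unname(got$classwise_auc["unripe"]), want, tolerance = 1e-12)
  # perfect ranking -> 1; inverted -> 0
  p2 <- probs
  p2[, , 2] <- matrix(as.numeric(truth == 1L), 2, 4)
  expect_identical(unname(pixel_auc(p2, truth)$classwise_auc["unripe"]), 1)
  p2[, , 2] <- 1 - p2[, , 2]
  expect_identical(unname(pixel_auc(p2, truth)$classwise_auc["unripe"]), 0)
  # absent classes are excluded; all absent -> NA
  expect_true(is.na(pixel_auc(probs, matrix(0L, 2, 4))$auc))
  # random cases against the pairwise oracle
  for (case in 1:10) {
    set.seed(630 + case)
    t2 <- rand_mask(3, 4, 630 + case)
    pr <- array(runif(3 * 4 * 4), c(3, 4, 4))
    got2 <- pixel_auc(pr, t2)
    for (cls in 1:3) {
      if (is.na(got2$classwise_auc[cls])) next
      expect_equal(unname(got2$classwise_auc[cls]),
                   auc_pairwise_oracle(as.vector(pr[, , cls + 1]),
                                       as.vector(t2 == cls)),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(640)
  truth <- rand_mask(8, 8, 641)
  probs <- array(runif(8 * 8 * 4), c(8, 8, 4))
  got <- pixel_auc(probs, truth)
  for (cls in 1:3) {
    if (is.na(got$classwise_auc[cls])) next
    ref <- suppressMessages(pROC::auc(as.vector(truth == cls),
                                      as.vector(probs[, , cls + 1]),
                                      direction = "<"))
    expect_equal(unname(got$classwise_auc[cls]), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("generator boxes score mAP 1 against mask-derived instances", {
  for (seed in c(3, 17)) {
    sc <- generate_scene(scene_config(occlusion_density = 0, seed = seed))
    derived <- masks_to_instances(sc$mask)
    gen <- sc$instances
    gen_boxes <- data.frame(class_label = gen$class_label,
                            row_min = gen$row_min, col_min = gen$col_min,
                            row_max = gen$row_max, col_max = gen$col_max,
                            score = 1, pixels = gen$visible_pixels)
    res <- average_precision(derived, gen_boxes)
    expect_identical(res$map, 1)
  }
})
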