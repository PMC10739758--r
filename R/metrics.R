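# Segmentation and detection metrics: confusion matrix, classwise IoU / Dice,
# pixelwise one-vs-rest ROC AUC, and the mask-derived bounding-box mAP
# protocol (connected components -> minimum bounding rectangles scored by
# mean pixel confidence -> greedy matching -> all-point interpolated AP).

#' Pixel confusion matrix
#'
#' @param pred,truth congruent integer label masks with labels in
#'   `0..c_se-1`.
#' @param c_se class count (default 4).
#' @return `c_se x c_se` count matrix; entry `(a, b)` counts pixels with
#'   truth `a-1` and prediction `b-1` (rows = truth).
#' @export
confusion_matrix <- function(pred, truth, c_se = 4L) {
  if (!identical(dim(pred), dim(truth))) stop("pred/truth shape mismatch")
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L | p >= c_se) || any(t < 0L | t >= c_se))
    stop("labels outside 0..", c_se - 1L)
  tab <- tabulate(t * c_se + p + 1L, nbins = c_se * c_se)
  m <- matrix(tab, c_se, c_se, byrow = TRUE)
  nms <- if (c_se == 4L) names(ripeness_levels()) else paste0("class", 0:(c_se - 1L))
  dimnames(m) <- list(truth = nms, pred = nms)
  m
}

#' IoU and Dice from a confusion matrix
#'
#' Per class: `IoU = TP / (TP + FP + FN)`, `Dice = 2 TP / (2 TP + FP + FN)`.
#' Means are taken over the three tomato classes (background excluded by
#' default, matching how the segmentation scores are reported); classes
#' absent from both prediction and truth are excluded from the means.
#'
#' @param confusion matrix from [confusion_matrix()].
#' @param include_background also average over the background class.
#' @return list: `classwise_iou`, `classwise_dice` (named, NA for absent
#'   classes), `mean_iou`, `mean_dice`.
#' @export
iou_and_dice <- function(confusion, include_background = FALSE) {
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  denom <- tp + fp + fn
  iou <- ifelse(denom == 0, NA_real_, tp / denom)
  dice <- ifelse(denom == 0, NA_real_, 2 * tp / (2 * tp + fp + fn))
  keep <- if (include_background) seq_along(tp) else seq_along(tp)[-1L]
  list(classwise_iou = iou[keep], classwise_dice = dice[keep],
       mean_iou = mean(iou[keep], na.rm = TRUE),
       mean_dice = mean(dice[keep], na.rm = TRUE))
}

#' Connected-component labelling of a binary mask
#'
#' Iterative minimum-label propagation; 8-connectivity by default
#' (diagonally touching pixels join one component), 4-connectivity optional.
#'
#' @param binary logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 for background, components numbered 1..k in
#'   first-pixel order.
#' @export
label_components <- function(binary, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  b <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  h <- nrow(b); w <- ncol(b)
  lab <- matrix(0L, h, w)
  lab[b] <- seq_len(h * w)[b] # initial label = linear pixel index
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- matrix(0L, h, w)
      r_src <- max(1L, 1L - s[1L]):min(h, h - s[1L])
      c_src <- max(1L, 1L - s[2L]):min(w, w - s[2L])
      sh[r_src + s[1L], c_src + s[2L]] <- lab[r_src, c_src]
      take <- b & sh > 0L & sh < new
      new[take] <- sh[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  relab <- integer(max(lab, 1L))
  relab[ids] <- seq_along(ids)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Instance boxes from a semantic mask
#'
#' For each tomato class, connected components of the class support are
#' extracted (8-connectivity by default); each component yields a minimum
#' bounding rectangle from the least and highest occupied row and column
#' indices, scored by the mean predicted probability of that class over the
#' component's pixels (1 when no probability map is supplied, e.g. for
#' ground-truth masks).
#'
#' @param mask `H x W` integer label mask.
#' @param probs optional `H x W x c_se` probability map.
#' @param connectivity 8 (default) or 4.
#' @return data frame: `class_label`, `row_min`, `col_min`, `row_max`,
#'   `col_max` (inclusive), `score`, `pixels`; zero rows for an empty mask.
#' @export
masks_to_instances <- function(mask, probs = NULL, connectivity = 8L) {
  out <- list()
  for (cls in 1:3) {
    lab <- label_components(mask == cls, connectivity)
    k <- max(lab)
    if (k == 0L) next
    for (comp in seq_len(k)) {
      idx <- which(lab == comp, arr.ind = TRUE)
      score <- if (is.null(probs)) 1 else
        mean(probs[, , cls + 1L][lab == comp])
      out[[length(out) + 1L]] <- data.frame(
        class_label = cls,
        row_min = min(idx[, 1L]), col_min = min(idx[, 2L]),
        row_max = max(idx[, 1L]), col_max = max(idx[, 2L]),
        score = score, pixels = nrow(idx))
    }
  }
  if (length(out) == 0L)
    return(data.frame(class_label = integer(0), row_min = integer(0),
                      col_min = integer(0), row_max = integer(0),
                      col_max = integer(0), score = numeric(0),
                      pixels = integer(0)))
  do.call(rbind, out)
}

#' Intersection-over-union of two boxes (inclusive pixel bounds)
#' @param a,b vectors/one-row frames with `row_min, col_min, row_max,
#'   col_max`.
#' @export
box_iou <- function(a, b) {
  ih <- max(0, min(a[["row_max"]], b[["row_max"]]) -
              max(a[["row_min"]], b[["row_min"]]) + 1)
  iw <- max(0, min(a[["col_max"]], b[["col_max"]]) -
              max(a[["col_min"]], b[["col_min"]]) + 1)
  inter <- ih * iw
  area <- function(x) (x[["row_max"]] - x[["row_min"]] + 1) *
    (x[["col_max"]] - x[["col_min"]] + 1)
  un <- area(a) + area(b) - inter
  if (un <= 0) 0 else inter / un
}

# AP for one class: predictions sorted by descending score, greedy one-to-one
# matching (within image) at IoU >= threshold, all-point interpolated area
# under the precision-recall curve.
.ap_one_class <- function(pred, truth, iou_threshold) {
  npos <- nrow(truth)
  if (nrow(pred) == 0L) return(if (npos == 0L) NA_real_ else 0)
  if (npos == 0L) return(0)
  ord <- order(-pred$score)
  pred <- pred[ord, , drop = FALSE]
  matched <- logical(npos)
  tp <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    best <- 0; best_j <- 0L
    for (j in seq_len(npos)) {
      if (matched[j]) next
      if (!is.null(pred$image) && !is.null(truth$image) &&
          pred$image[i] != truth$image[j]) next
      v <- box_iou(pred[i, ], truth[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      tp[i] <- 1
      matched[best_j] <- TRUE
    }
  }
  ctp <- cumsum(tp)
  cfp <- cumsum(1 - tp)
  recall <- ctp / npos
  precision <- ctp / (ctp + cfp)
  # precision envelope (running max from the right), integrated over recall
  penv <- rev(cummax(rev(precision)))
  ap <- 0
  prev_r <- 0
  for (i in seq_along(recall)) {
    if (recall[i] > prev_r) {
      ap <- ap + (recall[i] - prev_r) * penv[i]
      prev_r <- recall[i]
    }
  }
  ap
}

#' Average precision of instance boxes
#'
#' Detection-style evaluation of the mask-derived boxes: per class,
#' predictions are ranked by descending score and greedily matched one-to-one
#' to ground-truth boxes at box-IoU >= `iou_threshold`; AP is the area under
#' the all-point-interpolated precision-recall curve, and mAP the mean over
#' the three tomato classes. Classes with neither ground truth nor
#' predictions are excluded from the mean (mAP is 1 if every class is
#' excluded). An optional `image` column restricts matching to within-image
#' pairs.
#'
#' @param pred_boxes,truth_boxes data frames as returned by
#'   [masks_to_instances()] (optionally with an `image` id column).
#' @param iou_threshold box-IoU matching threshold in (0,1), default 0.5.
#' @return list: `ap` (named per-class vector, NA = excluded), `map`.
#' @export
average_precision <- function(pred_boxes, truth_boxes, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie in (0, 1)")
  ap <- stats::setNames(rep(NA_real_, 3L), c("unripe", "half_ripe", "fully_ripe"))
  for (cls in 1:3) {
    p <- pred_boxes[pred_boxes$class_label == cls, , drop = FALSE]
    t <- truth_boxes[truth_boxes$class_label == cls, , drop = FALSE]
    ap[cls] <- .ap_one_class(p, t, iou_threshold)
  }
  map <- if (all(is.na(ap))) 1 else mean(ap, na.rm = TRUE)
  list(ap = ap, map = map)
}

#' Pixelwise one-vs-rest ROC AUC
#'
#' For each tomato class present in the truth mask, the ROC AUC of that
#' class's predicted probability over all pixels (Mann-Whitney rank
#' statistic, ties counted 1/2), macro-averaged over the classes present.
#'
#' @param probs `H x W x c_se` probability map.
#' @param truth `H x W` integer label mask.
#' @return list: `classwise_auc` (named, NA for absent classes), `auc`
#'   (macro mean, NA if no tomato class is present).
#' @export
pixel_auc <- function(probs, truth) {
  if (!identical(dim(probs)[1:2], dim(truth))) stop("probs/truth shape mismatch")
  aucs <- stats::setNames(rep(NA_real_, 3L), c("unripe", "half_ripe", "fully_ripe"))
  for (cls in 1:3) {
    pos <- as.vector(truth == cls)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(as.vector(probs[, , cls + 1L]))
    aucs[cls] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(classwise_auc = aucs,
       auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE))
}
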