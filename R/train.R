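# Training: seed-deterministic dataset split, ADADELTA optimisation of the
# composite L_t objective, per-epoch validation, crash-safe JSON-line logs,
# checkpointing, and dataset-level evaluation.

#' Split a dataset into training and heldout parts
#'
#' Seed-deterministic shuffle followed by a `floor(n * split_fraction)` /
#' remainder split; the heldout part serves validation and testing.
#'
#' @param items list (or vector) of dataset items.
#' @param split_fraction training share in (0,1); default 0.75.
#' @param seed shuffle seed.
#' @return list: `train`, `heldout`, plus the index vectors `train_idx`,
#'   `heldout_idx`.
#' @export
split_dataset <- function(items, split_fraction = 0.75, seed = 1L) {
  n <- length(items)
  if (n < 2L) stop("need at least 2 items to split")
  n_train <- floor(n * split_fraction)
  if (n_train < 1L || n_train >= n)
    stop("split_fraction = ", split_fraction, " yields an empty part for n = ", n)
  perm <- with_seed(seed, sample.int(n))
  ti <- sort(perm[seq_len(n_train)])
  hi <- sort(perm[(n_train + 1L):n])
  list(train = items[ti], heldout = items[hi], train_idx = ti, heldout_idx = hi)
}

# One ADADELTA update; opt_state carries E[g^2] and E[dx^2] trees mirroring
# the gradient tree (lazily initialised to zero).
adadelta_step <- function(params, grads, opt_state, lr, rho, eps) {
  if (is.null(opt_state))
    opt_state <- list(eg = rapply(grads, function(x) x * 0, how = "replace"),
                      ed = rapply(grads, function(x) x * 0, how = "replace"))
  upd <- function(p, g, eg, ed) {
    if (!is.list(g)) {
      eg <- rho * eg + (1 - rho) * g * g
      dx <- -sqrt(ed + eps) / sqrt(eg + eps) * g
      ed <- rho * ed + (1 - rho) * dx * dx
      list(p = p + lr * dx, eg = eg, ed = ed)
    } else {
      keys <- if (!is.null(names(g))) names(g) else seq_along(g)
      for (k in keys) {
        if (is.null(g[[k]])) next
        r <- upd(p[[k]], g[[k]], eg[[k]], ed[[k]])
        p[[k]] <- r$p; eg[[k]] <- r$eg; ed[[k]] <- r$ed
      }
      list(p = p, eg = eg, ed = ed)
    }
  }
  r <- upd(params, grads, opt_state$eg, opt_state$ed)
  list(params = r$p, opt_state = list(eg = r$eg, ed = r$ed))
}

.stack_batch <- function(items, idx) {
  d <- dim(items[[idx[1L]]]$image)
  x <- array(0, c(length(idx), d))
  m <- array(0L, c(length(idx), d[1:2]))
  for (s in seq_along(idx)) {
    x[s, , , ] <- items[[idx[s]]]$image
    m[s, , ] <- items[[idx[s]]]$mask
  }
  list(x = x, mask = m)
}

#' Train the segmentation model
#'
#' Minimises `L_t` by mini-batch gradient descent with ADADELTA (published
#' defaults: learning rate 1.00, decay rho 0.95). After every epoch the
#' model is evaluated on the validation set (loss and tomato-class mean IoU,
#' batch norms in inference mode); the best-by-validation-mIoU and the final
#' parameters are both returned. Fully seed-deterministic.
#'
#' @param dataset list of scenes (`image`, `mask`), e.g. [read_dataset()]
#'   output; images must match `config$model$input_size`.
#' @param config a [train_config()].
#' @param validation optional heldout scenes; when `NULL` and
#'   `auto_split = TRUE`, [split_dataset()] carves out
#'   `1 - split_fraction` of `dataset`.
#' @param auto_split split `dataset` internally when no validation set is
#'   given (requires >= 2 scenes).
#' @param log_file optional path; one JSON line per epoch, flushed before
#'   the next epoch starts.
#' @param verbose print per-epoch progress.
#' @return list: `checkpoint` (best model + metadata), `last` (final-epoch
#'   model), `log` (data frame of per-epoch records).
#' @export
train <- function(dataset, config = train_config(), validation = NULL,
                  auto_split = is.null(validation) && length(dataset) >= 2L,
                  log_file = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("dataset is empty")
  if (auto_split && is.null(validation)) {
    sp <- split_dataset(dataset, config$split_fraction, config$seed)
    dataset <- sp$train
    validation <- sp$heldout
  }
  d <- dim(dataset[[1L]]$image)
  if (!identical(as.integer(d[1:2]), config$model$input_size))
    stop("dataset images are ", d[1L], "x", d[2L], " but the model expects ",
         paste(config$model$input_size, collapse = "x"))
  model <- build_model(config$model, seed = config$seed)
  n <- length(dataset)
  iters <- if (is.null(config$iterations_per_epoch))
    max(1L, ceiling(n / config$batch_size)) else config$iterations_per_epoch
  opt_state <- NULL
  best <- list(miou = -Inf, params = model$params)
  log <- vector("list", config$epochs)
  ce_calls <- 0L

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      epoch_losses <- numeric(iters)
      for (it in seq_len(iters)) {
        idx <- if (n == 1L) rep(1L, config$batch_size) else
          sample.int(n, config$batch_size, replace = n < config$batch_size)
        b <- .stack_batch(dataset, idx)
        truth <- one_hot(b$mask, config$loss$c_se)
        f <- net_fwd(model$params, model$config, b$x, training = TRUE)
        model$params <- f$params
        lt <- total_loss(truth, f$logits, config$loss)
        if (!is.finite(lt))
          stop("non-finite loss at epoch ", epoch, ", iteration ", it,
               " (batch indices ", paste(idx, collapse = ","), ")")
        if (isTRUE(attr(lt, "ce_evaluated"))) ce_calls <- ce_calls + 1L
        epoch_losses[it] <- as.numeric(lt)
        dl <- total_loss_grad(truth, f$logits, config$loss)
        grads <- net_bwd(dl, f$cache, model$params, model$config)
        st <- adadelta_step(model$params, grads, opt_state,
                            config$learning_rate, config$decay, config$epsilon)
        model$params <- st$params
        opt_state <- st$opt_state
      }
      rec <- list(epoch = epoch, train_loss = mean(epoch_losses),
                  val_loss = NA_real_, val_miou = NA_real_,
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
      if (!is.null(validation) && length(validation) > 0L) {
        v <- .validate(model, validation, config$loss)
        rec$val_loss <- v$loss
        rec$val_miou <- v$miou
        if (is.finite(v$miou) && v$miou > best$miou)
          best <- list(miou = v$miou, params = model$params, epoch = epoch)
      }
      log[[epoch]] <- rec
      if (!is.null(log_file)) {
        con <- file(log_file, open = "a")
        writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                                 digits = NA)), con)
        close(con) # flushed before the next epoch begins
      }
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f val_miou %s", epoch,
                        config$epochs, rec$train_loss,
                        ifelse(is.na(rec$val_miou), "-",
                               sprintf("%.3f", rec$val_miou))))
    }
  })
  if (!is.finite(best$miou)) best <- list(miou = NA_real_,
                                          params = model$params,
                                          epoch = config$epochs)
  best_model <- model
  best_model$params <- best$params
  ckpt <- list(model = best_model, train_config = config,
               best_epoch = best$epoch, best_val_miou = best$miou,
               hash = model$hash, ce_loss_calls = ce_calls)
  class(ckpt) <- "tf_checkpoint"
  list(checkpoint = ckpt, last = model,
       log = do.call(rbind, lapply(log, as.data.frame)))
}

.validate <- function(model, validation, loss_cfg) {
  losses <- numeric(length(validation))
  conf <- NULL
  for (i in seq_along(validation)) {
    item <- validation[[i]]
    f <- model_forward(model, item$image)
    truth <- one_hot(item$mask, loss_cfg$c_se)
    losses[i] <- as.numeric(total_loss(truth, f$logits, loss_cfg))
    cm <- confusion_matrix(f$mask, item$mask, loss_cfg$c_se)
    conf <- if (is.null(conf)) cm else conf + cm
  }
  list(loss = mean(losses), miou = iou_and_dice(conf)$mean_iou)
}

#' Save / load a training checkpoint
#'
#' Checkpoints embed the model parameters, the full training configuration
#' and the model-config hash; [load_checkpoint()] refuses a file whose
#' embedded hash does not match its own configuration.
#'
#' @param checkpoint a checkpoint from [train()].
#' @param path file path (RDS container).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "tf_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "tf_checkpoint")) stop(path, " is not a checkpoint")
  if (!identical(ck$hash, config_hash(ck$model$config)))
    stop("checkpoint hash mismatch: ", ck$hash, " vs ",
         config_hash(ck$model$config),
         " — the file does not match its embedded model configuration")
  ck
}

#' Evaluate a model on a dataset
#'
#' Runs the model over every scene and aggregates one report: the pixel
#' confusion matrix, classwise/mean IoU and Dice over the tomato classes,
#' pixelwise one-vs-rest AUC (pooled over scenes), and the mask-derived
#' bounding-box mAP (predicted-mask components scored by mean class
#' confidence, matched within each scene against ground-truth-mask
#' components).
#'
#' @param model a model from [build_model()]/[train()], or a checkpoint.
#' @param dataset list of scenes (`image`, `mask`).
#' @param iou_threshold box-IoU threshold of the mAP matching (default 0.5).
#' @param connectivity component connectivity for instancing (default 8).
#' @return list of class `"tf_metric_report"`: `classwise_iou`, `mean_iou`,
#'   `mean_dice`, `map_score`, `ap`, `auc`, `confusion`.
#' @export
evaluate <- function(model, dataset, iou_threshold = 0.5, connectivity = 8L) {
  if (inherits(model, "tf_checkpoint")) {
    if (!identical(model$hash, config_hash(model$model$config)))
      stop("checkpoint hash does not match its model configuration")
    model <- model$model
  }
  conf <- NULL
  pred_boxes <- truth_boxes <- list()
  auc_num <- c(unripe = 0, half_ripe = 0, fully_ripe = 0)
  auc_den <- c(unripe = 0L, half_ripe = 0L, fully_ripe = 0L)
  for (i in seq_along(dataset)) {
    item <- dataset[[i]]
    f <- model_forward(model, item$image)
    cm <- confusion_matrix(f$mask, item$mask)
    conf <- if (is.null(conf)) cm else conf + cm
    pb <- masks_to_instances(f$mask, f$probs, connectivity)
    tb <- masks_to_instances(item$mask, NULL, connectivity)
    if (nrow(pb)) { pb$image <- i; pred_boxes[[length(pred_boxes) + 1L]] <- pb }
    if (nrow(tb)) { tb$image <- i; truth_boxes[[length(truth_boxes) + 1L]] <- tb }
    pa <- pixel_auc(f$probs, item$mask)
    ok <- !is.na(pa$classwise_auc)
    auc_num[ok] <- auc_num[ok] + pa$classwise_auc[ok]
    auc_den[ok] <- auc_den[ok] + 1L
  }
  empty <- data.frame(class_label = integer(0), row_min = integer(0),
                      col_min = integer(0), row_max = integer(0),
                      col_max = integer(0), score = numeric(0),
                      pixels = integer(0), image = integer(0))
  pb <- if (length(pred_boxes)) do.call(rbind, pred_boxes) else empty
  tb <- if (length(truth_boxes)) do.call(rbind, truth_boxes) else empty
  ap <- average_precision(pb, tb, iou_threshold)
  seg <- iou_and_dice(conf)
  cw_auc <- ifelse(auc_den > 0, auc_num / pmax(auc_den, 1L), NA_real_)
  structure(list(classwise_iou = seg$classwise_iou, mean_iou = seg$mean_iou,
                 mean_dice = seg$mean_dice, map_score = ap$map, ap = ap$ap,
                 auc = if (all(is.na(cw_auc))) NA_real_ else
                   mean(cw_auc, na.rm = TRUE),
                 classwise_auc = cw_auc, confusion = conf),
            class = "tf_metric_report")
}
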