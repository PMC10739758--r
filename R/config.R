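# Model and training configuration.

#' Model configuration
#'
#' Describes the full segmentation network: a five-level convolutional encoder
#' of shape-preservation blocks (SPBs) and residual blocks (RBs), an optional
#' cascaded patch-transformer branch, the feature-fusion stage and the
#' max-unpooling decoder.
#'
#' @param input_size `c(rows, cols)`; both must be divisible by 32 (the
#'   encoder downsamples by 2^5) and by `transformer$patch_size`.
#' @param widths channel widths of encoder levels E-1..E-5.
#' @param width_multiplier scales all widths (rounded, floor 1); handy for
#'   desk-scale models.
#' @param spb_per_level SPB count per level; must sum to 11 and give 3-4
#'   blocks per level once the per-level RB is added.
#' @param n_classes segmentation classes including background (default 4:
#'   background, unripe, half-ripe, fully-ripe).
#' @param use_transformer `FALSE` builds the fully convolutional ablation
#'   variant (no transformer branch, no fusion stage).
#' @param fusion `"product"` gates the encoder features multiplicatively with
#'   the projected transformer tokens before a 3x3 convolution; `"concat"`
#'   concatenates instead.
#' @param transformer list: `depth` (cascaded encoders, default 3), `width`
#'   (embedding width l), `heads`, `ff_width`, `patch_size`.
#' @return validated config list of class `"tf_model_config"`.
#' @export
model_config <- function(input_size = c(64L, 64L),
                         widths = c(16L, 32L, 64L, 128L, 256L),
                         width_multiplier = 1,
                         spb_per_level = c(2L, 2L, 2L, 2L, 3L),
                         n_classes = 4L,
                         use_transformer = TRUE,
                         fusion = c("product", "concat"),
                         transformer = list(depth = 3L, width = 128L, heads = 4L,
                                            ff_width = 256L, patch_size = 8L)) {
  fusion <- match.arg(fusion)
  tdef <- list(depth = 3L, width = 128L, heads = 4L, ff_width = 256L, patch_size = 8L)
  transformer <- utils::modifyList(tdef, transformer)
  widths <- pmax(1L, as.integer(round(widths * width_multiplier)))
  if (length(widths) != 5L) stop("widths must have 5 entries (levels E-1..E-5)")
  if (length(spb_per_level) != 5L || sum(spb_per_level) != 11L)
    stop("spb_per_level must have 5 entries summing to 11")
  if (any(spb_per_level + 1L < 3L) || any(spb_per_level + 1L > 4L))
    stop("each level must hold 3-4 blocks (SPBs plus its RB)")
  if (any(input_size %% 32L != 0L))
    stop("input dims must be divisible by 2^5 = 32, got ",
         paste(input_size, collapse = "x"))
  if (transformer$depth < 1L)
    stop("transformer depth must be >= 1; disable the branch with use_transformer = FALSE")
  if (transformer$width %% transformer$heads != 0L)
    stop("transformer width must be divisible by the head count")
  p <- transformer$patch_size
  if (use_transformer && any(input_size %% p != 0L))
    stop("input dims must be divisible by patch_size = ", p)
  cfg <- list(input_size = as.integer(input_size), widths = widths,
              spb_per_level = as.integer(spb_per_level),
              n_classes = as.integer(n_classes),
              use_transformer = isTRUE(use_transformer), fusion = fusion,
              transformer = transformer)
  cfg$n_p <- as.integer(prod(input_size %/% p))
  class(cfg) <- "tf_model_config"
  cfg
}

#' Desk-scale model preset
#'
#' A small configuration (64x64 input, widths 4..64, 32-wide transformer)
#' used throughout the tests and the worked examples; architecture shape
#' (5 levels, 11 SPBs, 5 RBs, 3 cascaded transformer encoders) is unchanged.
#' @param ... overrides forwarded to [model_config()].
#' @export
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(input_size = c(64L, 64L), widths = c(16L, 32L, 64L, 128L, 256L),
         width_multiplier = 0.25,
         transformer = list(width = 32L, heads = 2L, ff_width = 64L,
                            patch_size = 8L)),
    list(...))
  do.call(model_config, args)
}

#' Training configuration
#'
#' @param epochs training epochs (published setting: 200).
#' @param batch_size mini-batch size (published setting: 16).
#' @param iterations_per_epoch batches per epoch; `NULL` derives it from the
#'   dataset size (`ceiling(n_train / batch_size)`). Set 512 to mirror the
#'   published schedule via oversampling.
#' @param split_fraction training share of a 2-way split (published: 0.75).
#' @param optimizer only `"adadelta"` is provided.
#' @param learning_rate ADADELTA learning rate (published default 1.00).
#' @param decay ADADELTA accumulation/decay rate rho (published default 0.95).
#' @param epsilon ADADELTA conditioning constant.
#' @param seed master seed for the run (model init, batch order).
#' @param loss a [loss_config()].
#' @param model a [model_config()].
#' @export
train_config <- function(epochs = 200L, batch_size = 16L,
                         iterations_per_epoch = NULL,
                         split_fraction = 0.75,
                         optimizer = "adadelta",
                         learning_rate = 1.00, decay = 0.95, epsilon = 1e-6,
                         seed = 1L,
                         loss = loss_config(),
                         model = model_config()) {
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  if (!identical(optimizer, "adadelta")) stop("unsupported optimizer: ", optimizer)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 iterations_per_epoch = iterations_per_epoch,
                 split_fraction = split_fraction, optimizer = optimizer,
                 learning_rate = learning_rate, decay = decay, epsilon = epsilon,
                 seed = as.integer(seed), loss = loss, model = model),
            class = "tf_train_config")
}

# Deterministic FNV-1a hash of a config (used to pair checkpoints with the
# model build that produced them).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
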