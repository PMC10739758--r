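# Paired image/mask augmentation. Geometric ops (flips, rotation, shear,
# zoom) transform the image and the mask with identical geometry — images
# bilinearly, masks nearest-neighbour (labels are categorical, so
# interpolation must never invent labels); exposed regions are filled with
# background (label 0, black pixels). Photometric and noise ops (brightness,
# blur, salt & pepper, speckle) leave the mask untouched. Rotation, shear,
# zoom and blur are delegated to EBImage.

AUG_OPS <- c("brightness", "blur", "hflip", "vflip", "rotation",
             "shear_h", "shear_v", "salt_pepper", "speckle", "zoom")

# default magnitude (or sampling range) per op
.aug_defaults <- function() {
  list(brightness = list(delta = c(-0.25, 0.25)),
       blur = list(sigma = 1.0),
       hflip = list(), vflip = list(),
       rotation = list(angle = c(-30, 30)),
       shear_h = list(shear = c(-0.27, 0.27)), # tan(15 deg) ~ 0.27
       shear_v = list(shear = c(-0.27, 0.27)),
       salt_pepper = list(rate = 0.02),
       speckle = list(variance = 0.05),
       zoom = list(factor = c(0.8, 1.2)))
}

#' Create an augmentation spec
#'
#' @param op_name one of `brightness`, `blur`, `hflip`, `vflip`, `rotation`,
#'   `shear_h`, `shear_v`, `salt_pepper`, `speckle`, `zoom`.
#' @param params named op parameters; a length-2 numeric entry is treated as
#'   a sampling range resolved with the spec seed. Defaults: rotation within
#'   +/-30 degrees, shear within +/-15 degrees, zoom 0.8-1.2, brightness
#'   +/-25%, salt-pepper rate 0.02, speckle variance 0.05, blur sigma 1.
#' @param seed integer seed driving range resolution and the noise ops.
#' @return list of class `"tf_aug_spec"`.
#' @export
augmentation_spec <- function(op_name, params = list(), seed = 1L) {
  if (!op_name %in% AUG_OPS)
    stop("unknown augmentation op '", op_name, "'; choose from: ",
         paste(AUG_OPS, collapse = ", "))
  p <- utils::modifyList(.aug_defaults()[[op_name]], params)
  if (op_name == "zoom" && length(p$factor) == 1L && p$factor <= 0)
    stop("zoom factor must be > 0")
  if (op_name == "salt_pepper" &&
      any(p$rate < 0 | p$rate > 1))
    stop("salt_pepper rate must lie in [0, 1]")
  structure(list(op_name = op_name, params = p, seed = as.integer(seed)),
            class = "tf_aug_spec")
}

.resolve_params <- function(spec) {
  p <- spec$params
  ranged <- vapply(p, function(v) is.numeric(v) && length(v) == 2L, logical(1))
  if (any(ranged)) {
    p[ranged] <- with_seed(spec$seed, lapply(p[ranged], function(v)
      stats::runif(1, min(v), max(v))))
  }
  p
}

.to_ebi <- function(img) EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                        colormode = "Color")
.from_ebi <- function(e) aperm(EBImage::imageData(e), c(2L, 1L, 3L))
.to_ebi_mask <- function(mask) EBImage::Image(t(mask))
.from_ebi_mask <- function(e) {
  m <- t(EBImage::imageData(e))
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

# centre-anchored affine for a 2x2 matrix A acting on EBImage (x, y) row
# vectors: p' = (p - c) A + c
.affine_pair <- function(image, mask, a) {
  h <- nrow(mask); w <- ncol(mask)
  ctr <- c(w / 2 + 0.5, h / 2 + 0.5)
  m <- rbind(a, ctr - ctr %*% a)
  img2 <- .from_ebi(EBImage::affine(.to_ebi(image), m, filter = "bilinear",
                                    output.dim = c(w, h), bg.col = 0))
  msk2 <- .from_ebi_mask(EBImage::affine(.to_ebi_mask(mask), m, filter = "none",
                                         output.dim = c(w, h), bg.col = 0))
  list(image = clip01(img2), mask = msk2)
}

#' Apply one augmentation to an image/mask pair
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @param mask `H x W` integer label mask of the same spatial shape.
#' @param spec an [augmentation_spec()].
#' @return list with the transformed `image` and `mask` and the resolved
#'   `params` actually applied.
#' @export
apply_augmentation <- function(image, mask, spec) {
  if (!inherits(spec, "tf_aug_spec")) stop("spec must be an augmentation_spec()")
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask must share spatial shape")
  p <- .resolve_params(spec)
  h <- nrow(mask); w <- ncol(mask)
  out <- switch(
    spec$op_name,
    hflip = list(image = image[, w:1, , drop = FALSE], mask = mask[, w:1, drop = FALSE]),
    vflip = list(image = image[h:1, , , drop = FALSE], mask = mask[h:1, , drop = FALSE]),
    rotation = {
      th <- p$angle * pi / 180
      .affine_pair(image, mask, rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))))
    },
    shear_h = .affine_pair(image, mask, rbind(c(1, 0), c(p$shear, 1))),
    shear_v = .affine_pair(image, mask, rbind(c(1, p$shear), c(0, 1))),
    zoom = {
      if (p$factor <= 0) stop("zoom factor must be > 0")
      .affine_pair(image, mask, diag(c(p$factor, p$factor)))
    },
    brightness = list(image = clip01(image * (1 + p$delta)), mask = mask),
    blur = {
      img2 <- if (p$sigma <= 0) image else
        clip01(.from_ebi(EBImage::gblur(.to_ebi(image), sigma = p$sigma)))
      list(image = img2, mask = mask)
    },
    salt_pepper = {
      img2 <- with_seed(spec$seed, {
        n <- h * w
        hit <- which(stats::runif(n) < p$rate)
        val <- sample(c(0, 1), length(hit), replace = TRUE)
        im <- image
        for (ch in 1:3) {
          plane <- im[, , ch]
          plane[hit] <- val
          im[, , ch] <- plane
        }
        im
      })
      list(image = img2, mask = mask)
    },
    speckle = {
      img2 <- with_seed(spec$seed, {
        noise <- array(stats::rnorm(length(image), 0, sqrt(p$variance)),
                       dim(image))
        clip01(image * (1 + noise))
      })
      list(image = img2, mask = mask)
    })
  out$image <- array(out$image, c(h, w, 3L))
  out$mask <- matrix(as.integer(out$mask), h, w)
  if (any(!out$mask %in% 0:3)) stop("augmentation produced labels outside 0..3")
  out$params <- p
  out
}

#' Augment a dataset
#'
#' Emits `multiplier` stochastic variants per input scene; each variant
#' applies every spec in `spec_list` in order, with fresh per-variant seeds
#' (recorded in the output) resolving ranged parameters and noise. Scenes
#' containing the minority half-ripe class can be oversampled by
#' `oversample_half_ripe`.
#'
#' @param dataset list of scenes (`image`, `mask`, ...), e.g. from
#'   [read_dataset()].
#' @param spec_list list of [augmentation_spec()]s (seeds therein are
#'   ignored; per-variant seeds are derived from `seed`).
#' @param multiplier variants per input (>= 1).
#' @param oversample_half_ripe extra multiplier factor for scenes containing
#'   label 2.
#' @param seed base seed.
#' @return list of augmented scenes, each with `image`, `mask`,
#'   `source_index`, `specs` (resolved op/param records) and `seed`.
#' @export
augment_dataset <- function(dataset, spec_list, multiplier = 1L,
                            oversample_half_ripe = 1L, seed = 1L) {
  if (length(spec_list) == 0L) stop("spec_list must contain at least one spec")
  if (multiplier < 1L) stop("multiplier must be >= 1")
  out <- list()
  vseed <- seed
  for (i in seq_along(dataset)) {
    item <- dataset[[i]]
    reps <- multiplier *
      if (any(item$mask == 2L)) oversample_half_ripe else 1L
    for (r in seq_len(reps)) {
      img <- item$image
      msk <- item$mask
      applied <- list()
      for (k in seq_along(spec_list)) {
        sp <- spec_list[[k]]
        sp$seed <- vseed + k
        a <- apply_augmentation(img, msk, sp)
        img <- a$image
        msk <- a$mask
        applied[[k]] <- list(op_name = sp$op_name, params = a$params,
                             seed = sp$seed)
      }
      out[[length(out) + 1L]] <- list(image = img, mask = msk,
                                      source_index = i, specs = applied,
                                      seed = vseed)
      vseed <- vseed + length(spec_list) + 1L
    }
  }
  out
}
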