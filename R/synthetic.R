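# Seeded synthetic greenhouse scenes: tomato discs with a red/green surface
# split determined by the ripeness red-fraction rule, foliage occluders drawn
# over them, and per-scene lighting gain. The generator emulates the
# statistical structure documented for greenhouse ripeness datasets (class
# definitions by red surface fraction, heavy class imbalance, occlusion,
# lighting variation); it makes no attempt at photorealism.

#' Ripeness class labels
#'
#' Label alphabet of the segmentation masks: 0 = background, 1 = unripe,
#' 2 = half-ripe, 3 = fully-ripe.
#' @return named integer vector.
#' @export
ripeness_levels <- function() {
  c(background = 0L, unripe = 1L, half_ripe = 2L, fully_ripe = 3L)
}

# Instance counts reported for the emulated greenhouse dataset
# (unripe / half-ripe / fully-ripe); their normalisation is the default
# class mix of the generator.
kutoma_class_counts <- function() c(unripe = 3557, half_ripe = 196, fully_ripe = 724)

#' Ripeness class from the red surface fraction
#'
#' Fully-ripe tomatoes have at least 90% of their surface red, half-ripe
#' 30-89%, unripe below 30%. Both boundaries are closed at the lower end of
#' their band (0.90 is fully-ripe, 0.30 is half-ripe).
#'
#' @param red_fraction numeric vector in `[0, 1]`.
#' @return integer vector of class labels (1 = unripe, 2 = half-ripe,
#'   3 = fully-ripe), see [ripeness_levels()].
#' @examples
#' ripeness_class_from_red_fraction(c(0.95, 0.5, 0.1)) # 3 2 1
#' @export
ripeness_class_from_red_fraction <- function(red_fraction) {
  if (any(!is.finite(red_fraction)) || any(red_fraction < 0 | red_fraction > 1))
    stop("red_fraction must lie in [0, 1]")
  ifelse(red_fraction >= 0.90, 3L, ifelse(red_fraction >= 0.30, 2L, 1L))
}

#' Scene generator configuration
#'
#' @param image_rows,image_cols canvas size in pixels (default 64x64, the
#'   desk scale used in the tests; 540x640 mirrors the published input size).
#' @param n_tomatoes_range inclusive integer range of tomatoes per scene.
#' @param radius_range inclusive pixel range of disc radii (min >= 2).
#' @param class_mix probability triple over (unripe, half-ripe, fully-ripe);
#'   must sum to 1. The default normalises the documented instance counts
#'   3557/196/724.
#' @param occlusion_density target fraction of the canvas covered by foliage
#'   strokes (drawn after the tomatoes, so they genuinely truncate
#'   instances).
#' @param lighting_gain_range multiplicative lighting gain interval.
#' @param allow_overlap if `FALSE` (default) tomato discs are placed with
#'   rejection sampling so that no two discs touch; the per-class connected
#'   components of an occlusion-free mask then coincide exactly with the
#'   generated instances.
#' @param seed integer seed; scenes are fully deterministic given the config.
#' @return validated config list of class `"tf_scene_config"`.
#' @export
scene_config <- function(image_rows = 64L, image_cols = 64L,
                         n_tomatoes_range = c(2L, 6L),
                         radius_range = c(4L, 9L),
                         class_mix = NULL,
                         occlusion_density = 0.15,
                         lighting_gain_range = c(0.7, 1.3),
                         allow_overlap = FALSE,
                         seed = 1L) {
  if (is.null(class_mix)) {
    cc <- kutoma_class_counts()
    class_mix <- cc / sum(cc)
  }
  if (length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-6)
    stop("class_mix must be 3 nonnegative probabilities summing to 1")
  if (radius_range[1L] < 2L) stop("minimum radius must be >= 2 px")
  if (diff(n_tomatoes_range) < 0 || diff(radius_range) < 0 ||
      diff(lighting_gain_range) < 0)
    stop("ranges must be nonempty (min <= max)")
  if (n_tomatoes_range[1L] < 0L) stop("tomato count cannot be negative")
  if (occlusion_density < 0 || occlusion_density > 1)
    stop("occlusion_density must lie in [0, 1]")
  if (min(image_rows, image_cols) < 2L * radius_range[2L] + 2L)
    stop("canvas ", image_rows, "x", image_cols,
         " too small for maximum radius ", radius_range[2L])
  structure(list(image_rows = as.integer(image_rows),
                 image_cols = as.integer(image_cols),
                 n_tomatoes_range = as.integer(n_tomatoes_range),
                 radius_range = as.integer(radius_range),
                 class_mix = unname(class_mix),
                 occlusion_density = occlusion_density,
                 lighting_gain_range = lighting_gain_range,
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "tf_scene_config")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# low-frequency per-channel colour field around a base colour
.background_canvas <- function(h, w, base = c(0.20, 0.33, 0.16), amp = 0.06) {
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    coarse <- matrix(stats::runif(16, -amp, amp), 4L, 4L)
    img[, , ch] <- base[ch] + resize_bilinear(array(coarse, c(4L, 4L, 1L)), h, w)[, , 1L]
  }
  clip01(img)
}

.disc_pixels <- function(h, w, r0, c0, rad) {
  rr <- pmax(1L, floor(r0 - rad)):pmin(h, ceiling(r0 + rad))
  cc <- pmax(1L, floor(c0 - rad)):pmin(w, ceiling(c0 + rad))
  sel <- outer((rr - r0)^2, (cc - c0)^2, "+") <= rad^2
  cbind(row = rep(rr, times = length(cc))[as.vector(sel)],
        col = rep(cc, each = length(rr))[as.vector(sel)])
}

#' Generate one synthetic greenhouse scene
#'
#' Renders tomato discs on a foliage-coloured canvas. Each disc's surface is
#' split into a red cap and a green remainder so that the red pixel fraction
#' matches the instance's sampled `red_fraction`, whose class band is drawn
#' from `class_mix`. Foliage occluders are drawn after the tomatoes and
#' overwrite them with background-labelled greenery; a global lighting gain
#' is applied last. Deterministic given the config (including its seed).
#'
#' @param config a [scene_config()].
#' @return list: `image` (`H x W x 3` in `[0,1]`), `mask` (`H x W` integer
#'   labels 0-3), `instances` (data frame: id, class_label, center_row,
#'   center_col, radius, red_fraction, visible_pixels and the bounding box
#'   row_min/col_min/row_max/col_max of the visible pixels, NA when fully
#'   occluded).
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "tf_scene_config"))
  with_seed(config$seed, {
    h <- config$image_rows; w <- config$image_cols
    img <- .background_canvas(h, w)
    mask <- matrix(0L, h, w)
    owner <- matrix(0L, h, w)

    nt_range <- config$n_tomatoes_range
    n_t <- if (nt_range[1L] == nt_range[2L]) nt_range[1L] else
      sample(nt_range[1L]:nt_range[2L], 1L)

    placed <- list()
    for (id in seq_len(n_t)) {
      rad <- if (config$radius_range[1L] == config$radius_range[2L])
        config$radius_range[1L] else
          sample(config$radius_range[1L]:config$radius_range[2L], 1L)
      cls <- sample(1:3, 1L, prob = config$class_mix)
      red_fraction <- switch(cls,
                             stats::runif(1, 0, 0.2999),
                             stats::runif(1, 0.30, 0.8999),
                             stats::runif(1, 0.90, 1))
      ok <- FALSE
      for (try in 1:60) {
        r0 <- sample(seq_len(h), 1L); c0 <- sample(seq_len(w), 1L)
        if (!config$allow_overlap && length(placed) > 0L) {
          sep <- vapply(placed, function(p)
            sqrt((p$r0 - r0)^2 + (p$c0 - c0)^2) > p$rad + rad + 2.5, logical(1))
          if (!all(sep)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) next # canvas saturated; scene holds fewer tomatoes
      px <- .disc_pixels(h, w, r0, c0, rad)
      if (nrow(px) == 0L) next
      n_red <- round(red_fraction * nrow(px))
      ord <- order(px[, "row"], px[, "col"])
      is_red <- logical(nrow(px))
      if (n_red > 0L) is_red[ord[seq_len(n_red)]] <- TRUE
      shade <- stats::runif(1, 0.85, 1.15)
      red_col <- clip01(c(0.78, 0.13, 0.10) * shade)
      green_col <- clip01(c(0.42, 0.55, 0.20) * shade)
      lin <- (px[, "col"] - 1L) * h + px[, "row"]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[lin] <- ifelse(is_red, red_col[ch], green_col[ch])
        img[, , ch] <- plane
      }
      mask[lin] <- cls
      owner[lin] <- id
      placed[[length(placed) + 1L]] <-
        list(id = id, r0 = r0, c0 = c0, rad = rad, cls = cls,
             red_fraction = red_fraction)
    }

    # foliage occluders: random rotated ellipses until the target canvas
    # coverage is reached
    if (config$occlusion_density > 0 && length(placed) >= 0L) {
      covered <- matrix(FALSE, h, w)
      target <- config$occlusion_density * h * w
      for (k in 1:200) {
        if (sum(covered) >= target) break
        ec <- c(sample(seq_len(h), 1L), sample(seq_len(w), 1L))
        a <- stats::runif(1, 2, max(3, h / 6))
        b <- stats::runif(1, 1, max(2, a / 2))
        th <- stats::runif(1, 0, pi)
        rr <- pmax(1L, floor(ec[1L] - a)):pmin(h, ceiling(ec[1L] + a))
        cc <- pmax(1L, floor(ec[2L] - a)):pmin(w, ceiling(ec[2L] + a))
        dr <- rep(rr - ec[1L], times = length(cc))
        dc <- rep(cc - ec[2L], each = length(rr))
        u <- dr * cos(th) + dc * sin(th)
        v <- -dr * sin(th) + dc * cos(th)
        sel <- (u / a)^2 + (v / b)^2 <= 1
        if (!any(sel)) next
        rows <- rep(rr, times = length(cc))[sel]
        cols <- rep(cc, each = length(rr))[sel]
        lin <- (cols - 1L) * h + rows
        shade <- stats::runif(1, 0.7, 1.1)
        leaf <- clip01(c(0.16, 0.30, 0.12) * shade)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[lin] <- leaf[ch]
          img[, , ch] <- plane
        }
        mask[lin] <- 0L
        owner[lin] <- 0L
        covered[lin] <- TRUE
      }
    }

    gain <- stats::runif(1, config$lighting_gain_range[1L],
                         config$lighting_gain_range[2L])
    img <- clip01(img * gain)

    inst <- lapply(placed, function(p) {
      vis <- which(owner == p$id)
      if (length(vis) > 0L) {
        rows <- ((vis - 1L) %% h) + 1L
        cols <- ((vis - 1L) %/% h) + 1L
        box <- c(min(rows), min(cols), max(rows), max(cols))
      } else box <- rep(NA_integer_, 4L)
      data.frame(id = p$id, class_label = p$cls, center_row = p$r0,
                 center_col = p$c0, radius = p$rad,
                 red_fraction = p$red_fraction,
                 visible_pixels = length(vis),
                 row_min = box[1L], col_min = box[2L],
                 row_max = box[3L], col_max = box[4L])
    })
    instances <- if (length(inst)) do.call(rbind, inst) else
      data.frame(id = integer(0), class_label = integer(0),
                 center_row = integer(0), center_col = integer(0),
                 radius = integer(0), red_fraction = numeric(0),
                 visible_pixels = integer(0), row_min = integer(0),
                 col_min = integer(0), row_max = integer(0),
                 col_max = integer(0))
    list(image = img, mask = mask, instances = instances)
  })
}

#' Generate and write a synthetic dataset
#'
#' Renders `n_images` scenes (scene i uses seed `config$seed + i - 1`),
#' writes 8-bit RGB PNG images and single-channel label-mask PNGs, and a
#' JSON manifest (array of `{image, mask, seed, instances}` entries, paths
#' relative to the manifest).
#'
#' @param config a [scene_config()]; its seed anchors the whole dataset.
#' @param n_images number of scenes (>= 1).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list: `manifest` (path), `entries`,
#'   `class_counts` (per-class instance counts across the dataset).
#' @export
generate_dataset <- function(config = scene_config(), n_images, out_dir) {
  if (n_images < 1L) stop("n_images must be >= 1")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  entries <- vector("list", n_images)
  counts <- c(unripe = 0L, half_ripe = 0L, fully_ripe = 0L)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    sc <- generate_scene(cfg_i)
    img_rel <- file.path("images", sprintf("scene_%04d.png", i))
    msk_rel <- file.path("masks", sprintf("scene_%04d.png", i))
    write_scene_image(sc$image, file.path(out_dir, img_rel))
    write_label_mask(sc$mask, file.path(out_dir, msk_rel))
    tab <- tabulate(sc$instances$class_label, nbins = 3L)
    counts <- counts + tab
    entries[[i]] <- list(image = img_rel, mask = msk_rel, seed = cfg_i$seed,
                         instances = sc$instances)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, manifest_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  message("wrote ", n_images, " scenes; instance counts: unripe=", counts[1L],
          " half_ripe=", counts[2L], " fully_ripe=", counts[3L])
  invisible(list(manifest = manifest_path, entries = entries,
                 class_counts = counts))
}

#' @rdname read_dataset
#' @param image `H x W x 3` array in `[0,1]`.
#' @param path file path.
#' @export
write_scene_image <- function(image, path) {
  png::writePNG(clip01(image), path)
  invisible(path)
}

#' @rdname read_dataset
#' @param mask `H x W` integer label matrix.
#' @export
write_label_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname read_dataset
#' @export
read_scene_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  array(img[, , 1:3], c(dim(img)[1:2], 3L)) # drop any alpha channel
}

#' @rdname read_dataset
#' @export
read_label_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  mi <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  if (any(mi < 0L | mi > 3L)) stop("mask ", path, " has labels outside 0..3")
  mi
}

#' Read a dataset from its JSON manifest
#'
#' Round-trips [generate_dataset()] output: masks are recovered exactly,
#' images up to 8-bit quantisation. Each entry is validated (files exist,
#' image and mask shapes agree); failures name the offending entry.
#'
#' @param manifest path to a `manifest.json`.
#' @return list of scenes: `image`, `mask`, `instances` (data frame, possibly
#'   empty).
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  entries <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  base <- dirname(manifest)
  lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    ip <- file.path(base, e$image)
    mp <- file.path(base, e$mask)
    if (!file.exists(ip) || !file.exists(mp))
      stop("manifest entry ", i, ": missing file ",
           if (!file.exists(ip)) e$image else e$mask)
    img <- read_scene_image(ip)
    msk <- read_label_mask(mp)
    if (!identical(dim(img)[1:2], dim(msk)))
      stop("manifest entry ", i, " (", e$image,
           "): image/mask shape mismatch (", paste(dim(img)[1:2], collapse = "x"),
           " vs ", paste(dim(msk), collapse = "x"), ")")
    inst <- e$instances
    inst <- if (is.null(inst) || length(inst) == 0L) NULL else
      do.call(rbind, lapply(inst, function(r) as.data.frame(r)))
    list(image = img, mask = msk, instances = inst, seed = e$seed)
  })
}
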